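#' Image volume: a stack of 2-D slices with a pixel spacing
#'
#' The unit every pipeline stage consumes and produces: an ordered list of
#' equally shaped 2-D numeric matrices (axial slices) plus the in-plane pixel
#' spacing in millimetres. Slices are non-contiguous in the emulated
#' acquisition, so no slice spacing is modelled beyond metadata.
#'
#' @param slices list of numeric matrices, all the same shape.
#' @param pixel_spacing in-plane pixel spacing in mm.
#' @param metadata optional named list carried through (protocol details etc.).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(slices, pixel_spacing, metadata = list()) {
  if (is.matrix(slices)) slices <- list(slices)
  stopifnot(is.list(slices), length(slices) >= 1L,
            all(vapply(slices, is.matrix, logical(1))),
            is.numeric(pixel_spacing), pixel_spacing > 0)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices of an image volume must share one shape")
  structure(
    list(slices = slices, pixel_spacing = as.numeric(pixel_spacing),
         slice_count = length(slices), metadata = metadata),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<image_volume> %d slice(s) of %d x %d, pixel spacing %.3f mm\n",
              x$slice_count, d[1], d[2], x$pixel_spacing))
  rng <- range(unlist(lapply(x$slices, range)))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) c(dim(x$slices[[1]]), x$slice_count)

# map a function over slices, preserving class/metadata
map_slices <- function(volume, f, ...) {
  volume$slices <- lapply(volume$slices, f, ...)
  volume
}

volume_matrix_size <- function(volume) ncol(volume$slices[[1]])

check_same_geometry <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("image volumes have mismatched geometry: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}
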