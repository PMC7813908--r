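#' Circular ROI specification
#'
#' Centre and radius are given in pixels at a reference matrix size; when a
#' slice at another matrix size is sampled, both are rescaled by
#' `matrix / reference_matrix` so the physical region covered stays constant
#' (the field of view is fixed). Coordinates are 1-based (row, col) at pixel
#' centres.
#'
#' @param center numeric length-2, (row, col) at the reference matrix.
#' @param radius radius in pixels at the reference matrix.
#' @param reference_matrix matrix size the centre/radius refer to.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center = c(128.5, 128.5), radius = 60,
                     reference_matrix = 256L) {
  stopifnot(length(center) == 2, radius > 0, reference_matrix >= 8)
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 reference_matrix = as.integer(reference_matrix)),
            class = "roi_spec")
}

scale_roi <- function(spec, matrix) {
  s <- matrix / spec$reference_matrix
  # pixel-centre coordinates scale about the grid origin at 0.5
  list(center = (spec$center - 0.5) * s + 0.5, radius = spec$radius * s)
}

#' Extract a circular ROI patch from a slice
#'
#' Selects pixels whose centre lies within the circle (squared-distance
#' `<=` rule), after rescaling the ROI to the slice's matrix size.
#'
#' @param slice 2-D numeric matrix.
#' @param spec an [roi_spec].
#' @param matrix matrix size of `slice`; defaults to `ncol(slice)`.
#' @return An object of class `roi_patch` with fields `values` (in-mask
#'   intensities, column-major order), `mask` (logical matrix) and
#'   `normalized` flag.
#' @export
extract_roi <- function(slice, spec, matrix = ncol(slice)) {
  stopifnot(is.matrix(slice), inherits(spec, "roi_spec"))
  sc <- scale_roi(spec, matrix)
  nr <- nrow(slice); nc <- ncol(slice)
  if (sc$center[1] - sc$radius < 0.5 || sc$center[1] + sc$radius > nr + 0.5 ||
      sc$center[2] - sc$radius < 0.5 || sc$center[2] + sc$radius > nc + 0.5)
    stop(sprintf("scaled ROI (centre %.1f,%.1f radius %.1f) falls outside the %dx%d image",
                 sc$center[1], sc$center[2], sc$radius, nr, nc))
  r <- matrix(seq_len(nr), nr, nc)
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask <- (r - sc$center[1])^2 + (c_ - sc$center[2])^2 <= sc$radius^2
  if (!any(mask)) stop("ROI selects no pixels")
  roi_patch(slice[mask], mask)
}

roi_patch <- function(values, mask, normalized = FALSE) {
  stopifnot(sum(mask) == length(values))
  structure(list(values = as.numeric(values), mask = mask,
                 grid_shape = dim(mask), normalized = normalized),
            class = "roi_patch")
}

#' @export
print.roi_patch <- function(x, ...) {
  cat(sprintf("<roi_patch> %d pixels on a %d x %d grid%s\n", length(x$values),
              x$grid_shape[1], x$grid_shape[2],
              if (x$normalized) " (z-normalized)" else ""))
  invisible(x)
}

#' Z-score normalize an ROI patch
#'
#' Subtracts the in-mask mean and divides by the in-mask SD, so any affine
#' rescaling of the raw intensities leaves the downstream quantization and
#' texture matrices unchanged.
#'
#' @param patch an [roi_patch].
#' @return A normalized [roi_patch] (mean 0, SD 1).
#' @export
znormalize <- function(patch) {
  stopifnot(inherits(patch, "roi_patch"))
  s <- stats::sd(patch$values)
  if (!is.finite(s) || s == 0)
    stop("cannot z-normalize a constant ROI (zero SD); ",
         "use quantize(..., constant_fallback = TRUE) upstream if intended")
  patch$values <- (patch$values - mean(patch$values)) / s
  patch$normalized <- TRUE
  patch
}

#' Quantize a z-normalized ROI into uniform grey-level bins
#'
#' Z-values are clipped to the fixed range `[-clip, +clip]` (default 3.29,
#' the two-sided 99.9% normal quantile) and mapped to `n_levels` uniform
#' half-open bins over that range, the last bin closed. The fixed range
#' gives identical bin edges for every ROI. Set `range = "minmax"` for
#' per-ROI min-max binning instead.
#'
#' @param patch a z-normalized [roi_patch] (raw patches are accepted when
#'   `constant_fallback` routes a constant ROI to the middle level).
#' @param n_levels number of grey levels G (default 16).
#' @param clip half-width of the fixed quantization range in z units.
#' @param range "fixed" (default) or "minmax".
#' @param constant_fallback if TRUE, a constant ROI is assigned the middle
#'   level everywhere instead of erroring.
#' @return An object of class `quantized_roi`: `levels` (integer matrix, 0
#'   outside the mask, 1..G inside), `mask`, `n_levels`.
#' @export
quantize <- function(patch, n_levels = 16L, clip = 3.29,
                     range = c("fixed", "minmax"), constant_fallback = FALSE) {
  stopifnot(inherits(patch, "roi_patch"))
  range <- match.arg(range)
  if (n_levels < 2) stop("n_levels must be at least 2")
  v <- patch$values
  if (stats::sd(v) == 0 || !isTRUE(patch$normalized)) {
    if (stats::sd(v) == 0) {
      if (!constant_fallback)
        stop("constant ROI cannot be quantized; set constant_fallback = TRUE ",
             "to assign the middle grey level")
      lev <- rep(as.integer(ceiling(n_levels / 2)), length(v))
      return(quantized_roi(lev, patch$mask, n_levels))
    }
    stop("quantize expects a z-normalized patch; call znormalize() first")
  }
  if (range == "fixed") {
    lo <- -clip; hi <- clip
    v <- pmin(pmax(v, lo), hi)
  } else {
    lo <- min(v); hi <- max(v)
  }
  lev <- floor((v - lo) / (hi - lo) * n_levels) + 1L
  lev <- pmin(as.integer(lev), as.integer(n_levels)) # close the last bin
  quantized_roi(lev, patch$mask, n_levels)
}

quantized_roi <- function(levels_in_mask, mask, n_levels) {
  m <- matrix(0L, nrow(mask), ncol(mask))
  m[mask] <- levels_in_mask
  structure(list(levels = m, mask = mask, n_levels = as.integer(n_levels)),
            class = "quantized_roi")
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> %d pixels, G = %d levels\n", sum(x$mask),
              x$n_levels))
  invisible(x)
}
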