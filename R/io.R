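#' Write an image volume as NIfTI with a JSON sidecar
#'
#' Slices are stacked into a 3-D array; the in-plane pixel spacing and a
#' nominal 5 mm slice dimension go into the NIfTI header, and the volume
#' metadata (phantom/protocol details) into a `.json` sidecar next to the
#' image.
#'
#' @param volume an [image_volume].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param sidecar optional named list merged into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path, sidecar = list()) {
  stopifnot(inherits(volume, "image_volume"))
  arr <- array(unlist(volume$slices),
               dim = c(dim(volume$slices[[1]]), volume$slice_count))
  img <- RNifti::asNifti(arr)
  pixdim(img) <- c(volume$pixel_spacing, volume$pixel_spacing, 5)
  RNifti::writeNifti(img, path)
  meta <- c(list(pixel_spacing_mm = volume$pixel_spacing,
                 slice_count = volume$slice_count), volume$metadata, sidecar)
  jsonlite::write_json(meta, sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image volume from NIfTI
#'
#' @param path NIfTI file path.
#' @return An [image_volume] (slices from the 3rd dimension; pixel spacing
#'   from the header).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  slices <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  image_volume(slices, pixel_spacing = RNifti::pixdim(img)[1])
}

#' Export an ROI mask as NIfTI for audit
#'
#' @param mask logical matrix (one slice) or [quantize]d ROI.
#' @param path output NIfTI path.
#' @param pixel_spacing mm per pixel.
#' @export
write_mask_nifti <- function(mask, path, pixel_spacing = 1) {
  if (inherits(mask, "quantized_roi")) mask <- mask$mask
  stopifnot(is.logical(mask), is.matrix(mask))
  write_volume_nifti(image_volume(list(mask * 1), pixel_spacing), path)
}

#' Serialize a study configuration to YAML
#'
#' @param config a [study_config].
#' @param path output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  yaml::write_yaml(strip(unclass(config)), path)
  invisible(path)
}

#' Read a study configuration from YAML
#'
#' @param path `.yaml` path written by [write_study_config].
#' @return A [study_config].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  proto <- function(p) acquisition_protocol(p$weighting, p$nex, p$matrix,
                                            p$pixel_spacing, p$slice_count,
                                            if (is.null(p$metadata)) list()
                                            else p$metadata)
  spec <- function(s) {
    ph <- phantom_spec(s$kind, s$mean_intensity, s$texture_sd,
                       s$texture_correlation_length, s$object_radius, s$seed)
    ph
  }
  fc <- y$feature_config
  study_config(
    master_seed = y$master_seed,
    water = spec(y$water), tissue = spec(y$tissue),
    protocols = lapply(y$protocols, proto),
    roi = roi_spec(unlist(y$roi$center), y$roi$radius, y$roi$reference_matrix),
    nex_levels = unlist(y$nex_levels), r_levels = unlist(y$r_levels),
    snr_t1 = y$snr_t1, snr_t2 = y$snr_t2,
    max_shift = y$max_shift, max_rotation = y$max_rotation,
    share_noise_seed = y$share_noise_seed,
    feature_config = feature_config(fc$n_levels, fc$clip, fc$quant_range,
                                    fc$hist_bins, fc$distance,
                                    lapply(fc$directions, as.integer),
                                    fc$constant_fallback)
  )
}

#' Write the study's tabular outputs
#'
#' Writes `robustness_noise.csv`, `robustness_resolution.csv`,
#' `repeatability_T1.csv`, `repeatability_T2.csv` and `summary.json` into
#' `out_dir`.
#'
#' @param study a [run_phantom_study] result.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_study_outputs <- function(study, out_dir) {
  stopifnot(inherits(study, "texrep_study"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rb <- as.data.frame(study$robustness)
  rp <- as.data.frame(study$repeatability)
  utils::write.csv(rb[rb$parameter == "noise", ],
                   file.path(out_dir, "robustness_noise.csv"), row.names = FALSE)
  utils::write.csv(rb[rb$parameter == "resolution", ],
                   file.path(out_dir, "robustness_resolution.csv"), row.names = FALSE)
  utils::write.csv(rp[rp$weighting == "T1", ],
                   file.path(out_dir, "repeatability_T1.csv"), row.names = FALSE)
  utils::write.csv(rp[rp$weighting == "T2", ],
                   file.path(out_dir, "repeatability_T2.csv"), row.names = FALSE)
  jsonlite::write_json(study$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
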