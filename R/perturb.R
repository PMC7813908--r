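#' Difference-method SNR estimate
#'
#' The two-image difference method: SNR = mean of the averaged image over
#' the ROI, divided by SD of the difference image over the ROI divided by
#' sqrt(2). With two independent acquisitions the difference cancels the
#' object and its SD is sigma * sqrt(2), so the estimator recovers
#' mean / sigma. Pixels are pooled across all slices.
#'
#' @param img1,img2 two [image_volume]s of identical geometry, independently
#'   acquired or simulated.
#' @param roi an [roi_spec].
#' @return SNR estimate (dimensionless); `Inf` with a warning when the
#'   difference image has zero SD (identical inputs).
#' @export
estimate_snr_difference <- function(img1, img2, roi) {
  stopifnot(inherits(img1, "image_volume"), inherits(img2, "image_volume"))
  check_same_geometry(img1, img2)
  m <- volume_matrix_size(img1)
  sums <- numeric(0); diffs <- numeric(0)
  for (k in seq_len(img1$slice_count)) {
    p1 <- extract_roi(img1$slices[[k]], roi, m)
    p2 <- extract_roi(img2$slices[[k]], roi, m)
    sums <- c(sums, (p1$values + p2$values) / 2)
    diffs <- c(diffs, p1$values - p2$values)
  }
  sd_diff <- stats::sd(diffs)
  if (sd_diff == 0) {
    warning("difference image has zero SD (identical inputs); SNR is infinite")
    return(Inf)
  }
  mean(sums) / (sd_diff / sqrt(2))
}

#' Noise ladder specification
#'
#' The added-noise SD at each NEX level is `base_sigma / sqrt(NEX)`,
#' emulating signal averaging: `base_sigma` is the noise SD estimated at
#' NEX = 1.
#'
#' @param base_sigma noise SD at NEX = 1, signal units.
#' @param nex_levels integer NEX levels (default 1, 7, 13, 19, 25, 31).
#' @param seed ladder seed; each level draws an independent substream.
#' @return A list of class `noise_ladder`.
#' @export
noise_ladder <- function(base_sigma, nex_levels = c(1L, 7L, 13L, 19L, 25L, 31L),
                         seed = 1L) {
  stopifnot(base_sigma >= 0, all(nex_levels >= 1),
            all(nex_levels == round(nex_levels)))
  structure(list(base_sigma = as.numeric(base_sigma),
                 nex_levels = as.integer(nex_levels), seed = as.integer(seed)),
            class = "noise_ladder")
}

#' Simulate the NEX noise ladder
#'
#' Adds Gaussian noise of SD `base_sigma / sqrt(NEX)` to the base volume
#' (treated as noise-free), one independent realization per NEX level, in a
#' single pass per level (noise is never compounded across levels).
#'
#' @param base the base [image_volume].
#' @param ladder a [noise_ladder].
#' @return Named list `nex<k>` of noisy [image_volume]s.
#' @export
simulate_noise_ladder <- function(base, ladder) {
  stopifnot(inherits(base, "image_volume"), inherits(ladder, "noise_ladder"))
  out <- lapply(ladder$nex_levels, function(nex) {
    apply_acquisition_noise(base, sigma = ladder$base_sigma / sqrt(nex),
                            model = "gaussian",
                            seed = derive_seed(ladder$seed, paste0("nex", nex)))
  })
  names(out) <- paste0("nex", ladder$nex_levels)
  out
}

#' Resolution ladder specification
#'
#' Output matrix at level r is `round(base_matrix / r)`; non-integer ratios
#' are rounded to the nearest integer (256/3 -> 85 etc.), keeping the field
#' of view error below one pixel.
#'
#' @param base_matrix base matrix size (default 256).
#' @param r_levels integer reduction factors (default 1..6).
#' @return A list of class `resolution_ladder`.
#' @export
resolution_ladder <- function(base_matrix = 256L, r_levels = 1:6) {
  stopifnot(base_matrix >= 8, all(r_levels >= 1),
            all(r_levels == round(r_levels)))
  structure(list(base_matrix = as.integer(base_matrix),
                 r_levels = as.integer(r_levels)),
            class = "resolution_ladder")
}

#' Simulate the resolution ladder
#'
#' Downsamples the base volume to `round(base_matrix / r)` pixels per side
#' with bicubic interpolation and an antialiasing prefilter; pixel spacing
#' is rescaled so the field of view is preserved.
#'
#' @param base the base [image_volume] at `base_matrix` resolution.
#' @param ladder a [resolution_ladder].
#' @return Named list `r<k>` of resampled [image_volume]s.
#' @export
simulate_resolution_ladder <- function(base, ladder) {
  stopifnot(inherits(base, "image_volume"), inherits(ladder, "resolution_ladder"))
  if (volume_matrix_size(base) != ladder$base_matrix)
    stop("base volume matrix size does not match the ladder base_matrix")
  out <- lapply(ladder$r_levels, function(r) {
    resize_volume(base, round(ladder$base_matrix / r), antialias = TRUE)
  })
  names(out) <- paste0("r", ladder$r_levels)
  out
}

#' Extract features across a ladder of conditions
#'
#' Applies the ROI (rescaled per slice matrix size so the physical region is
#' constant) and the 46-feature extractor to every slice of every condition,
#' returning a tidy long table.
#'
#' @param volumes named list of [image_volume]s, one per condition.
#' @param roi an [roi_spec].
#' @param config a [feature_config].
#' @return `data.frame` with columns `condition`, `slice`, `feature`,
#'   `value`; one row per (condition, slice, feature).
#' @export
run_condition_sweep <- function(volumes, roi, config = feature_config()) {
  stopifnot(is.list(volumes), length(volumes) >= 1, !is.null(names(volumes)))
  rows <- lapply(names(volumes), function(cond) {
    vol <- volumes[[cond]]
    if (!inherits(vol, "image_volume"))
      stop("condition '", cond, "' is not an image_volume")
    m <- volume_matrix_size(vol)
    per_slice <- lapply(seq_len(vol$slice_count), function(k) {
      fv <- extract_all_features(extract_roi(vol$slices[[k]], roi, m), config)
      data.frame(condition = cond, slice = k, feature = names(fv),
                 value = unname(fv), stringsAsFactors = FALSE)
    })
    do.call(rbind, per_slice)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
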