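#' First-order intensity statistics
#'
#' The 14 first-order features, computed on the RAW (pre-normalization) ROI
#' intensities: energy, entropy, kurtosis, maximum, mean, mean absolute
#' deviation, median, minimum, root mean square, range, skewness, standard
#' deviation, uniformity and variance. Entropy and uniformity use a
#' `hist_bins` equal-width histogram over `[min, max]`; kurtosis is
#' non-excess (normal gives 3) and skewness, SD and variance use population
#' (n) denominators. Entropy is in bits.
#'
#' @param patch an [roi_patch] (raw intensities).
#' @param hist_bins number of histogram bins for entropy/uniformity.
#' @return Named numeric vector of length 14 (names `S.En` .. `S.Var`).
#' @export
first_order_features <- function(patch, hist_bins = 16L) {
  stopifnot(inherits(patch, "roi_patch"))
  x <- patch$values
  n <- length(x)
  if (n == 0) stop("empty ROI patch")
  mu <- mean(x)
  v_pop <- mean((x - mu)^2)
  sd_pop <- sqrt(v_pop)
  p <- intensity_histogram(x, hist_bins)
  skew <- if (sd_pop > 0) mean((x - mu)^3) / sd_pop^3 else 0
  kurt <- if (sd_pop > 0) mean((x - mu)^4) / v_pop^2 else 0
  c(
    S.En   = sum(x^2),
    S.Ent  = -sum(ifelse(p > 0, p * log2(p), 0)),
    S.Kur  = kurt,
    S.Max  = max(x),
    S.Mean = mu,
    S.MAD  = mean(abs(x - mu)),
    S.Med  = stats::median(x),
    S.Min  = min(x),
    S.RMS  = sqrt(mean(x^2)),
    S.Ran  = max(x) - min(x),
    S.Sk   = skew,
    S.Std  = sd_pop,
    S.Un   = sum(p^2),
    S.Var  = v_pop
  )
}

# equal-width histogram probabilities over [min, max]; a constant vector
# occupies a single bin (uniformity 1, entropy 0)
intensity_histogram <- function(x, bins) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(1)
  idx <- floor((x - lo) / (hi - lo) * bins) + 1L
  idx <- pmin(idx, bins)
  tabulate(idx, bins) / length(x)
}
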