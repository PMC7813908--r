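#' Names of the 46 radiomic features
#'
#' 14 first-order statistics (`S.*`) and 32 second-order texture features
#' (`T.*`): 21 from the grey-level co-occurrence matrix and 11 from the
#' grey-level run-length matrix. `S.En`/`T.En` are distinct: intensity
#' energy versus GLCM angular second moment.
#'
#' @return Character vector of length 46, in the canonical table order.
#' @export
feature_names <- function() {
  c("S.En", "S.Ent", "S.Kur", "S.Max", "S.Mean", "S.MAD", "S.Med", "S.Min",
    "S.RMS", "S.Ran", "S.Sk", "S.Std", "S.Un", "S.Var",
    "T.Aut", "T.Clp", "T.Cls", "T.Clt", "T.Con", "T.Cor", "T.Den", "T.Dis",
    "T.En", "T.Ent", "T.GLNU", "T.HGLRU", "T.Hom1", "T.Hom2", "T.IMC1",
    "T.IMC2", "T.IDMN", "T.IDN", "T.IV", "T.LRE", "T.LRHGLE", "T.LRLGLE",
    "T.LoGLRU", "T.MP", "T.RLNU", "T.RP", "T.SRE", "T.SRHGLE", "T.SRLGLE",
    "T.SA", "T.SE", "T.SV")
}

#' Feature-extraction configuration
#'
#' @param n_levels grey levels G for quantization (default 16).
#' @param clip fixed quantization half-range in z units (default 3.29, the
#'   two-sided 99.9% normal quantile).
#' @param quant_range "fixed" or "minmax" quantization range.
#' @param hist_bins histogram bins for first-order entropy/uniformity.
#' @param distance GLCM offset distance in pixels.
#' @param directions list of `(drow, dcol)` offsets for GLCM/GLRLM.
#' @param constant_fallback route constant ROIs to the middle grey level
#'   instead of erroring (default TRUE, so noise-free uniform phantoms are
#'   processable end-to-end).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(n_levels = 16L, clip = 3.29,
                           quant_range = c("fixed", "minmax"),
                           hist_bins = 16L, distance = 1L,
                           directions = list(c(0L, 1L), c(1L, 0L),
                                             c(1L, 1L), c(1L, -1L)),
                           constant_fallback = TRUE) {
  structure(list(n_levels = as.integer(n_levels), clip = clip,
                 quant_range = match.arg(quant_range),
                 hist_bins = as.integer(hist_bins),
                 distance = as.integer(distance), directions = directions,
                 constant_fallback = constant_fallback),
            class = "feature_config")
}

#' Extract all 46 radiomic features from an ROI patch
#'
#' Composes the full per-ROI pipeline: first-order statistics on the raw
#' intensities, then z-normalization, grey-level quantization, GLCM and
#' GLRLM construction with direction averaging, and the second-order feature
#' formulas.
#'
#' @param patch an [roi_patch] of raw intensities.
#' @param config a [feature_config].
#' @return Named numeric vector of length 46 ([feature_names] order).
#' @export
extract_all_features <- function(patch, config = feature_config()) {
  stopifnot(inherits(patch, "roi_patch"))
  fo <- first_order_features(patch, hist_bins = config$hist_bins)
  constant <- stats::sd(patch$values) == 0
  q <- if (constant) {
    quantize(patch, n_levels = config$n_levels, clip = config$clip,
             range = config$quant_range,
             constant_fallback = config$constant_fallback)
  } else {
    quantize(znormalize(patch), n_levels = config$n_levels, clip = config$clip,
             range = config$quant_range)
  }
  P <- compute_glcm(q, distance = config$distance,
                    directions = config$directions)
  R <- compute_glrlm(q, directions = config$directions)
  out <- c(fo, glcm_features(P), glrlm_features(R))[feature_names()]
  stopifnot(length(out) == 46L, !anyNA(out))
  out
}
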