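#' Percentage coefficient of variation
#'
#' `100 * SD / |mean|` with the sample (n-1) SD, the spread of a feature
#' across repeated measurements normalised to its mean. A mean at or near
#' zero (below `tol` times the value scale) makes the ratio meaningless —
#' typical of sign-crossing features such as skewness or cluster shade — and
#' returns `NA` with a warning rather than an explosive value.
#'
#' @param values numeric vector, length >= 2.
#' @param tol relative near-zero-mean threshold.
#' @return %COV as a percentage, or `NA_real_` when undefined.
#' @export
percent_cov <- function(values, tol = 1e-12) {
  stopifnot(is.numeric(values), length(values) >= 2)
  m <- mean(values)
  scale <- max(abs(values), 1e-300)
  if (abs(m) <= tol * scale) {
    warning("mean is (near) zero; %COV undefined")
    return(NA_real_)
  }
  100 * stats::sd(values) / abs(m)
}

#' Pearson correlation between feature values and an acquisition parameter
#'
#' Standard product-moment correlation; either series being constant leaves
#' the correlation undefined (`NA` with a warning).
#'
#' @param feature_values,parameter_values equal-length numeric vectors
#'   (length >= 3).
#' @return Correlation in `[-1, 1]`, or `NA_real_`.
#' @export
pearson_r <- function(feature_values, parameter_values) {
  stopifnot(length(feature_values) == length(parameter_values),
            length(feature_values) >= 3)
  if (stats::sd(feature_values) == 0 || stats::sd(parameter_values) == 0) {
    warning("constant series; Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(feature_values, parameter_values)
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 rho sigma_x sigma_y / (sigma_x^2 + sigma_y^2 + (mu_x - mu_y)^2)`
#' with population (n-denominator) moments, Lin's original definition. It
#' combines precision (correlation) with accuracy (closeness to the
#' identity line): 1 is perfect agreement, 0 none.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return CCC in `[-1, 1]`, or `NA_real_` when both series are constant.
#' @export
ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) {
    warning("both series constant and equal; CCC undefined")
    return(NA_real_)
  }
  2 * sxy / denom
}

#' Classify %COV into robustness bins
#'
#' High: %COV < 5; mid: 5 <= %COV <= 30; low: %COV > 30. Exact boundary
#' values fall into the middle class; undefined metrics are
#' "unclassifiable".
#'
#' @param pct_cov %COV value(s).
#' @return Character vector of class labels.
#' @export
classify_robustness <- function(pct_cov) {
  vapply(pct_cov, function(v) {
    if (is.na(v)) "unclassifiable"
    else if (v < 5) "high"
    else if (v <= 30) "mid"
    else "low"
  }, character(1))
}

#' Classify a correlation into strength bins
#'
#' Uses `|r|`: high when |r| > 0.8, low when |r| < 0.2, mid otherwise
#' (boundaries fall into mid); negative trends classify by magnitude.
#'
#' @param r correlation value(s).
#' @return Character vector of class labels.
#' @export
classify_correlation <- function(r) {
  vapply(r, function(v) {
    if (is.na(v)) "unclassifiable"
    else if (abs(v) > 0.8) "high"
    else if (abs(v) < 0.2) "low"
    else "mid"
  }, character(1))
}

#' Classify a CCC into repeatability bins
#'
#' Poor: CCC < 0.90; moderate: 0.90 <= CCC < 0.95; substantial:
#' 0.95 <= CCC <= 0.99; near-perfect: CCC > 0.99 (the 0.99 boundary falls
#' into the lower class).
#'
#' @param ccc_values CCC value(s).
#' @return Character vector of class labels.
#' @export
classify_repeatability <- function(ccc_values) {
  vapply(ccc_values, function(v) {
    if (is.na(v)) "unclassifiable"
    else if (v < 0.90) "poor"
    else if (v < 0.95) "moderate"
    else if (v <= 0.99) "substantial"
    else "near_perfect"
  }, character(1))
}

#' Per-feature robustness report for one perturbation sweep
#'
#' Aggregates a tidy feature table (one sweep: conditions x slices x
#' features) to one value per condition (mean over slices), then computes
#' %COV across conditions with its robustness class, and the Pearson
#' correlation of the per-condition values against the acquisition parameter
#' with its strength class.
#'
#' @param feature_table output of [run_condition_sweep].
#' @param parameter_values named numeric vector mapping each condition label
#'   to its acquisition-parameter value (NEX, or matrix size).
#' @param parameter label, "noise" or "resolution".
#' @return `data.frame` with one row per feature: `feature`, `parameter`,
#'   `pct_cov`, `robustness_class`, `pearson_r`, `correlation_class`.
#' @export
robustness_report <- function(feature_table, parameter_values,
                              parameter = c("noise", "resolution")) {
  parameter <- match.arg(parameter)
  conds <- unique(feature_table$condition)
  missing_p <- setdiff(conds, names(parameter_values))
  if (length(missing_p))
    stop("no parameter value for condition(s): ", paste(missing_p, collapse = ", "))
  if (length(conds) < 2)
    warning("only ", length(conds),
            " condition(s): %COV is undefined and flagged unclassifiable")
  feats <- unique(feature_table$feature)
  rows <- lapply(feats, function(f) {
    tf <- feature_table[feature_table$feature == f, ]
    per_cond <- vapply(conds, function(cc) mean(tf$value[tf$condition == cc]),
                       numeric(1))
    if (anyNA(per_cond))
      stop("incomplete sweep for feature ", f)
    pc <- if (length(per_cond) < 2) NA_real_
      else suppressWarnings(percent_cov(per_cond))
    pr <- if (length(per_cond) < 3) NA_real_
      else suppressWarnings(pearson_r(per_cond, parameter_values[conds]))
    data.frame(feature = f, parameter = parameter, pct_cov = pc,
               robustness_class = classify_robustness(pc),
               pearson_r = pr,
               correlation_class = classify_correlation(pr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-feature repeatability report from paired test-retest tables
#'
#' Pairs the two arms on (condition, slice, feature) and computes the CCC
#' per feature over the paired series, with its repeatability class.
#'
#' @param test_table,retest_table tidy feature tables of identical layout
#'   ([run_condition_sweep] output) for the two arms.
#' @param weighting label carried into the report ("T1" or "T2").
#' @return `data.frame` with one row per feature: `feature`, `weighting`,
#'   `ccc`, `repeatability_class`, `n_pairs`.
#' @export
repeatability_report <- function(test_table, retest_table, weighting = "T2") {
  key <- function(t) paste(t$condition, t$slice, t$feature, sep = "|")
  if (!identical(sort(key(test_table)), sort(key(retest_table))))
    stop("test and retest tables do not cover the same (condition, slice, feature) cells")
  retest_table <- retest_table[match(key(test_table), key(retest_table)), ]
  feats <- unique(test_table$feature)
  rows <- lapply(feats, function(f) {
    i <- test_table$feature == f
    cc <- suppressWarnings(ccc(test_table$value[i], retest_table$value[i]))
    data.frame(feature = f, weighting = weighting, ccc = cc,
               repeatability_class = classify_repeatability(cc),
               n_pairs = sum(i), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary counts for a set of reports
#'
#' @param robustness data.frame from [robustness_report] rows (possibly
#'   several sweeps bound together).
#' @param repeatability data.frame from [repeatability_report] rows.
#' @return Nested list of class counts per parameter / weighting, plus the
#'   features highly robust to both noise and resolution.
#' @export
summarize_reports <- function(robustness = NULL, repeatability = NULL) {
  out <- list()
  if (!is.null(robustness)) {
    out$robustness <- lapply(split(robustness, robustness$parameter), function(d)
      as.list(table(factor(d$robustness_class,
                           levels = c("high", "mid", "low", "unclassifiable")))))
    hi <- lapply(split(robustness, robustness$parameter), function(d)
      d$feature[d$robustness_class == "high"])
    if (all(c("noise", "resolution") %in% names(hi)))
      out$high_robust_both <- sort(intersect(hi$noise, hi$resolution))
  }
  if (!is.null(repeatability)) {
    out$repeatability <- lapply(split(repeatability, repeatability$weighting),
      function(d) as.list(table(factor(d$repeatability_class,
        levels = c("poor", "moderate", "substantial", "near_perfect",
                   "unclassifiable")))))
  }
  out
}
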