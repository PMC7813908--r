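#' Study configuration
#'
#' One object holding everything the full repeatability/robustness study
#' needs: phantom specs, acquisition protocols, ROI, ladders, repositioning
#' bounds and the master seed from which every stochastic stage derives a
#' named substream. Round-trips losslessly through YAML
#' ([write_study_config] / [read_study_config]).
#'
#' @param master_seed integer master seed.
#' @param water,tissue [phantom_spec]s for the two phantoms.
#' @param protocols named list of [acquisition_protocol]s (default the six
#'   standard protocols, [default_protocols]).
#' @param roi an [roi_spec].
#' @param nex_levels NEX levels of the noise ladder.
#' @param r_levels reduction factors of the resolution ladder.
#' @param snr_t1,snr_t2 target SNR at NEX = 1 for the two weightings, used to
#'   set the simulated noise SD (`mean_intensity / snr`). Defaults 4.69 and
#'   3.75, the difference-method measurements at NEX = 1.
#' @param max_shift,max_rotation repositioning jitter bounds (mm, degrees).
#' @param share_noise_seed if TRUE the retest arm reuses the test arm's
#'   noise seed (with zero jitter the arms are then identical).
#' @param feature_config a [feature_config].
#' @return A list of class `study_config`.
#' @export
study_config <- function(master_seed = 1L,
                         water = phantom_spec("water"),
                         tissue = phantom_spec("tissue"),
                         protocols = default_protocols(),
                         roi = roi_spec(),
                         nex_levels = c(1L, 7L, 13L, 19L, 25L, 31L),
                         r_levels = 1:6,
                         snr_t1 = 4.69, snr_t2 = 3.75,
                         max_shift = 2, max_rotation = 1,
                         share_noise_seed = FALSE,
                         feature_config = texrep::feature_config()) {
  stopifnot(master_seed == round(master_seed), snr_t1 > 0, snr_t2 > 0)
  structure(list(master_seed = as.integer(master_seed), water = water,
                 tissue = tissue, protocols = protocols, roi = roi,
                 nex_levels = as.integer(nex_levels),
                 r_levels = as.integer(r_levels),
                 snr_t1 = snr_t1, snr_t2 = snr_t2,
                 max_shift = max_shift, max_rotation = max_rotation,
                 share_noise_seed = isTRUE(share_noise_seed),
                 feature_config = feature_config),
            class = "study_config")
}

# phantom spec with its texture seed tied to the master seed
seeded_phantom <- function(config, which) {
  spec <- config[[which]]
  spec$seed <- derive_seed(config$master_seed, paste0("phantom-", which))
  spec
}

base_sigma_for <- function(config, weighting) {
  snr <- if (weighting == "T1") config$snr_t1 else config$snr_t2
  mean(c(config$water$mean_intensity, config$tissue$mean_intensity)) / snr
}

# noise-free object resized to the protocol matrix, then given the residual
# noise of a NEX-32 acquisition (the base images are acquired, not ideal)
acquired_base <- function(config, which, protocol, arm = "test") {
  spec <- seeded_phantom(config, which)
  ref <- config$protocols[[1]]$matrix
  clean <- generate_phantom(spec, acquisition_protocol(
    protocol$weighting, protocol$nex, ref,
    protocol$pixel_spacing * protocol$matrix / ref,
    slice_count = protocol$slice_count, metadata = protocol$metadata))
  if (protocol$matrix != ref) clean <- resize_volume(clean, protocol$matrix)
  sigma <- base_sigma_for(config, protocol$weighting) / sqrt(32)
  apply_acquisition_noise(clean, sigma, "gaussian",
                          seed = derive_seed(config$master_seed,
                                             paste0("base-", which, "-",
                                                    protocol$weighting, "-", arm)))
}

#' Run the noise and resolution robustness experiment
#'
#' For each phantom, simulates the NEX noise ladder and the resolution
#' ladder from a T2-weighted base acquisition, extracts the 46 features at
#' every (condition, slice), and reports per-feature %COV and Pearson
#' correlation with the acquisition parameter (NEX for noise, matrix size
#' for resolution), with classification bins.
#'
#' @param config a [study_config].
#' @return A `texrep_robustness` data.frame: one row per (phantom, feature,
#'   parameter), 46 x 2 rows per phantom, with attribute `summary`.
#' @export
run_robustness <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  t2 <- Filter(function(p) p$weighting == "T2" && p$matrix ==
                 max(vapply(config$protocols, `[[`, integer(1), "matrix")),
               config$protocols)[[1]]
  sigma1 <- base_sigma_for(config, "T2")
  out <- lapply(c("water", "tissue"), function(ph) {
    base <- acquired_base(config, ph, t2)
    nl <- noise_ladder(sigma1, config$nex_levels,
                       seed = derive_seed(config$master_seed,
                                          paste0("noise-ladder-", ph)))
    noise_vols <- simulate_noise_ladder(base, nl)
    rl <- resolution_ladder(t2$matrix, config$r_levels)
    res_vols <- simulate_resolution_ladder(base, rl)
    noise_tab <- run_condition_sweep(noise_vols, config$roi, config$feature_config)
    res_tab <- run_condition_sweep(res_vols, config$roi, config$feature_config)
    nex_par <- stats::setNames(as.numeric(config$nex_levels), names(noise_vols))
    mat_par <- stats::setNames(round(t2$matrix / config$r_levels), names(res_vols))
    rb <- rbind(robustness_report(noise_tab, nex_par, "noise"),
                robustness_report(res_tab, mat_par, "resolution"))
    rb$phantom <- ph
    rb
  })
  res <- do.call(rbind, out)
  res <- res[, c("phantom", "feature", "parameter", "pct_cov",
                 "robustness_class", "pearson_r", "correlation_class")]
  attr(res, "summary") <- summarize_reports(robustness = res)
  class(res) <- c("texrep_robustness", "data.frame")
  res
}

#' Run the test-retest repeatability experiment
#'
#' For each weighting, acquires test and retest arms of both phantoms under
#' every protocol of that weighting: the retest arm is the same physical
#' object after repositioning jitter and with an independent noise
#' realization (or the identical realization when `share_noise_seed` is
#' set). Features are extracted per slice and paired across arms on
#' (phantom, protocol, slice); the CCC per feature is computed over the
#' pooled pairs.
#'
#' @param config a [study_config].
#' @return A `texrep_repeatability` data.frame: one row per (weighting,
#'   feature), 46 x 2 rows, with attribute `summary`.
#' @export
run_test_retest <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  arms <- function(weighting) {
    protos <- Filter(function(p) p$weighting == weighting, config$protocols)
    tabs <- lapply(c("test", "retest"), function(arm) {
      per <- lapply(names(protos), function(pn) {
        p <- protos[[pn]]
        per_ph <- lapply(c("water", "tissue"), function(ph) {
          vol <- acquired_base(config, ph, p, arm = "base")
          if (arm == "retest")
            vol <- apply_repositioning(vol, config$max_shift, config$max_rotation,
                                       seed = derive_seed(config$master_seed,
                                                          paste0("jitter-", ph, "-", pn)))
          noise_arm <- if (config$share_noise_seed) "test" else arm
          vol <- apply_acquisition_noise(
            vol, base_sigma_for(config, weighting) / sqrt(p$nex), "gaussian",
            seed = derive_seed(config$master_seed,
                               paste0("arm-", noise_arm, "-", ph, "-", pn)))
          vols <- stats::setNames(list(vol), paste(ph, pn, sep = "-"))
          run_condition_sweep(vols, config$roi, config$feature_config)
        })
        do.call(rbind, per_ph)
      })
      do.call(rbind, per)
    })
    repeatability_report(tabs[[1]], tabs[[2]], weighting = weighting)
  }
  res <- rbind(arms("T1"), arms("T2"))
  rownames(res) <- NULL
  attr(res, "summary") <- summarize_reports(repeatability = res)
  class(res) <- c("texrep_repeatability", "data.frame")
  res
}

#' Run the full phantom study
#'
#' Robustness (noise + resolution ladders) and test-retest repeatability in
#' one call, with optional CSV/JSON output.
#'
#' @param config a [study_config].
#' @param out_dir optional directory; when given, writes
#'   `robustness_noise.csv`, `robustness_resolution.csv`,
#'   `repeatability_T1.csv`, `repeatability_T2.csv` and `summary.json`.
#' @return A list of class `texrep_study` with elements `robustness`,
#'   `repeatability`, `summary`, `config`.
#' @export
run_phantom_study <- function(config = study_config(), out_dir = NULL) {
  rb <- run_robustness(config)
  rp <- run_test_retest(config)
  smry <- c(summarize_reports(robustness = rb), summarize_reports(repeatability = rp))
  res <- structure(list(robustness = rb, repeatability = rp, summary = smry,
                        config = config),
                   class = "texrep_study")
  if (!is.null(out_dir)) write_study_outputs(res, out_dir)
  res
}

#' @export
print.texrep_robustness <- function(x, ...) {
  cat("Texture-feature robustness (per phantom, per parameter)\n")
  s <- attr(x, "summary")$robustness
  for (p in names(s))
    cat(sprintf("  %-10s high %d | mid %d | low %d | unclassifiable %d\n", p,
                s[[p]]$high, s[[p]]$mid, s[[p]]$low, s[[p]]$unclassifiable))
  hb <- attr(x, "summary")$high_robust_both
  if (length(hb))
    cat("  highly robust to both:", paste(hb, collapse = ", "), "\n")
  cat(sprintf("  %d rows; first rows:\n", nrow(x)))
  print.data.frame(utils::head(x))
  invisible(x)
}

#' @export
print.texrep_repeatability <- function(x, ...) {
  cat("Texture-feature test-retest repeatability (CCC)\n")
  s <- attr(x, "summary")$repeatability
  for (w in names(s))
    cat(sprintf(
      "  %s: poor %d | moderate %d | substantial %d | near-perfect %d\n", w,
      s[[w]]$poor, s[[w]]$moderate, s[[w]]$substantial, s[[w]]$near_perfect))
  cat(sprintf("  %d rows; first rows:\n", nrow(x)))
  print.data.frame(utils::head(x))
  invisible(x)
}

#' @export
print.texrep_study <- function(x, ...) {
  cat("<texrep_study> master seed", x$config$master_seed, "\n")
  print(x$robustness)
  print(x$repeatability)
  invisible(x)
}

#' @export
summary.texrep_study <- function(object, ...) object$summary
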