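#' Acquisition protocol metadata
#'
#' Describes one simulated acquisition: contrast weighting label, number of
#' excitations (NEX), matrix size and pixel spacing. Sequence timing (TR/TE,
#' flip angle, ...) is carried as free-form metadata only — contrast physics
#' is not simulated. The field of view (matrix x pixel spacing) is expected
#' to stay fixed across protocols of one weighting.
#'
#' @param weighting "T1" or "T2".
#' @param nex number of excitations, >= 1. Noise SD scales as 1/sqrt(NEX).
#' @param matrix pixels per side (square matrix).
#' @param pixel_spacing in-plane pixel spacing, mm.
#' @param slice_count number of axial slices (default 5).
#' @param metadata named list of carried-but-unsimulated parameters.
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(weighting, nex, matrix, pixel_spacing,
                                 slice_count = 5L, metadata = list()) {
  weighting <- match.arg(weighting, c("T1", "T2"))
  stopifnot(nex >= 1, nex == round(nex), matrix >= 8, matrix == round(matrix),
            pixel_spacing > 0, slice_count >= 1)
  structure(
    list(weighting = weighting, nex = as.integer(nex),
         matrix = as.integer(matrix), pixel_spacing = as.numeric(pixel_spacing),
         slice_count = as.integer(slice_count), metadata = metadata),
    class = "acquisition_protocol"
  )
}

#' The six default acquisition protocols
#'
#' Protocols A-C are T2-weighted and D-F are T1-weighted; within each
#' weighting the first favours SNR (NEX 32), the second reduces SNR (NEX 1),
#' and the third additionally halves the matrix (128 at doubled pixel
#' spacing, fixed field of view). Timing parameters are metadata only.
#'
#' @return Named list of [acquisition_protocol] objects `A` .. `F`.
#' @export
default_protocols <- function() {
  t2_meta <- list(tr_ms = 3000, te_ms = 82, echo_train_length = 24,
                  bandwidth_khz = 300, flip_angle_deg = 150,
                  slice_thickness_mm = 5, slice_spacing_mm = 5.5)
  t1_meta <- list(tr_ms = 323, te_ms = 4.76, echo_train_length = 2,
                  bandwidth_khz = 455, flip_angle_deg = 70,
                  slice_thickness_mm = 5, slice_spacing_mm = 5.5)
  list(
    A = acquisition_protocol("T2", 32, 256, 1.18, metadata = t2_meta),
    B = acquisition_protocol("T2", 1, 256, 1.18, metadata = t2_meta),
    C = acquisition_protocol("T2", 1, 128, 2.34, metadata = t2_meta),
    D = acquisition_protocol("T1", 32, 256, 1.17, metadata = t1_meta),
    E = acquisition_protocol("T1", 1, 256, 1.17, metadata = t1_meta),
    F = acquisition_protocol("T1", 1, 128, 2.34, metadata = t1_meta)
  )
}

#' Phantom specification
#'
#' A circular object centred in the field of view: spatially uniform for the
#' water phantom, or carrying a smooth stationary Gaussian random-field
#' texture of given standard deviation and correlation length for the tissue
#' phantom. Intensity units are arbitrary; only first-order features depend
#' on the absolute scale.
#'
#' @param kind "water" (uniform) or "tissue" (textured).
#' @param mean_intensity mean signal inside the object, arbitrary units.
#' @param texture_sd SD of the texture field inside the object (0 for water).
#' @param texture_correlation_length correlation length of the texture, mm.
#' @param object_radius radius of the circular object, mm.
#' @param seed integer seed for the texture field.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("water", "tissue"), mean_intensity = 100,
                         texture_sd = if (kind == "water") 0 else 20,
                         texture_correlation_length = 3,
                         object_radius = 100, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(texture_sd >= 0, texture_correlation_length > 0, object_radius > 0)
  if (kind == "water" && texture_sd != 0)
    stop("water phantom must have texture_sd = 0")
  structure(
    list(kind = kind, mean_intensity = as.numeric(mean_intensity),
         texture_sd = as.numeric(texture_sd),
         texture_correlation_length = as.numeric(texture_correlation_length),
         object_radius = as.numeric(object_radius), seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Stationary Gaussian random field on an n x n grid: white noise smoothed by
# a periodic Gaussian kernel (FFT convolution), then rescaled to unit sample
# SD so the requested texture_sd is met empirically.
gaussian_random_field <- function(n, sigma_px) {
  noise <- matrix(rnorm(n * n), n, n)
  if (sigma_px <= .Machine$double.eps) return(noise)
  i <- 0:(n - 1)
  d <- ifelse(i > n / 2, i - n, i) # wrapped circular offsets
  g <- exp(-d^2 / (2 * sigma_px^2))
  K <- outer(g, g)
  K <- K / sum(K)
  f <- Re(fft(fft(noise) * fft(K), inverse = TRUE)) / (n * n)
  f / stats::sd(as.vector(f))
}

disc_mask <- function(n, radius_px, center = NULL) {
  if (is.null(center)) center <- rep((n + 1) / 2, 2)
  r <- matrix(seq_len(n), n, n)
  c_ <- matrix(seq_len(n), n, n, byrow = TRUE)
  (r - center[1])^2 + (c_ - center[2])^2 <= radius_px^2
}

#' Generate a noise-free phantom volume
#'
#' Renders a disc of the phantom's radius centred in each slice at the mean
#' intensity; for the tissue phantom a smooth correlated Gaussian random
#' field (independent per slice, emulating non-contiguous slices) is added
#' inside the disc. Background is 0. Deterministic given the spec seed.
#'
#' @param spec a [phantom_spec].
#' @param protocol an [acquisition_protocol].
#' @return A noise-free [image_volume].
#' @export
generate_phantom <- function(spec, protocol) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(protocol, "acquisition_protocol"))
  n <- protocol$matrix
  fov <- n * protocol$pixel_spacing
  radius_px <- spec$object_radius / protocol$pixel_spacing
  if (2 * spec$object_radius > fov)
    stop(sprintf(
      "object diameter %.1f mm exceeds the %.1f mm field of view",
      2 * spec$object_radius, fov))
  mask <- disc_mask(n, radius_px)
  sigma_px <- spec$texture_correlation_length / protocol$pixel_spacing
  slices <- with_seed(derive_seed(spec$seed, "phantom-texture"), {
    lapply(seq_len(protocol$slice_count), function(k) {
      s <- matrix(0, n, n)
      s[mask] <- spec$mean_intensity
      if (spec$texture_sd > 0) {
        f <- gaussian_random_field(n, sigma_px)
        s[mask] <- s[mask] + spec$texture_sd * f[mask]
      }
      s
    })
  })
  image_volume(slices, protocol$pixel_spacing,
               metadata = list(phantom = spec$kind, weighting = protocol$weighting,
                               nex = protocol$nex))
}

#' Add magnitude-MRI acquisition noise
#'
#' `gaussian` adds independent zero-mean Gaussian noise of SD `sigma` to
#' every pixel (the regime valid at SNR above about 3, where Rician noise is
#' essentially Gaussian). `rician` forms the magnitude of the complex signal
#' with independent Gaussian noise of SD `sigma` in each channel, the exact
#' magnitude-image noise model.
#'
#' @param volume an [image_volume].
#' @param sigma noise SD in signal units, >= 0.
#' @param model "gaussian" or "rician".
#' @param seed integer seed.
#' @return A noisy [image_volume].
#' @export
apply_acquisition_noise <- function(volume, sigma, model = c("gaussian", "rician"),
                                    seed = 1L) {
  stopifnot(inherits(volume, "image_volume"))
  model <- match.arg(model)
  if (sigma < 0) stop("noise sigma must be non-negative")
  if (sigma == 0) return(volume)
  with_seed(derive_seed(seed, paste0("noise-", model)), {
    map_slices(volume, function(s) {
      if (model == "gaussian") {
        s + matrix(rnorm(length(s), sd = sigma), nrow(s), ncol(s))
      } else {
        re <- s + matrix(rnorm(length(s), sd = sigma), nrow(s), ncol(s))
        im <- matrix(rnorm(length(s), sd = sigma), nrow(s), ncol(s))
        sqrt(re^2 + im^2)
      }
    })
  })
}

#' Apply test-retest repositioning jitter
#'
#' Draws one rigid in-plane transform — per-axis translation uniform in
#' `[-max_shift, max_shift]` mm and rotation uniform in
#' `[-max_rotation, max_rotation]` degrees — and applies it identically to
#' all slices with bicubic resampling and zero background fill, emulating
#' removal and immediate repositioning of the phantom between arms.
#'
#' @param volume an [image_volume].
#' @param max_shift maximum absolute translation per axis, mm.
#' @param max_rotation maximum absolute in-plane rotation, degrees.
#' @param seed integer seed.
#' @return A repositioned [image_volume].
#' @export
apply_repositioning <- function(volume, max_shift = 2, max_rotation = 1,
                                seed = 1L) {
  stopifnot(inherits(volume, "image_volume"))
  if (max_shift < 0 || max_rotation < 0)
    stop("max_shift and max_rotation must be non-negative")
  if (max_shift == 0 && max_rotation == 0) return(volume)
  draw <- with_seed(derive_seed(seed, "reposition"), {
    list(shift = stats::runif(2, -max_shift, max_shift),
         theta = stats::runif(1, -max_rotation, max_rotation) * pi / 180)
  })
  shift_px <- draw$shift / volume$pixel_spacing
  n_r <- nrow(volume$slices[[1]]); n_c <- ncol(volume$slices[[1]])
  ctr <- c((n_r + 1) / 2, (n_c + 1) / 2)
  rr <- matrix(seq_len(n_r), n_r, n_c) - ctr[1]
  cc <- matrix(seq_len(n_c), n_r, n_c, byrow = TRUE) - ctr[2]
  # inverse map: rotate output coords back, subtract the shift
  ct <- cos(draw$theta); st <- sin(draw$theta)
  src_r <- ct * rr + st * cc - shift_px[1] + ctr[1]
  src_c <- -st * rr + ct * cc - shift_px[2] + ctr[2]
  map_slices(volume, function(s) {
    matrix(bicubic_interp(s, as.vector(src_r), as.vector(src_c)), n_r, n_c)
  })
}
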