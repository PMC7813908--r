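# Bicubic resampling primitives.
#
# Keys' cubic convolution kernel with a = -0.5, the conventional "bicubic"
# of image-processing toolboxes. Downsampling widens the kernel support by
# the inverse scale factor (antialiasing prefilter folded into the kernel),
# which is the standard imresize behaviour the resolution simulation needs.

cubic_kernel <- function(x) {
  ax <- abs(x)
  w <- numeric(length(x))
  i1 <- ax <= 1
  i2 <- ax > 1 & ax < 2
  w[i1] <- (1.5 * ax[i1] - 2.5) * ax[i1]^2 + 1
  w[i2] <- ((-0.5 * ax[i2] + 2.5) * ax[i2] - 4) * ax[i2] + 2
  w
}

# n_out x n_in weight matrix for 1-D cubic resampling with optional
# antialiasing; boundary handling is edge replication.
resample_weights <- function(n_in, n_out, antialias = TRUE) {
  scale <- n_out / n_in
  if (scale < 1 && antialias) {
    width <- 4 / scale
    kern <- function(x) scale * cubic_kernel(scale * x)
  } else {
    width <- 4
    kern <- function(x) cubic_kernel(x)
  }
  # centre of output pixel i (1-based, pixel-centre convention) in input coords
  u <- (seq_len(n_out) - 0.5) / scale + 0.5
  p <- ceiling(width) + 2L
  left <- floor(u - width / 2)
  W <- matrix(0, n_out, n_in)
  for (k in seq_len(p)) {
    idx <- left + (k - 1L)
    w <- kern(u - idx)
    idx_cl <- pmin(pmax(idx, 1L), n_in) # replicate edges
    W[cbind(seq_len(n_out), idx_cl)] <- W[cbind(seq_len(n_out), idx_cl)] + w
  }
  W / rowSums(W)
}

resize_matrix_bicubic <- function(m, n_out_rows, n_out_cols, antialias = TRUE) {
  if (n_out_rows == nrow(m) && n_out_cols == ncol(m)) return(m)
  Wr <- resample_weights(nrow(m), n_out_rows, antialias)
  Wc <- resample_weights(ncol(m), n_out_cols, antialias)
  Wr %*% m %*% t(Wc)
}

#' Resize an image volume by bicubic interpolation
#'
#' Resamples every slice to a `matrix_out` x `matrix_out` grid with the cubic
#' convolution kernel; when downsampling, an antialiasing prefilter (kernel
#' support widened by the inverse scale) is applied. The pixel spacing is
#' rescaled so the field of view is preserved.
#'
#' @param volume an [image_volume].
#' @param matrix_out output pixels per side.
#' @param antialias logical; widen the kernel when downsampling (default TRUE).
#' @return An [image_volume] at the new matrix size.
#' @export
resize_volume <- function(volume, matrix_out, antialias = TRUE) {
  stopifnot(inherits(volume, "image_volume"),
            matrix_out >= 1, matrix_out == round(matrix_out))
  n_in <- volume_matrix_size(volume)
  out <- map_slices(volume, resize_matrix_bicubic, matrix_out, matrix_out,
                    antialias = antialias)
  out$pixel_spacing <- volume$pixel_spacing * n_in / matrix_out
  out
}

# Bicubic interpolation of matrix m at fractional (row, col) positions;
# positions whose 4x4 support leaves the image use zero fill for the
# missing taps (background 0).
bicubic_interp <- function(m, rs, cs) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(rs); c0 <- floor(cs)
  out <- numeric(length(rs))
  for (dr in -1:2) {
    ri <- r0 + dr
    wr <- cubic_kernel(rs - ri)
    rok <- ri >= 1 & ri <= nr
    for (dc in -1:2) {
      ci <- c0 + dc
      wc <- cubic_kernel(cs - ci)
      ok <- rok & ci >= 1 & ci <= nc
      w <- wr * wc
      if (any(ok)) {
        idx <- cbind(ri[ok], ci[ok])
        out[ok] <- out[ok] + w[ok] * m[idx]
      }
    }
  }
  out
}
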