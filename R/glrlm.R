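#' Grey-level run-length matrix
#'
#' Counts maximal runs of consecutive equal grey levels along each direction
#' within the ROI mask (mask gaps break runs). The four per-direction count
#' matrices are padded to a common maximum run length and averaged
#' element-wise; counts are kept unnormalized so run-total formulas apply.
#'
#' @param q a [quantize]d ROI.
#' @param directions list of `(drow, dcol)` step offsets; default the four
#'   in-plane directions.
#' @return An object of class `glrlm`: `matrix` (G x Rmax average counts),
#'   `n_levels`, `n_runs` (total averaged run count Nr), `n_pixels` (mask
#'   size), `per_direction` (list of per-direction count matrices).
#' @export
compute_glrlm <- function(q, directions = list(c(0L, 1L), c(1L, 0L),
                                               c(1L, 1L), c(1L, -1L))) {
  stopifnot(inherits(q, "quantized_roi"))
  if (!any(q$mask)) stop("empty ROI mask")
  G <- q$n_levels
  per_dir <- lapply(directions, function(d) glrlm_direction_counts(q$levels, G, d))
  rmax <- max(vapply(per_dir, ncol, integer(1)))
  padded <- lapply(per_dir, function(m) {
    if (ncol(m) < rmax) cbind(m, matrix(0, G, rmax - ncol(m))) else m
  })
  avg <- Reduce(`+`, padded) / length(padded)
  structure(list(matrix = avg, n_levels = G, n_runs = sum(avg),
                 n_pixels = sum(q$mask), per_direction = padded,
                 directions = directions),
            class = "glrlm")
}

# Run counts along one direction: lines of the level matrix are concatenated
# with a 0 separator and run-length encoded in one pass; level-0 runs
# (out-of-mask and separators) are dropped.
glrlm_direction_counts <- function(lev, G, d) {
  key <- if (d[1] == 0L) row(lev)                 # (0,1): rows
    else if (d[2] == 0L) col(lev)                 # (1,0): columns
    else if (d[1] == d[2]) col(lev) - row(lev)    # (1,1): diagonals
    else col(lev) + row(lev)                      # (1,-1): anti-diagonals
  lines <- split(lev, key) # within-group order follows the line
  v <- unlist(lapply(lines, function(g) c(g, 0L)), use.names = FALSE)
  r <- rle(v)
  keep <- r$values > 0L
  lv <- r$values[keep]
  ln <- r$lengths[keep]
  rmax <- if (length(ln)) max(ln) else 1L
  counts <- matrix(0, G, rmax)
  if (length(ln)) {
    tab <- tabulate((lv - 1L) * rmax + ln, G * rmax)
    counts <- matrix(tab, G, rmax, byrow = TRUE)
  }
  counts
}

#' @export
print.glrlm <- function(x, ...) {
  cat(sprintf("<glrlm> %d levels x max run %d, Nr = %.2f over %d pixels\n",
              x$n_levels, ncol(x$matrix), x$n_runs, x$n_pixels))
  invisible(x)
}

#' Galloway run-length texture features
#'
#' The 11 run-length features from the direction-averaged run counts
#' `r(g, l)` (grey level g, run length l), total run count Nr and in-mask
#' pixel count Np: short/long run emphasis, grey-level and run-length
#' non-uniformity, run percentage (Nr / Np), and the low/high grey-level and
#' combined short/long-run variants.
#'
#' @param R a [compute_glrlm] result.
#' @return Named numeric vector of length 11 (`T.GLNU` .. `T.SRLGLE`).
#' @export
glrlm_features <- function(R) {
  stopifnot(inherits(R, "glrlm"))
  M <- R$matrix
  if (R$n_runs <= 0) stop("GLRLM has zero runs")
  G <- nrow(M); L <- ncol(M)
  g <- matrix(seq_len(G), G, L)
  l <- matrix(seq_len(L), G, L, byrow = TRUE)
  Nr <- R$n_runs
  c(
    T.GLNU   = sum(rowSums(M)^2) / Nr,
    T.HGLRU  = sum(M * g^2) / Nr,
    T.LRE    = sum(M * l^2) / Nr,
    T.LRHGLE = sum(M * g^2 * l^2) / Nr,
    T.LRLGLE = sum(M * l^2 / g^2) / Nr,
    T.LoGLRU = sum(M / g^2) / Nr,
    T.RLNU   = sum(colSums(M)^2) / Nr,
    T.RP     = Nr / R$n_pixels,
    T.SRE    = sum(M / l^2) / Nr,
    T.SRHGLE = sum(M * g^2 / l^2) / Nr,
    T.SRLGLE = sum(M / (g^2 * l^2)) / Nr
  )
}
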