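#' Grey-level co-occurrence matrix
#'
#' Counts symmetric co-occurrences of quantized grey levels in pixel pairs at
#' the given offset distance, separately per direction; pairs with either
#' pixel outside the ROI mask are skipped. The per-direction matrices are
#' averaged element-wise and normalized to sum 1. The four in-plane
#' neighbour directions (0,1), (1,0), (1,1), (1,-1) at distance 1 are the
#' default, matching 2-D direction averaging.
#'
#' @param q a [quantize]d ROI.
#' @param distance offset distance in pixels (default 1).
#' @param directions list of integer `(drow, dcol)` offsets.
#' @return An object of class `glcm`: `matrix` (G x G, sums to 1, symmetric),
#'   `n_levels`, `distance`, `directions`, `normalized`.
#' @export
compute_glcm <- function(q, distance = 1L,
                         directions = list(c(0L, 1L), c(1L, 0L),
                                           c(1L, 1L), c(1L, -1L))) {
  stopifnot(inherits(q, "quantized_roi"), distance >= 1)
  G <- q$n_levels
  lev <- q$levels
  acc <- matrix(0, G, G)
  n_used <- 0L
  for (d in directions) {
    co <- glcm_direction_counts(lev, G, d[1] * distance, d[2] * distance)
    if (sum(co) > 0) n_used <- n_used + 1L
    acc <- acc + co
  }
  if (sum(acc) == 0)
    stop("ROI has no valid co-occurrence pair in any direction")
  P <- acc / length(directions)
  P <- P / sum(P)
  structure(list(matrix = P, n_levels = G, distance = as.integer(distance),
                 directions = directions, normalized = TRUE),
            class = "glcm")
}

# symmetric pair counts at one offset; level 0 marks out-of-mask pixels
glcm_direction_counts <- function(lev, G, dr, dc) {
  nr <- nrow(lev); nc <- ncol(lev)
  if (abs(dr) >= nr || abs(dc) >= nc) return(matrix(0, G, G))
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- lev[r1, c1, drop = FALSE]
  b <- lev[r1 + dr, c1 + dc, drop = FALSE]
  ok <- a > 0L & b > 0L
  if (!any(ok)) return(matrix(0, G, G))
  counts <- matrix(tabulate((a[ok] - 1L) * G + b[ok], G * G), G, G, byrow = TRUE)
  counts + t(counts)
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> %d x %d, distance %d, %d direction(s), sum = %.6f\n",
              x$n_levels, x$n_levels, x$distance, length(x$directions),
              sum(x$matrix)))
  invisible(x)
}

#' Haralick-style GLCM texture features
#'
#' The 21 second-order co-occurrence features: autocorrelation, cluster
#' prominence/shade/tendency, contrast, correlation, difference entropy,
#' dissimilarity, energy (angular second moment), entropy, homogeneity 1 and
#' 2, informational measures of correlation 1 and 2, inverse difference
#' moment normalised, inverse difference normalised, inverse variance,
#' maximum probability, sum average, sum entropy and sum variance.
#' Logarithms are base 2 with the convention 0*log(0) = 0. Sum variance is
#' centred on the sum entropy, following Haralick's original compilation.
#' Degenerate inputs with zero marginal variance (all mass in one level)
#' return 0 for correlation and the informational measures, with a warning.
#'
#' @param P a normalized [compute_glcm] result (or a plain normalized
#'   square matrix).
#' @return Named numeric vector of length 21 (`T.Aut` .. `T.SV`).
#' @export
glcm_features <- function(P) {
  if (inherits(P, "glcm")) P <- P$matrix
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM must be normalized to sum 1")
  G <- nrow(P)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(G) * px); muy <- sum(seq_len(G) * py)
  sdx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(G) - muy)^2 * py))

  # diagonal-band and anti-diagonal-band marginals
  pxmy <- vapply(0:(G - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  kxpy <- 2:(2 * G)
  pxpy <- vapply(kxpy, function(k) sum(P[i + j == k]), numeric(1))

  xlog2 <- function(z) ifelse(z > 0, log2(z), 0)
  HXY <- -sum(P * xlog2(P))
  HX <- -sum(px * xlog2(px)); HY <- -sum(py * xlog2(py))
  pxpy_prod <- outer(px, py)
  HXY1 <- -sum(P * xlog2(pxpy_prod))
  HXY2 <- -sum(pxpy_prod * xlog2(pxpy_prod))

  degenerate <- sdx == 0 || sdy == 0
  if (degenerate)
    warning("GLCM has zero marginal variance; correlation and informational ",
            "measures set to 0")
  corr <- if (degenerate) 0 else (sum(i * j * P) - mux * muy) / (sdx * sdy)
  imc1 <- if (degenerate || max(HX, HY) == 0) 0 else (HXY - HXY1) / max(HX, HY)
  imc2 <- if (degenerate) 0 else sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))

  se <- -sum(pxpy * xlog2(pxpy))
  c(
    T.Aut  = sum(i * j * P),
    T.Clp  = sum((i + j - mux - muy)^4 * P),
    T.Cls  = sum((i + j - mux - muy)^3 * P),
    T.Clt  = sum((i + j - mux - muy)^2 * P),
    T.Con  = sum((i - j)^2 * P),
    T.Cor  = corr,
    T.Den  = -sum(pxmy * xlog2(pxmy)),
    T.Dis  = sum(abs(i - j) * P),
    T.En   = sum(P^2),
    T.Ent  = HXY,
    T.Hom1 = sum(P / (1 + abs(i - j))),
    T.Hom2 = sum(P / (1 + (i - j)^2)),
    T.IMC1 = imc1,
    T.IMC2 = imc2,
    T.IDMN = sum(P / (1 + (i - j)^2 / G^2)),
    T.IDN  = sum(P / (1 + abs(i - j) / G)),
    T.IV   = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    T.MP   = max(P),
    T.SA   = sum(kxpy * pxpy),
    T.SE   = se,
    T.SV   = sum((kxpy - se)^2 * pxpy)
  )
}
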