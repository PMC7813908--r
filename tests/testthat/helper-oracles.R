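# Independent brute-force oracles: plain loops straight from the textbook
# definitions, deliberately sharing no code with the package internals.

oracle_dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

# GLCM by exhaustive pixel-pair enumeration
naive_glcm <- function(lev, G, distance = 1L, directions = oracle_dirs) {
  nr <- nrow(lev); nc <- ncol(lev)
  acc <- matrix(0, G, G)
  for (d in directions) {
    co <- matrix(0, G, G)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + d[1] * distance; c2 <- c + d[2] * distance
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      a <- lev[r, c]; b <- lev[r2, c2]
      if (a > 0 && b > 0) {
        co[a, b] <- co[a, b] + 1
        co[b, a] <- co[b, a] + 1
      }
    }
    acc <- acc + co
  }
  P <- acc / length(directions)
  P / sum(P)
}

# GLRLM by walking maximal runs pixel by pixel
naive_glrlm_direction <- function(lev, G, d) {
  nr <- nrow(lev); nc <- ncol(lev)
  runs <- list()
  inb <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    g <- lev[r, c]
    if (g == 0) next
    pr <- r - d[1]; pc <- c - d[2]
    if (inb(pr, pc) && lev[pr, pc] == g) next # not a run start
    len <- 1L
    nr_ <- r + d[1]; nc_ <- c + d[2]
    while (inb(nr_, nc_) && lev[nr_, nc_] == g) {
      len <- len + 1L
      nr_ <- nr_ + d[1]; nc_ <- nc_ + d[2]
    }
    runs[[length(runs) + 1L]] <- c(g, len)
  }
  rmax <- if (length(runs)) max(vapply(runs, `[`, integer(1), 2L)) else 1L
  M <- matrix(0, G, rmax)
  for (rn in runs) M[rn[1], rn[2]] <- M[rn[1], rn[2]] + 1
  M
}

naive_glrlm <- function(lev, G, directions = oracle_dirs) {
  mats <- lapply(directions, function(d) naive_glrlm_direction(lev, G, d))
  rmax <- max(vapply(mats, ncol, integer(1)))
  mats <- lapply(mats, function(m)
    if (ncol(m) < rmax) cbind(m, matrix(0, G, rmax - ncol(m))) else m)
  Reduce(`+`, mats) / length(mats)
}

# Haralick features by explicit double loops
naive_glcm_features <- function(P) {
  G <- nrow(P)
  l2 <- function(z) if (z > 0) log2(z) else 0
  px <- numeric(G); py <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:G) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sdx <- sqrt(sum(sapply(1:G, function(i) (i - mux)^2 * px[i])))
  sdy <- sqrt(sum(sapply(1:G, function(j) (j - muy)^2 * py[j])))
  pxmy <- numeric(G); pxpy <- numeric(2 * G - 1)
  for (i in 1:G) for (j in 1:G) {
    pxmy[abs(i - j) + 1] <- pxmy[abs(i - j) + 1] + P[i, j]
    pxpy[i + j - 1] <- pxpy[i + j - 1] + P[i, j]
  }
  f <- c(aut = 0, clp = 0, cls = 0, clt = 0, con = 0, dis = 0, en = 0,
         ent = 0, hom1 = 0, hom2 = 0, idmn = 0, idn = 0, iv = 0)
  HXY1 <- 0; HXY2 <- 0
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    f["aut"] <- f["aut"] + i * j * p
    f["clp"] <- f["clp"] + (i + j - mux - muy)^4 * p
    f["cls"] <- f["cls"] + (i + j - mux - muy)^3 * p
    f["clt"] <- f["clt"] + (i + j - mux - muy)^2 * p
    f["con"] <- f["con"] + (i - j)^2 * p
    f["dis"] <- f["dis"] + abs(i - j) * p
    f["en"] <- f["en"] + p^2
    f["ent"] <- f["ent"] - p * l2(p)
    f["hom1"] <- f["hom1"] + p / (1 + abs(i - j))
    f["hom2"] <- f["hom2"] + p / (1 + (i - j)^2)
    f["idmn"] <- f["idmn"] + p / (1 + (i - j)^2 / G^2)
    f["idn"] <- f["idn"] + p / (1 + abs(i - j) / G)
    if (i != j) f["iv"] <- f["iv"] + p / (i - j)^2
    HXY1 <- HXY1 - p * l2(px[i] * py[j])
    HXY2 <- HXY2 - px[i] * py[j] * l2(px[i] * py[j])
  }
  HX <- -sum(sapply(px, function(z) z * l2(z)))
  HY <- -sum(sapply(py, function(z) z * l2(z)))
  corr <- if (sdx == 0 || sdy == 0) 0 else
    (f[["aut"]] - mux * muy) / (sdx * sdy)
  imc1 <- if (sdx == 0 || sdy == 0 || max(HX, HY) == 0) 0 else
    (f[["ent"]] - HXY1) / max(HX, HY)
  imc2 <- if (sdx == 0 || sdy == 0) 0 else
    sqrt(max(0, 1 - exp(-2 * (HXY2 - f[["ent"]]))))
  den <- 0
  for (k in 0:(G - 1)) den <- den - pxmy[k + 1] * l2(pxmy[k + 1])
  sa <- 0; se <- 0
  for (k in 2:(2 * G)) {
    sa <- sa + k * pxpy[k - 1]
    se <- se - pxpy[k - 1] * l2(pxpy[k - 1])
  }
  sv <- 0
  for (k in 2:(2 * G)) sv <- sv + (k - se)^2 * pxpy[k - 1]
  c(T.Aut = f[["aut"]], T.Clp = f[["clp"]], T.Cls = f[["cls"]],
    T.Clt = f[["clt"]], T.Con = f[["con"]], T.Cor = unname(corr),
    T.Den = den, T.Dis = f[["dis"]], T.En = f[["en"]], T.Ent = f[["ent"]],
    T.Hom1 = f[["hom1"]], T.Hom2 = f[["hom2"]], T.IMC1 = unname(imc1),
    T.IMC2 = unname(imc2), T.IDMN = f[["idmn"]], T.IDN = f[["idn"]],
    T.IV = f[["iv"]], T.MP = max(P), T.SA = sa, T.SE = se, T.SV = sv)
}

# run-length features from first principles
naive_glrlm_features <- function(M, n_pixels) {
  G <- nrow(M); L <- ncol(M)
  Nr <- sum(M)
  s <- c(glnu = 0, hglre = 0, lre = 0, lrhgle = 0, lrlgle = 0, lglre = 0,
         rlnu = 0, sre = 0, srhgle = 0, srlgle = 0)
  for (g in 1:G) {
    rowsum <- sum(M[g, ])
    s["glnu"] <- s["glnu"] + rowsum^2
    for (l in 1:L) {
      m <- M[g, l]
      s["hglre"] <- s["hglre"] + m * g^2
      s["lre"] <- s["lre"] + m * l^2
      s["lrhgle"] <- s["lrhgle"] + m * g^2 * l^2
      s["lrlgle"] <- s["lrlgle"] + m * l^2 / g^2
      s["lglre"] <- s["lglre"] + m / g^2
      s["sre"] <- s["sre"] + m / l^2
      s["srhgle"] <- s["srhgle"] + m * g^2 / l^2
      s["srlgle"] <- s["srlgle"] + m / (g^2 * l^2)
    }
  }
  for (l in 1:L) s["rlnu"] <- s["rlnu"] + sum(M[, l])^2
  c(T.GLNU = s[["glnu"]] / Nr, T.HGLRU = s[["hglre"]] / Nr,
    T.LRE = s[["lre"]] / Nr, T.LRHGLE = s[["lrhgle"]] / Nr,
    T.LRLGLE = s[["lrlgle"]] / Nr, T.LoGLRU = s[["lglre"]] / Nr,
    T.RLNU = s[["rlnu"]] / Nr, T.RP = Nr / n_pixels,
    T.SRE = s[["sre"]] / Nr, T.SRHGLE = s[["srhgle"]] / Nr,
    T.SRLGLE = s[["srlgle"]] / Nr)
}

naive_first_order <- function(x, bins = 16L) {
  n <- length(x)
  mu <- sum(x) / n
  vr <- sum((x - mu)^2) / n
  sdev <- sqrt(vr)
  lo <- min(x); hi <- max(x)
  if (hi > lo) {
    idx <- pmin(floor((x - lo) / (hi - lo) * bins) + 1, bins)
    p <- as.numeric(table(factor(idx, levels = 1:bins))) / n
  } else p <- 1
  ent <- -sum(sapply(p, function(z) if (z > 0) z * log2(z) else 0))
  xs <- sort(x)
  med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  c(S.En = sum(x^2), S.Ent = ent,
    S.Kur = if (sdev > 0) sum((x - mu)^4) / n / vr^2 else 0,
    S.Max = max(x), S.Mean = mu, S.MAD = sum(abs(x - mu)) / n,
    S.Med = med,
    S.Min = min(x), S.RMS = sqrt(sum(x^2) / n), S.Ran = hi - lo,
    S.Sk = if (sdev > 0) sum((x - mu)^3) / n / sdev^3 else 0,
    S.Std = sdev, S.Un = sum(p^2), S.Var = vr)
}

# CCC by direct substitution into the concordance formula
naive_ccc <- function(x, y) {
  n <- length(x)
  sx <- sqrt(sum((x - mean(x))^2) / n)
  sy <- sqrt(sum((y - mean(y))^2) / n)
  rho <- stats::cor(x, y)
  2 * rho * sx * sy / (sx^2 + sy^2 + (mean(x) - mean(y))^2)
}

# random small quantized ROI for oracle-equivalence sweeps
random_quantized_roi <- function(max_side = 8L, max_G = 4L) {
  nr <- sample(2:max_side, 1); nc <- sample(2:max_side, 1)
  G <- sample(2:max_G, 1)
  lev <- matrix(sample(1:G, nr * nc, replace = TRUE), nr, nc)
  mask <- matrix(stats::runif(nr * nc) < 0.8, nr, nc)
  if (sum(mask) < 4) mask[sample(nr * nc, 4)] <- TRUE
  lev[!mask] <- 0L
  structure(list(levels = lev, mask = mask, n_levels = G),
            class = "quantized_roi")
}

make_patch <- function(values, nr = NULL) {
  n <- length(values)
  if (is.null(nr)) nr <- 1L
  mask <- matrix(TRUE, nr, n / nr)
  texrep_patch(values, mask)
}

# build an roi_patch without going through extract_roi
texrep_patch <- function(values, mask) {
  p <- structure(list(values = as.numeric(values), mask = mask,
                      grid_shape = dim(mask), normalized = FALSE),
                 class = "roi_patch")
  p
}
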