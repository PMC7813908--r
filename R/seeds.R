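#' Derive a reproducible substream seed
#'
#' Every stochastic stage of the pipeline draws its own seed from one master
#' seed plus a stream label, so that e.g. the phantom texture, the noise
#' ladder and the retest jitter are independently reproducible.
#'
#' @param master integer master seed.
#' @param stream character label of the substream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(master) %% m
  for (ch in utf8ToInt(stream)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library functions stay pure in (inputs, seed).
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
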