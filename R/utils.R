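#' Derive a reproducible sub-seed for a named stage
#'
#' All stochastic stages of the package draw their random numbers from a
#' stream derived deterministically from one master seed and a stage label,
#' so each stage is reproducible in isolation and stages do not share state.
#' The derivation is a multiplicative hash of the label folded into the seed,
#' reduced modulo 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param seed master integer seed.
#' @param stage character stage label (e.g. `"simulate"`, `"rna_render"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  s <- (abs(as.numeric(seed)) %% m)
  as.integer((s * 48271 + h) %% (m - 1) + 1)
}

#' Evaluate code with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package internals never clobber a user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Spearman rank correlation with mid-ranked ties (thin wrapper, kept in one
# place so tie handling is uniform across modules).
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(NA_real_)
  stats::cor(x[ok], y[ok], method = "spearman")
}
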