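# Internal helpers: scoped RNG and reproducible per-axon seed derivation.

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive reproducible per-unit seeds from a top-level seed
#'
#' Counter-based scheme: the i-th derived seed is
#' `(48271 * ((seed + i) mod (2^31 - 1))) mod (2^31 - 1)`, i.e. one step of
#' the MINSTD multiplicative congruential generator applied to `seed + i`.
#' Seeds are therefore independent of the order in which units are
#' simulated, and each derived seed fits a 32-bit integer.
#'
#' @param seed top-level integer seed.
#' @param n number of seeds to derive.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(n), length(n) == 1L, n >= 0)
  m <- 2147483647
  s <- abs(as.numeric(seed)) %% m
  as.integer(vapply(seq_len(n),
                    function(i) (48271 * ((s + i) %% m)) %% m,
                    numeric(1)))
}

# single positive finite scalar
is_scalar_pos <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
}
is_scalar_nonneg <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0
}
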