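# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never perturbs user
# simulations.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministically fold a master seed with a stream of small integers into a
# new seed in [1, 2^31 - 2].  Used to give every scenario/repeat/arm its own
# reproducible RNG stream.
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  m <- 2147483647 # 2^31 - 1, prime
  for (k in ks) {
    h <- (h * 48271 + (as.numeric(k) %% m) + 11) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
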