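# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. Every exported generator routes its randomness through this.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Population (divide-by-n) standard deviation; the slide-wide CK threshold
# is defined on it.
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# Deterministic half-up rounding (base round() is banker's).
round_half_up <- function(x) {
  floor(x + 0.5)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}
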