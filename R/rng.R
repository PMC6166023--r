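# Seed plumbing. All stochastic operations take an explicit integer seed and
# run under a locally scoped RNG state so the caller's .Random.seed is never
# disturbed. Sub-streams (per subject, per trial, per frame) are derived
# deterministically from the parent seed so one cohort seed fixes everything.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# derive a child seed; keeps results in [0, 2^31 - 2]
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.double(k) * 1299721 + 1) %% 2147483647
  as.integer(s)
}
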