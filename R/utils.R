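# Evaluate code with a local RNG seed, restoring the caller's RNG state.
# Every stochastic function in the package funnels through this so that its
# output is a pure function of (arguments, seed).
with_seed_local <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.",
          class = "formateswitch_domain_error")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# stable ordinary-least-squares slope of y on x (used as the association
# statistic on log2 intensities vs the one-carbon availability index)
.ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc * xc)
}
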