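# shared fixtures: built in code, deterministic

fix_er <- local({
  cache <- new.env()
  function(n = 200, k = 10, seed = 7) {
    key <- paste(n, k, seed, sep = "_")
    if (is.null(cache[[key]])) cache[[key]] <- generate_network("er", n, mean_degree = k, seed = seed)
    cache[[key]]
  }
})

# the standard recovery law used throughout the experiments
fix_rec <- function() wt_weibull(2, 0.5)

# test grid of waiting-time laws covering all three families
fix_dist_grid <- function() {
  list(
    wt_weibull(0.5, 1), wt_weibull(1, 2), wt_weibull(2, 0.5),
    wt_beta(0.7), wt_beta(1), wt_beta(2.5),
    wt_exponential(0.3), wt_exponential(4)
  )
}

expect_close <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}
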