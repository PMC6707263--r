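test_that("closed-form evaluations match hand computations", {
  # Weibull shape 1 is exponential with rate 1/scale: constant hazard
  e <- wt_eval(wt_weibull(1, 2), 0)
  expect_equal(unlist(e[, c("density", "survival", "hazard")], use.names = FALSE),
               c(0.5, 1, 0.5))
  # Weibull(2, 0.5) at x = 0.5: psi = 4 e^-1, Psi = e^-1, omega = 4
  e <- wt_eval(wt_weibull(2, 0.5), 0.5)
  expect_equal(e$density, 4 * exp(-1), tolerance = 1e-12)
  expect_equal(e$survival, exp(-1), tolerance = 1e-12)
  expect_equal(e$hazard, 4, tolerance = 1e-12)
  # Beta(1, 1) is uniform on [0, 1)
  e <- wt_eval(wt_beta(1), 0.5)
  expect_equal(unlist(e[, c("density", "survival", "hazard")], use.names = FALSE),
               c(1, 0.5, 2))
  # beyond the support end: zero density/survival, infinite hazard sentinel
  e <- wt_eval(wt_beta(2), c(1, 1.5))
  expect_equal(e$density, c(0, 0))
  expect_equal(e$survival, c(0, 0))
  expect_true(all(is.infinite(e$hazard)))
})

test_that("domain and parameter errors are raised", {
  expect_error(wt_weibull(-1, 1), "shape")
  expect_error(wt_weibull(1, 0), "scale")
  expect_error(wt_beta(0), "gamma")
  expect_error(wt_exponential(-2), "rate")
  expect_error(wt_density(wt_beta(1), -0.1), "non-negative")
  expect_error(wt_quantile(wt_beta(1), 0), "0, 1")
  expect_error(wt_quantile(wt_weibull(1, 1), 1.2), "0, 1")
  expect_error(wt_laplace(wt_exponential(1), -1), "non-negative")
})

test_that("density = hazard * survival and normalization hold across the grid", {
  x <- c(1e-6, 0.05, 0.3, 0.9, 1.7, 4)
  for (d in fix_dist_grid()) {
    xs <- x[x < d$support_upper]
    psi <- wt_density(d, xs)
    prod <- wt_hazard(d, xs) * wt_survival(d, xs)
    expect_lt(max(abs(psi - prod) / psi), 1e-10)
    # survival: starts at 1, non-increasing, vanishes at the support end
    expect_identical(wt_survival(d, 0), 1)
    s <- wt_survival(d, seq(0, min(d$support_upper, 50), length.out = 200))
    expect_true(all(diff(s) <= 0))
    # unit mass
    up <- if (is.finite(d$support_upper)) d$support_upper else Inf
    total <- stats::integrate(function(u) wt_density(d, u), 0, up,
                              rel.tol = 1e-10, abs.tol = 1e-12)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("inverse-survival sampling solves Psi(x) = u", {
  expect_equal(wt_quantile(wt_weibull(1, 1), exp(-1)), 1, tolerance = 1e-12)
  expect_equal(wt_quantile(wt_beta(2), 0.25), 0.5, tolerance = 1e-12)
  for (d in fix_dist_grid()) {
    expect_identical(wt_quantile(d, 1), 0)
    u <- c(0.9, 0.5, 0.12, 1e-4)
    expect_close(wt_survival(d, wt_quantile(d, u)), u, 1e-10)
  }
})

test_that("sampled waiting times follow the target law (KS, seeded)", {
  set.seed(2024)
  # float collisions among 1e5 draws produce benign KS tie warnings
  x <- wt_sample(wt_weibull(1.7, 0.8), 1e5)
  expect_gt(suppressWarnings(
    stats::ks.test(x, stats::pweibull, shape = 1.7, scale = 0.8))$p.value, 1e-3)
  y <- wt_sample(wt_beta(1.5), 1e5)
  expect_gt(suppressWarnings(
    stats::ks.test(y, function(q) 1 - (1 - q)^1.5))$p.value, 1e-3)
  z <- wt_sample(wt_exponential(3), 1e5)
  expect_gt(suppressWarnings(
    stats::ks.test(z, stats::pexp, rate = 3))$p.value, 1e-3)
})

test_that("Weibull with shape 1 is pointwise the exponential law", {
  w <- wt_weibull(1, 0.4)
  e <- wt_exponential(2.5)
  x <- seq(0, 5, length.out = 101)
  expect_close(wt_density(w, x), wt_density(e, x), 1e-12)
  expect_close(wt_survival(w, x), wt_survival(e, x), 1e-12)
  expect_close(wt_hazard(w, x), wt_hazard(e, x), 1e-12)
})

test_that("Laplace transform matches closed forms", {
  expect_equal(wt_laplace(wt_exponential(1), 1), 0.5)
  for (d in fix_dist_grid()) expect_equal(wt_laplace(d, 0), 1, tolerance = 1e-8)
  # Weibull shape 2 scale 1: psi_hat(s) = 1 - (s sqrt(pi)/2) e^(s^2/4) erfc(s/2)
  erfc <- function(z) 2 * stats::pnorm(-z * sqrt(2))
  s <- c(0.5, 1, 2)
  closed <- 1 - (s * sqrt(pi) / 2) * exp(s^2 / 4) * erfc(s / 2)
  expect_close(wt_laplace(wt_weibull(2, 1), s), closed, 1e-8)
})

test_that("the mean equals the survival integral", {
  expect_equal(wt_mean(wt_weibull(1, 2)), 2)
  expect_equal(wt_mean(wt_weibull(2, 0.5)), 0.5 * gamma(1.5), tolerance = 1e-12)
  expect_equal(wt_mean(wt_weibull(2, 0.5)), 0.443113, tolerance = 1e-5)
  expect_equal(wt_mean(wt_beta(1)), 0.5)
  for (d in fix_dist_grid()) {
    up <- if (is.finite(d$support_upper)) d$support_upper else Inf
    quad <- stats::integrate(function(u) wt_survival(d, u), 0, up,
                             rel.tol = 1e-12, abs.tol = 1e-12)$value
    expect_equal(wt_mean(d), quad, tolerance = 1e-8)
  }
})

test_that("spec strings and config lists parse to the same objects", {
  expect_equal(wt_parse("weibull:2,0.5"), wt_weibull(2, 0.5))
  expect_equal(wt_parse("beta:1.5"), wt_beta(1.5))
  expect_equal(wt_parse("exp:3"), wt_exponential(3))
  expect_equal(wt_parse(list(family = "weibull", shape = 2, scale = 1)), wt_weibull(2, 1))
  expect_error(wt_parse("cauchy:1"), "unknown")
})
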