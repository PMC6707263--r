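test_that("effective recovery rate inverts the mean infectious period", {
  expect_equal(delta_eff(wt_exponential(3)), 3)
  expect_equal(delta_eff(wt_weibull(2, 0.5)), 1 / (0.5 * gamma(1.5)), tolerance = 1e-12)
  expect_equal(delta_eff(wt_weibull(2, 0.5)), 2.25676, tolerance = 1e-5)
  # sharply peaked recovery approaches the deterministic limit 1/T
  expect_equal(delta_eff(wt_weibull(50, 2)), 0.5, tolerance = 0.02)
})

test_that("type-II effective infection rate recovers closed forms", {
  expect_equal(lambda_eff_type2(wt_exponential(2), wt_exponential(4)), 0.5,
               tolerance = 1e-6)
  # eta == 1 for unit-rate exponential infection: lambda = int Psi_rec
  expect_equal(lambda_eff_type2(wt_weibull(1, 1), wt_weibull(2, 0.5)),
               0.443113, tolerance = 1e-5)
  expect_error(lambda_eff_type2(wt_exponential(1), wt_weibull(0.2, 50)),
               "resolve")
})

test_that("effective infection rate matches Monte-Carlo renewal counting", {
  # draw a recovery age, count infection renewals before it
  inf <- wt_weibull(2, 1); rec <- wt_weibull(2, 0.5)
  set.seed(55)
  n <- 2e4
  cnt <- vapply(wt_sample(rec, n), function(tt) {
    s <- 0; k <- 0L
    repeat {
      s <- s + wt_quantile(inf, stats::runif(1))
      if (s > tt) break
      k <- k + 1L
    }
    k
  }, integer(1))
  lam <- lambda_eff_type2(inf, rec)
  expect_lt(abs(lam - mean(cnt)), 3 * stats::sd(cnt) / sqrt(n))
})

test_that("constant infection hazard collapses the activation series", {
  b <- 2; rec <- wt_weibull(2, 0.5); d_eff <- delta_eff(rec)
  ot <- omega_theta(wt_exponential(b), rec)
  # Omega(tau) = b tau, theta' = 1/b, higher derivatives vanish
  expect_true(all(abs(ot$omega$omega - b * ot$omega$tau) <=
                    1e-6 + 1e-3 * ot$omega$omega))
  expect_equal(ot$theta_derivs[1], 1 / b, tolerance = 1e-12)
  expect_true(all(ot$theta_derivs[-1] == 0))
  expect_equal(ot$lambda_eff_star, b / d_eff, tolerance = 1e-12)
  # exact Markovian equivalence: lambda_eff equals lambda_eff_star
  expect_equal(lambda_eff_type2(wt_exponential(b), rec), ot$lambda_eff_star,
               tolerance = 1e-6)
})

test_that("lambda_eff_star equals the age-zero hazard over delta_eff", {
  cases <- list(
    list(wt_beta(1.5), wt_weibull(2, 0.5)),
    list(wt_exponential(0.7), wt_exponential(2)),
    list(wt_weibull(1, 0.8), wt_weibull(4, 0.5)),
    list(wt_beta(0.8), wt_exponential(1))
  )
  for (cs in cases) {
    ot <- omega_theta(cs[[1]], cs[[2]])
    expect_equal(ot$lambda_eff_star,
                 wt_hazard(cs[[1]], 0) / delta_eff(cs[[2]]),
                 tolerance = 1e-10)
  }
  # the worked number: gamma = 1.5 with the standard recovery law
  ot <- omega_theta(wt_beta(1.5), wt_weibull(2, 0.5))
  expect_equal(ot$lambda_eff_star, 0.66467, tolerance = 1e-4)
  # non-smooth laws are refused rather than silently mis-expanded
  expect_error(omega_theta(wt_weibull(0.5, 1), wt_weibull(2, 0.5)), "integer")
  # a hazard vanishing at age 0 (Weibull shape 2) has no invertible series
  expect_error(omega_theta(wt_weibull(2, 1), wt_weibull(2, 0.5)), "ill-conditioned")
})

test_that("scaling the Beta hazard scales Omega and the inverse derivatives", {
  rec <- wt_weibull(2, 0.5)
  o1 <- omega_theta(wt_beta(1.5), rec)
  o2 <- omega_theta(wt_beta(3), rec)
  # Omega doubles pointwise; theta^(n)(0) shrinks by 2^n (inverse-function
  # scaling), which leaves the series a function of 2 * pressure only
  expect_close(o2$omega$omega / o1$omega$omega, 2, 1e-8)
  expect_close(o1$theta_derivs / o2$theta_derivs, 2^seq_along(o1$theta_derivs), 1e-6)
})

test_that("quenched mean-field fixed point solves the stationary equation", {
  g <- generate_network("regular", 100, k = 10, seed = 5)
  # below threshold: identically zero
  sub <- qmf_fixed_point(g, 0.05)
  expect_true(all(sub$infected == 0))
  # 10-regular at lambda = 0.2: closed form 1 - 1/(lambda k) = 0.5
  fit <- qmf_fixed_point(g, 0.2)
  expect_close(fit$infected, 0.5, 1e-10)
  expect_true(fit$converged)
  # residual of the defining equation
  A <- igraph::as_adjacency_matrix(g)
  x <- fit$infected
  expect_close(x, 0.2 * (1 - x) * as.numeric(A %*% x), 1e-10)
  td <- tidy(fit); gl <- glance(fit)
  expect_equal(nrow(td), 100)
  expect_equal(gl$network_density, 0.5, tolerance = 1e-10)
})

test_that("star-graph fixed point matches an independent two-variable solve", {
  g <- igraph::make_star(6, mode = "undirected")  # hub + 5 leaves
  lam <- 0.6
  fit <- qmf_fixed_point(g, lam)
  # reduced system: h = 5 lam l (1-h), l = lam h (1-l); solve for h by
  # high-precision root finding on the scalar composition
  f <- function(h) {
    l <- lam * h / (1 + lam * h)
    x <- 5 * lam * l
    x / (1 + x) - h
  }
  h <- stats::uniroot(f, c(1e-6, 1 - 1e-6), tol = 1e-15)$root
  l <- lam * h / (1 + lam * h)
  expect_equal(fit$infected[1], h, tolerance = 1e-10)
  expect_close(fit$infected[-1], l, 1e-10)
})

test_that("the type-I series reduces to the QMF solution for constant hazard", {
  g <- generate_network("regular", 100, k = 10, seed = 5)
  rec <- wt_weibull(2, 0.5)
  b <- 1.2
  ot <- omega_theta(wt_exponential(b), rec)
  fit1 <- type1_fixed_point(g, wt_exponential(b), rec)
  fit2 <- qmf_fixed_point(g, ot$lambda_eff_star)
  expect_close(fit1$infected, fit2$infected, 1e-10)
  expect_false(fit1$partial)
})

test_that("the type-I series is truncation-stable at high density", {
  g <- generate_network("regular", 100, k = 10, seed = 5)
  rec <- wt_weibull(2, 0.5)
  d8 <- type1_fixed_point(g, wt_beta(2), rec, n_max = 8)$network_density
  d10 <- type1_fixed_point(g, wt_beta(2), rec, n_max = 10)$network_density
  d12 <- type1_fixed_point(g, wt_beta(2), rec, n_max = 12)$network_density
  expect_gt(d8, 0.5)                     # genuinely supercritical case
  expect_lt(abs(d8 - d12), 1e-5)
  expect_lte(abs(d10 - d12), abs(d8 - d12) + 1e-12)  # asymptotic shrinkage
})

test_that("the type-I/QMF gap closes as the Beta hazard grows", {
  g <- generate_network("regular", 100, k = 10, seed = 5)
  rec <- wt_weibull(2, 0.5)
  gaps <- sapply(c(1.5, 2, 2.5), function(gam) {
    t1 <- type1_fixed_point(g, wt_beta(gam), rec)
    q <- qmf_fixed_point(g, t1$lambda_eff_star)
    abs(t1$network_density - q$network_density)
  })
  expect_true(all(diff(gaps) < 0))
  # at low pressure the asymptotic expansion cannot reach its tolerance
  # anywhere on the (homogeneous) graph and the solver says so
  expect_error(type1_fixed_point(g, wt_beta(0.8), rec), "inapplicable")
})

test_that("subcritical type-I series returns the zero solution", {
  g <- generate_network("regular", 100, k = 10, seed = 5)
  fit <- type1_fixed_point(g, wt_beta(0.05), wt_weibull(2, 0.5))
  expect_true(all(fit$infected == 0))
})

test_that("the Markovian reference preserves the effective rates", {
  ref <- markovian_reference(1, 0.5)
  expect_equal(ref$infection$params$rate, 0.5)
  expect_equal(ref$recovery$params$rate, 1)
  ref <- markovian_reference(2.2568, 0.18)
  expect_equal(lambda_eff_type2(ref$infection, ref$recovery), 0.18,
               tolerance = 1e-8)
})

test_that("scale inversion round-trips the effective rate", {
  rec <- wt_weibull(2, 0.5)
  for (target in c(0.1, 0.25)) {
    b <- beta_for_lambda(target, 2, rec)
    expect_equal(lambda_eff_type2(wt_weibull(2, b), rec), target,
                 tolerance = 1e-6)
  }
})

test_that("effective_rates bundles the pieces consistently", {
  er <- effective_rates(wt_beta(1.5), wt_weibull(2, 0.5))
  expect_s3_class(er, "effective_rates")
  expect_equal(er$delta_eff, delta_eff(wt_weibull(2, 0.5)))
  expect_equal(er$lambda_eff_star, 1.5 / er$delta_eff, tolerance = 1e-10)
  expect_length(er$theta_derivs, 10)
})
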