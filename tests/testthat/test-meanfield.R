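test_that("the age grid covers the recovery tail and finite supports", {
  g <- age_grid(0.02, fix_rec())
  expect_lt(wt_survival(fix_rec(), g$tau_max), 1e-8)
  g2 <- age_grid(0.02, wt_exponential(5), infection = wt_beta(2))
  expect_gte(g2$tau_max, 1)
  expect_equal(g2$centers[1], 0.01)
})

test_that("no infected mass means no epidemic, and probability is conserved", {
  g <- fix_er(10, 3, seed = 1)
  mf <- mean_field_sis(g, "type2", wt_exponential(1), wt_exponential(1),
                       rho0 = 0, t_max = 5, delta = 0.02)
  expect_true(all(mf$infected == 0))
  # per-node conservation after many steps, audited to 1e-9
  mf <- mean_field_sis(g, "type1", wt_weibull(2, 1), fix_rec(),
                       rho0 = 0.2, t_max = 20, delta = 0.02)
  fs <- attr(mf, "final_state")
  tot <- rowSums(fs$infected) + rowSums(fs$susceptible)
  expect_close(tot, 1, 1e-9)
})

test_that("a malformed initial condition is rejected", {
  g <- fix_er(10, 3, seed = 1)
  grid <- age_grid(0.02, wt_exponential(1))
  MI <- matrix(0.7, 10, grid$n_bins)  # sums far above 1
  expect_error(
    mean_field_sis(g, "type2", wt_exponential(1), wt_exponential(1),
                   t_max = 1, delta = 0.02,
                   init = list(infected = MI, susceptible = MI)),
    "sum to 1"
  )
})

test_that("type-I pressure equals a brute-force min-age quadrature", {
  om <- wt_hazard(wt_weibull(2, 1), c(0.05, 0.15, 0.25))   # 3-cell toy grid
  G <- rbind(c(0.2, 0.1, 0), c(0.05, 0.3, 0.02))
  brute <- matrix(0, nrow(G), 3)
  for (i in seq_len(nrow(G))) for (b in 1:3) for (bp in 1:3) {
    brute[i, b] <- brute[i, b] + om[min(b, bp)] * G[i, bp]
  }
  expect_equal(nmsis:::type1_pressure(G, om), brute, tolerance = 1e-14)
})

test_that("both mechanisms coincide for constant infection hazard", {
  g <- fix_er(60, 6, seed = 8)
  args <- list(g, infection = wt_exponential(0.8), recovery = fix_rec(),
               rho0 = 0.05, t_max = 6, delta = 0.02)
  mf1 <- do.call(mean_field_sis, c(args, mechanism = "type1"))
  mf2 <- do.call(mean_field_sis, c(args, mechanism = "type2"))
  # type-II uses the renewal intensity (constant up to quadrature error)
  expect_close(mf1$infected, mf2$infected, 1e-4)
})

test_that("the Markovian limit reproduces the quenched mean-field ODE", {
  skip_if_not_installed("deSolve")
  g <- fix_er(200, 8, seed = 10)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  b <- 0.12; d <- 1
  rhs <- function(t, y, parms) {
    list(-d * y + b * (1 - y) * as.numeric(A %*% y))
  }
  times <- seq(0, 8, by = 0.5)
  y0 <- rep(0.05, 200)
  ode <- deSolve::ode(y0, times, rhs, NULL, method = "ode45")
  I_ode <- rowMeans(ode[, -1])
  errs <- sapply(c(0.04, 0.02), function(dl) {
    mf <- mean_field_sis(g, "type2", wt_exponential(b), wt_exponential(d),
                         rho0 = 0.05, t_max = 8, delta = dl, sample_times = times)
    max(abs(mf$infected - I_ode))
  })
  expect_lt(errs[2], 0.01)          # small at the working resolution
  expect_lt(errs[2], errs[1])       # and shrinking with the step
})

test_that("the late-time field satisfies the stationary age equations", {
  g <- generate_network("regular", 50, k = 8, seed = 3)
  rec <- fix_rec()
  mf <- mean_field_sis(g, "type2", wt_exponential(1), rec,
                       rho0 = 0.2, t_max = 30, delta = 0.01)
  fs <- attr(mf, "final_state")
  grid <- attr(mf, "grid")
  # stationary infected density profile decays with the recovery hazard:
  # d log I(tau) / d tau = -omega_rec(tau)
  m <- colMeans(fs$infected)
  keep <- 2:(grid$n_bins %/% 2)
  dlog <- diff(log(m))[keep] / grid$delta
  om <- wt_hazard(rec, (grid$centers[keep] + grid$centers[keep + 1]) / 2)
  expect_lt(max(abs(dlog + om)), 0.05)
  # equal boundary inflows: newborn infected and susceptible mass agree to
  # the half-step exposure correction (O(delta) in the cell masses)
  bi <- mean(fs$infected[, 1]); bs <- mean(fs$susceptible[, 1])
  expect_lt(abs(bi - bs) / bs, 0.05)
})

test_that("transient time measures plateau onset", {
  traj <- tibble::tibble(time = seq(0, 20, by = 0.01), infected = 0.4)
  expect_equal(transient_time(traj, 1e-3, window = 5), 0)
  decay <- tibble::tibble(time = seq(0, 20, by = 0.01),
                          infected = exp(-seq(0, 20, by = 0.01)))
  expect_equal(transient_time(decay, 1e-3, window = 8), log(1e3), tolerance = 0.5)
  ramp <- tibble::tibble(time = seq(0, 20, by = 0.1),
                         infected = seq(0, 20, by = 0.1) * 0.01)
  expect_identical(transient_time(ramp, 1e-3, window = 8), Inf)
  expect_error(transient_time(decay, 1e-3, window = 15), "span")
})

test_that("heavier-tailed infection shapes prolong the transient", {
  g <- fix_er(200, 10, seed = 14)
  tt <- sapply(c(1, 2, 4), function(a) {
    mf <- mean_field_sis(g, "type1", wt_weibull(a, 1), fix_rec(),
                         rho0 = 0.01, t_max = 30, delta = 0.04,
                         sample_times = seq(0, 30, by = 0.25))
    transient_time(mf, epsilon = 1e-3, window = 5)
  })
  expect_true(all(diff(tt) > 0))
})
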