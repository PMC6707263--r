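#' Effective recovery rate
#'
#' The reciprocal mean infectious period,
#' \eqn{\delta_{\mathrm{eff}} = 1/\int_0^\infty \Psi_{\mathrm{rec}}(\tau)
#' d\tau}: the constant recovery rate of the Markovian process whose mean
#' infectious period matches the non-Markovian one.
#'
#' @param recovery A [wt_dist][wt_weibull] object (the recovery law).
#' @return A positive scalar (per unit time).
#' @export
delta_eff <- function(recovery) {
  1 / wt_mean(check_wt(recovery))
}

#' Effective infection rate under type-II activation
#'
#' The expected number of transmission events along one active edge over an
#' infectious period,
#' \eqn{\lambda_{\mathrm{eff}} = \int_0^\infty \eta(\tau)
#' \Psi_{\mathrm{rec}}(\tau) d\tau},
#' where \eqn{\eta} is the renewal intensity of the infection law. For
#' type-II activation the stationary state of the non-Markovian process
#' coincides with that of a Markovian process with rates
#' (\eqn{\lambda_{\mathrm{eff}} \delta_{\mathrm{eff}}},
#' \eqn{\delta_{\mathrm{eff}}}); this function computes the decisive number.
#'
#' The integral is evaluated in Riemann–Stieltjes form against the renewal
#' function (\eqn{\int \Psi_{\mathrm{rec}} dM}) on a grid truncated where
#' \eqn{\Psi_{\mathrm{rec}} < 10^{-9}}, with one Richardson extrapolation
#' step over the grid spacing.
#'
#' @param infection,recovery [wt_dist][wt_weibull] objects.
#' @param n_grid Number of grid cells at the coarse level; by default
#'   chosen so the step resolves both the recovery tail and the mean
#'   infection waiting time.
#' @param richardson Apply Richardson extrapolation (halved step).
#' @return The dimensionless effective infection rate.
#' @examples
#' lambda_eff_type2(wt_exponential(2), wt_exponential(4))  # 0.5
#' @export
lambda_eff_type2 <- function(infection, recovery, n_grid = NULL, richardson = TRUE) {
  check_wt(infection); check_wt(recovery)
  tau_max <- survival_tail_time(recovery, 1e-9)
  if (wt_survival(recovery, tau_max) > 1e-6) {
    stop("recovery survival not negligible at the grid end", call. = FALSE)
  }
  if (is.null(n_grid)) {
    n_grid <- max(3000L, ceiling(tau_max / (0.05 * wt_mean(infection))))
  }
  if (n_grid > 5e4) {
    stop("recovery tail too long to resolve the infection law on the ",
         "renewal grid", call. = FALSE)
  }
  lam <- function(n) {
    delta <- tau_max / n
    M <- renewal_mass(infection, delta, n)
    centers <- (seq_len(n) - 0.5) * delta
    sum(wt_survival(recovery, centers) * diff(M))
  }
  l1 <- lam(n_grid)
  if (!richardson) return(l1)
  l2 <- lam(2L * n_grid)
  (4 * l2 - l1) / 3
}

# time at which the survival function of `dist` drops below `tol`
survival_tail_time <- function(dist, tol) {
  p <- dist$params
  switch(dist$family,
    weibull = p$scale * log(1 / tol)^(1 / p$shape),
    exponential = log(1 / tol) / p$rate,
    beta_sigma1 = 1
  )
}

#' Scale parameter of the infection law matching a target effective rate
#'
#' Solves \eqn{\lambda_{\mathrm{eff}}(\beta_I) = \lambda} for the Weibull
#' scale \eqn{\beta_I} at fixed shape, by monotone root bracketing
#' (\eqn{\lambda_{\mathrm{eff}}} is decreasing in \eqn{\beta_I}). This is
#' how steady-state sweeps are parameterized: pick the effective rate,
#' derive the microscopic scale.
#'
#' @param lambda Target effective infection rate.
#' @param shape Weibull shape of the infection law, held fixed.
#' @param recovery Recovery [wt_dist][wt_weibull].
#' @param tol Root tolerance on `lambda`.
#' @return The Weibull scale \eqn{\beta_I}.
#' @export
beta_for_lambda <- function(lambda, shape, recovery, tol = 1e-8) {
  stopifnot(lambda > 0)
  f <- function(b) lambda_eff_type2(wt_weibull(shape, b), recovery) - lambda
  # bracket around the mean-matched guess lambda ~ mean_rec / mean_inf,
  # expanding geometrically (lambda_eff is decreasing in the scale)
  guess <- wt_mean(recovery) / (lambda * gamma(1 + 1 / shape))
  lo <- guess; hi <- guess
  for (i in 1:40) { if (f(lo) > 0) break; lo <- lo / 3 }
  for (i in 1:40) { if (f(hi) < 0) break; hi <- hi * 3 }
  if (f(lo) <= 0 || f(hi) >= 0) stop("could not bracket the target rate", call. = FALSE)
  r <- stats::uniroot(f, interval = c(lo, hi), tol = 1e-12)
  if (abs(r$f.root) > tol) {
    warning("lambda residual ", signif(r$f.root, 3), " above tolerance")
  }
  r$root
}

#' Age-integrated activation function and its inverse-function derivatives
#'
#' For type-I activation the stationary state obeys a series in the inverse
#' neighborhood infection pressure, whose coefficients are the derivatives
#' at 0 of \eqn{\vartheta}, the inverse of
#' \deqn{\Omega(\tau) = \delta_{\mathrm{eff}} \int_0^\tau \int_0^{+\infty}
#'  \omega_{\mathrm{inf}}[\min(\tau',\tau'')] \Psi_{\mathrm{rec}}(\tau')
#'  d\tau' d\tau''.}
#' The Taylor coefficients of \eqn{\Omega} at 0 are computed in closed form
#' (writing \eqn{\Omega' = \delta_{\mathrm{eff}} g} with
#' \eqn{g' (u) = \omega_{\mathrm{inf}}'(u) \int_u^\infty \Psi_{\mathrm{rec}}},
#' all derivatives at 0 reduce to hazard derivatives of the infection law
#' and density derivatives of the recovery law), and
#' \eqn{\vartheta^{(n)}(0)} follows by power-series reversion. This requires
#' both laws to be smooth at 0: Beta(1, gamma) or exponential or
#' integer-shape Weibull infection, and exponential, Beta or integer-shape
#' Weibull recovery.
#'
#' \eqn{\lambda^*_{\mathrm{eff}} = 1/[\delta_{\mathrm{eff}}
#' \vartheta^{(1)}(0)]} equals
#' \eqn{\omega_{\mathrm{inf}}(0)/\delta_{\mathrm{eff}}}; with constant
#' infection hazard all higher \eqn{\vartheta^{(n)}(0)} vanish and
#' \eqn{\lambda_{\mathrm{eff}} = \lambda^*_{\mathrm{eff}}} (the exact
#' Markovian-equivalence case).
#'
#' @param infection,recovery [wt_dist][wt_weibull] objects.
#' @param n_max Series truncation order (at most 12).
#' @param n_grid Cells for the returned \eqn{\Omega} curve.
#' @return A list with `omega` (tibble `tau`, `omega` on cell centers),
#'   `omega_coefs` (Taylor coefficients of \eqn{\Omega} at 0),
#'   `theta_derivs` (\eqn{\vartheta^{(n)}(0)}, n = 1..n_max),
#'   `lambda_eff_star` and `delta_eff`.
#' @export
omega_theta <- function(infection, recovery, n_max = 10L, n_grid = 400L) {
  check_wt(infection); check_wt(recovery)
  stopifnot(n_max >= 1, n_max <= 12)
  d_eff <- delta_eff(recovery)
  mean_rec <- 1 / d_eff

  # Omega curve on cell centers (descriptive output; hazards capped just
  # inside a finite support end)
  tau_max <- min(survival_tail_time(recovery, 1e-9) * 2,
                 if (is.finite(infection$support_upper)) infection$support_upper else Inf)
  delta <- tau_max / n_grid
  centers <- (seq_len(n_grid) - 0.5) * delta
  cap <- if (is.finite(infection$support_upper)) infection$support_upper - delta / 2 else Inf
  om <- wt_hazard(infection, pmin(centers, cap))
  Psi <- wt_survival(recovery, centers)
  # midpoint cumulative integrals evaluated at the cell centers themselves
  mid_cum <- function(v) cumsum(v * delta) - v * delta / 2
  inner_cum <- mid_cum(om * Psi)                    # int_0^u omega Psi
  Hu <- mean_rec - mid_cum(Psi)                     # int_u^inf Psi
  g <- inner_cum + om * pmax(Hu, 0)
  omega_curve <- tibble::tibble(tau = centers, omega = d_eff * mid_cum(g))

  # Taylor coefficients a_n of Omega at 0: Omega'(0) = omega_inf(0);
  # Omega^(n)(0) = delta_eff * g^(n-1)(0),
  # g^(m)(0) = sum_j C(m-1, j) omega_inf^(j+1)(0) H^(m-1-j)(0),
  # H(0) = 1/delta_eff, H'(0) = -1, H^(m)(0) = psi_rec^(m-2)(0) for m >= 2.
  om_d <- hazard_derivs0(infection, n_max)          # omega^(k)(0), k = 0..n_max
  psi_d <- density_derivs0(recovery, n_max)         # psi_rec^(j)(0), j = 0..n_max
  H_d <- c(mean_rec, -1, psi_d[seq_len(n_max - 1)]) # H^(m)(0), m = 0..n_max
  a <- numeric(n_max)
  a[1] <- om_d[1]
  if (n_max >= 2) {
    for (n in 2:n_max) {
      m <- n - 1
      g_m <- sum(choose(m - 1, 0:(m - 1)) * om_d[2:(m + 1)] * H_d[m:1])
      a[n] <- d_eff * g_m / factorial(n)
    }
  }
  if (abs(a[1]) < 1e-12) stop("Omega'(0) vanishes; series reversion ill-conditioned", call. = FALSE)
  b <- revert_series(a)
  theta_derivs <- factorial(seq_len(n_max)) * b
  list(
    omega = omega_curve,
    omega_coefs = a,
    theta_derivs = theta_derivs,
    lambda_eff_star = 1 / (d_eff * theta_derivs[1]),
    delta_eff = d_eff
  )
}

# derivatives of the hazard at age 0 (orders 0..kmax); smooth families only
hazard_derivs0 <- function(dist, kmax) {
  p <- dist$params
  k <- 0:kmax
  switch(dist$family,
    exponential = c(p$rate, rep(0, kmax)),
    beta_sigma1 = p$gamma * factorial(k),
    weibull = {
      if (abs(p$shape - round(p$shape)) > 1e-12) {
        stop("the type-I series requires an integer Weibull shape ",
             "(hazard not smooth at 0 otherwise)", call. = FALSE)
      }
      a <- round(p$shape)
      out <- rep(0, kmax + 1)
      if (a - 1 <= kmax) out[a] <- (a / p$scale^a) * factorial(a - 1)
      out
    },
    stop("unsupported family", call. = FALSE)
  )
}

# derivatives of the density at age 0 (orders 0..jmax); smooth families only
density_derivs0 <- function(dist, jmax) {
  p <- dist$params
  switch(dist$family,
    exponential = p$rate * (-p$rate)^(0:jmax),
    beta_sigma1 = {
      out <- numeric(jmax + 1)
      for (j in 0:jmax) {
        out[j + 1] <- p$gamma * (-1)^j * prod(p$gamma - seq_len(j))
        if (j == 0) out[1] <- p$gamma
      }
      out
    },
    weibull = {
      if (abs(p$shape - round(p$shape)) > 1e-12) {
        stop("the type-I series requires an integer Weibull recovery shape ",
             "(density not smooth at 0 otherwise)", call. = FALSE)
      }
      a <- round(p$shape); b <- p$scale
      # psi(u) = (a/b^a) sum_m (-1)^m u^(a(m+1)-1) / (b^(a m) m!)
      out <- numeric(jmax + 1)
      m <- 0
      repeat {
        pow <- a * (m + 1) - 1
        if (pow > jmax) break
        out[pow + 1] <- (a / b^a) * (-1)^m / (b^(a * m) * factorial(m)) * factorial(pow)
        m <- m + 1
      }
      out
    },
    stop("unsupported family", call. = FALSE)
  )
}

# power-series reversion: given Omega(t) = sum a_n t^n (a_1 != 0), return b
# with theta(v) = sum b_n v^n and theta(Omega(t)) = t. Triangular solve on
# truncated series powers.
revert_series <- function(a) {
  n_max <- length(a)
  powers <- vector("list", n_max)
  powers[[1]] <- a
  if (n_max >= 2) {
    for (k in 2:n_max) {
      prev <- powers[[k - 1]]
      cur <- numeric(n_max)
      for (n in k:n_max) {
        i <- (k - 1):(n - 1)
        cur[n] <- sum(prev[i] * a[n - i])
      }
      powers[[k]] <- cur
    }
  }
  b <- numeric(n_max)
  b[1] <- 1 / a[1]
  if (n_max >= 2) {
    for (n in 2:n_max) {
      s <- sum(vapply(1:(n - 1), function(k) b[k] * powers[[k]][n], numeric(1)))
      b[n] <- -s / a[1]^n
    }
  }
  b
}

#' Effective rates of a non-Markovian SIS parameterization
#'
#' Bundles [delta_eff()], [lambda_eff_type2()] and, when both laws are
#' smooth at age 0, the type-I series quantities from [omega_theta()].
#'
#' @inheritParams omega_theta
#' @return A list of class `effective_rates` with elements `delta_eff`,
#'   `lambda_eff`, `lambda_eff_star` (or `NA` if the series is unavailable)
#'   and `theta_derivs`.
#' @export
effective_rates <- function(infection, recovery, n_max = 10L) {
  d <- delta_eff(recovery)
  l <- lambda_eff_type2(infection, recovery)
  ot <- tryCatch(omega_theta(infection, recovery, n_max = n_max), error = function(e) NULL)
  structure(
    list(
      delta_eff = d,
      lambda_eff = l,
      lambda_eff_star = if (is.null(ot)) NA_real_ else ot$lambda_eff_star,
      theta_derivs = if (is.null(ot)) NULL else ot$theta_derivs
    ),
    class = "effective_rates"
  )
}

#' @export
#' @method print effective_rates
print.effective_rates <- function(x, ...) {
  cat("<effective rates>\n")
  cat("  delta_eff      :", format(x$delta_eff), "\n")
  cat("  lambda_eff     :", format(x$lambda_eff), "\n")
  cat("  lambda_eff_star:", format(x$lambda_eff_star), "\n")
  if (!is.null(x$theta_derivs)) {
    cat("  theta_derivs   :", paste(signif(x$theta_derivs, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Markovian reference process for given effective rates
#'
#' Returns the exponential infection/recovery pair whose stationary state
#' the non-Markovian process is compared against: recovery rate
#' \eqn{\delta_{\mathrm{eff}}} and infection rate
#' \eqn{\lambda_{\mathrm{eff}} \delta_{\mathrm{eff}}}, so the Markovian
#' ratio reproduces \eqn{\lambda_{\mathrm{eff}}}.
#'
#' @param delta_eff Effective recovery rate.
#' @param lambda_eff Effective infection rate.
#' @return A list with `infection` and `recovery` [wt_dist][wt_weibull]
#'   objects.
#' @export
markovian_reference <- function(delta_eff, lambda_eff) {
  stopifnot(delta_eff > 0, lambda_eff > 0)
  list(
    infection = wt_exponential(lambda_eff * delta_eff),
    recovery = wt_exponential(delta_eff)
  )
}

#' Quenched mean-field stationary state
#'
#' Solves the stationary fixed point
#' \eqn{\tilde I_i = \lambda_{\mathrm{eff}} (1 - \tilde I_i)
#' \sum_j a_{ij} \tilde I_j}
#' by damped iteration (\eqn{\tilde I_i \leftarrow x/(1+x)} with
#' \eqn{x = \lambda \sum_j a_{ij} \tilde I_j}, damping 0.5, started at 0.5)
#' until the sup-norm change is below `tol`. Below the spectral threshold
#' (\eqn{\lambda \Lambda_{\max} \le 1}) the solution is identically zero and
#' is returned directly.
#'
#' @param graph An igraph object.
#' @param lambda Effective infection rate (dimensionless).
#' @param tol Sup-norm convergence tolerance.
#' @param max_iter Iteration cap.
#' @return An object of class `qmf_fit`: list with `infected` (per-node
#'   probabilities), `network_density`, `lambda`, `threshold`, `converged`,
#'   `iterations`.
#' @examples
#' g <- igraph::sample_k_regular(100, 10)
#' glance(qmf_fixed_point(g, 0.2))  # density 0.5 on a 10-regular graph
#' @export
qmf_fixed_point <- function(graph, lambda, tol = 1e-12, max_iter = 1e5) {
  stopifnot(lambda >= 0)
  n <- igraph::vcount(graph)
  lam_max <- leading_eigenvalue(graph)
  thr <- 1 / lam_max
  if (lambda * lam_max <= 1) {
    return(new_qmf_fit(numeric(n), lambda, thr, TRUE, 0L))
  }
  A <- methods::as(igraph::as_adjacency_matrix(graph, sparse = TRUE), "generalMatrix")
  x <- rep(0.5, n)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    p <- lambda * as.numeric(A %*% x)
    x_new <- 0.5 * x + 0.5 * p / (1 + p)
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      converged <- TRUE
      break
    }
    x <- x_new
  }
  new_qmf_fit(x, lambda, thr, converged, it)
}

new_qmf_fit <- function(infected, lambda, threshold, converged, iterations) {
  structure(
    list(infected = infected, network_density = mean(infected),
         lambda = lambda, threshold = threshold,
         converged = converged, iterations = iterations),
    class = "qmf_fit"
  )
}

#' @export
#' @method print qmf_fit
print.qmf_fit <- function(x, ...) {
  cat("<quenched mean-field stationary state>\n")
  cat("  lambda:", format(x$lambda), " threshold:", format(x$threshold), "\n")
  cat("  network density:", format(x$network_density),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @rdname qmf_fixed_point
#' @param x A `qmf_fit` object.
#' @param ... Unused.
#' @export
tidy.qmf_fit <- function(x, ...) {
  tibble::tibble(node = seq_along(x$infected) - 1L,
                 infected_prob = x$infected,
                 susceptible_prob = 1 - x$infected)
}

#' @rdname qmf_fixed_point
#' @export
glance.qmf_fit <- function(x, ...) {
  tibble::tibble(network_density = x$network_density, lambda = x$lambda,
                 threshold = x$threshold, converged = x$converged,
                 iterations = x$iterations)
}

#' Type-I stationary state from the inverse-function series
#'
#' Solves the type-I stationary relation
#' \deqn{\frac{1}{\tilde I_i} = \frac{1}{\tilde S_i} \sum_{n \ge 1}
#'   \delta_{\mathrm{eff}} \vartheta^{(n)}(0)
#'   \Big(\sum_j a_{ij} \tilde I_j\Big)^{-n}}
#' by damped fixed-point iteration. The expansion is asymptotic in the
#' inverse neighborhood infection pressure: its terms first shrink and then
#' grow, so each node's series is summed to its smallest term (optimal
#' asymptotic truncation, capped at `n_max`). Nodes whose smallest term is
#' still a material fraction of the sum — low pressure, small degree, low
#' density — are flagged and the fit is marked partial, mirroring the
#' regime where the expansion is known to break down. With constant
#' infection hazard all higher-order terms vanish and the solution
#' coincides with [qmf_fixed_point()] at \eqn{\lambda^*_{\mathrm{eff}}}.
#'
#' @param graph An igraph object.
#' @param infection,recovery [wt_dist][wt_weibull] objects (smooth at 0; see
#'   [omega_theta()]).
#' @param n_max Series truncation order.
#' @param tol Sup-norm convergence tolerance.
#' @param max_iter Iteration cap.
#' @return An object of class `type1_fit`: list with `infected`,
#'   `network_density`, `lambda_eff_star`, `theta_derivs`, `converged`,
#'   `flagged` (logical per node), `partial`, `iterations`.
#' @export
type1_fixed_point <- function(graph, infection, recovery, n_max = 10L,
                              tol = 1e-12, max_iter = 1e5) {
  ot <- omega_theta(infection, recovery, n_max = n_max)
  d_eff <- ot$delta_eff
  th <- ot$theta_derivs
  n <- igraph::vcount(graph)
  lam_max <- leading_eigenvalue(graph)
  if (ot$lambda_eff_star * lam_max <= 1) {
    fit <- new_qmf_fit(numeric(n), ot$lambda_eff_star, 1 / lam_max, TRUE, 0L)
    return(structure(
      list(infected = fit$infected, network_density = 0,
           lambda_eff_star = ot$lambda_eff_star, theta_derivs = th,
           converged = TRUE, flagged = rep(FALSE, n), partial = FALSE,
           iterations = 0L),
      class = "type1_fit"
    ))
  }
  A <- methods::as(igraph::as_adjacency_matrix(graph, sparse = TRUE), "generalMatrix")
  ns <- seq_len(n_max)
  coefs <- d_eff * th                      # delta_eff * theta^(n)(0)
  x <- rep(0.5, n)
  converged <- FALSE
  flagged <- rep(FALSE, n)
  it <- 0L
  series_sum <- function(k) {
    terms <- outer(1 / k, ns, `^`) * rep(coefs, each = length(k))  # n x n_max
    absT <- abs(terms)
    # optimal asymptotic truncation: per node, sum up to the smallest term
    usable <- matrix(TRUE, length(k), n_max)
    alive <- rep(TRUE, length(k))
    if (n_max >= 2) {
      for (j in 2:n_max) {
        alive <- alive & !(absT[, j] > absT[, j - 1])
        usable[, j] <- alive
      }
    }
    R <- rowSums(terms * usable)
    last_used <- absT[cbind(seq_along(k), rowSums(usable))]
    # material truncation error (> 1% of the sum) marks the node
    flag <- is.finite(k) & (last_used > 0.01 * abs(R) | !is.finite(R) | R <= 0)
    R[!is.finite(R) | R <= 0] <- coefs[1] / k[!is.finite(R) | R <= 0]
    list(R = R, flag = flag)
  }
  while (it < max_iter) {
    it <- it + 1L
    k <- as.numeric(A %*% x)
    k[k <= 0] <- NA                         # isolated/zero-pressure nodes
    ss <- series_sum(k)
    flagged <- ss$flag & is.finite(k)
    target <- 1 / (1 + ss$R)
    target[!is.finite(k)] <- 0
    x_new <- 0.5 * x + 0.5 * target
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      converged <- TRUE
      break
    }
    x <- x_new
  }
  if (all(flagged)) stop("series inapplicable at this density (all nodes flagged)", call. = FALSE)
  structure(
    list(infected = x, network_density = mean(x),
         lambda_eff_star = ot$lambda_eff_star, theta_derivs = th,
         converged = converged, flagged = flagged, partial = any(flagged),
         iterations = it),
    class = "type1_fit"
  )
}

#' @export
#' @method print type1_fit
print.type1_fit <- function(x, ...) {
  cat("<type-I series stationary state>\n")
  cat("  lambda_eff_star:", format(x$lambda_eff_star), "\n")
  cat("  network density:", format(x$network_density),
      if (x$partial) sprintf("(partial: %d node(s) flagged)", sum(x$flagged)) else "", "\n")
  invisible(x)
}

#' @rdname type1_fixed_point
#' @param x A `type1_fit` object.
#' @param ... Unused.
#' @export
tidy.type1_fit <- function(x, ...) {
  tibble::tibble(node = seq_along(x$infected) - 1L,
                 infected_prob = x$infected,
                 susceptible_prob = 1 - x$infected,
                 flagged = x$flagged)
}

#' @rdname type1_fixed_point
#' @export
glance.type1_fit <- function(x, ...) {
  tibble::tibble(network_density = x$network_density,
                 lambda_eff_star = x$lambda_eff_star,
                 converged = x$converged, partial = x$partial,
                 n_flagged = sum(x$flagged), iterations = x$iterations)
}
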