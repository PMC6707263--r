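#' Waiting-time distributions for epidemic events
#'
#' Constructors for the waiting-time laws used by the infection and recovery
#' processes. Each returns a `wt_dist` object carrying the density \eqn{\psi},
#' survival function \eqn{\Psi}, hazard \eqn{\omega = \psi/\Psi}, an
#' inverse-survival sampler and a Laplace transform.
#'
#' * `wt_weibull()`: density
#'   \eqn{\psi(x) = (\alpha/\beta)(x/\beta)^{\alpha-1} e^{-(x/\beta)^\alpha}}
#'   with shape \eqn{\alpha} and scale \eqn{\beta}. Shape 1 is the exponential
#'   law with rate \eqn{1/\beta}; shape < 1 gives a heavy tail and a hazard
#'   that diverges at the origin.
#' * `wt_beta()`: the Beta\eqn{(\sigma = 1, \gamma)} law
#'   \eqn{\psi(x) = \gamma (1-x)^{\gamma-1}} on \eqn{[0, 1)}, hazard
#'   \eqn{\gamma/(1-x)}. The first Beta parameter is fixed at 1, so the
#'   hazard at age 0 equals \eqn{\gamma} and every draw is below 1.
#' * `wt_exponential()`: constant hazard equal to `rate` (the Markovian
#'   special case; identical to `wt_weibull(1, 1/rate)`).
#'
#' @param shape,scale Positive Weibull shape and scale parameters.
#' @param gamma Positive shape parameter of the Beta(1, gamma) law.
#' @param rate Positive rate of the exponential law.
#' @return An object of class `wt_dist`.
#' @examples
#' d <- wt_weibull(2, 0.5)
#' wt_eval(d, c(0, 0.25, 0.5))
#' wt_mean(d)
#' @seealso [wt_eval()], [wt_sample()], [wt_laplace()], [wt_mean()]
#' @export
wt_weibull <- function(shape, scale) {
  stopifnot(is.numeric(shape), length(shape) == 1, is.numeric(scale), length(scale) == 1)
  if (!is.finite(shape) || shape <= 0) stop("`shape` must be a positive number", call. = FALSE)
  if (!is.finite(scale) || scale <= 0) stop("`scale` must be a positive number", call. = FALSE)
  new_wt_dist("weibull", list(shape = shape, scale = scale), support_upper = Inf)
}

#' @rdname wt_weibull
#' @export
wt_beta <- function(gamma) {
  stopifnot(is.numeric(gamma), length(gamma) == 1)
  if (!is.finite(gamma) || gamma <= 0) stop("`gamma` must be a positive number", call. = FALSE)
  new_wt_dist("beta_sigma1", list(gamma = gamma), support_upper = 1)
}

#' @rdname wt_weibull
#' @export
wt_exponential <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1)
  if (!is.finite(rate) || rate <= 0) stop("`rate` must be a positive number", call. = FALSE)
  new_wt_dist("exponential", list(rate = rate), support_upper = Inf)
}

new_wt_dist <- function(family, params, support_upper) {
  structure(
    list(family = family, params = params, support_upper = support_upper),
    class = "wt_dist"
  )
}

#' @export
#' @method print wt_dist
print.wt_dist <- function(x, ...) {
  pars <- paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", ")
  cat("<waiting-time distribution: ", x$family, " (", pars, ")>\n", sep = "")
  invisible(x)
}

#' @export
#' @method format wt_dist
format.wt_dist <- function(x, ...) {
  paste0(x$family, "(", paste(unlist(x$params), collapse = ", "), ")")
}

is_wt_dist <- function(x) inherits(x, "wt_dist")

check_wt <- function(dist) {
  if (!is_wt_dist(dist)) stop("expected a `wt_dist` object", call. = FALSE)
  dist
}

check_nonneg_x <- function(x) {
  if (any(!is.finite(x) & !is.infinite(x)) || any(x < 0, na.rm = TRUE)) {
    stop("evaluation points must be non-negative", call. = FALSE)
  }
  x
}

#' Density, survival and hazard of a waiting-time distribution
#'
#' `wt_density()`, `wt_survival()` and `wt_hazard()` evaluate the density
#' \eqn{\psi(x)}, the survival probability \eqn{\Psi(x)} and the hazard
#' \eqn{\omega(x) = \psi(x)/\Psi(x)} at non-negative ages. `wt_eval()`
#' returns all three in one tibble. Beyond the upper support boundary
#' (age 1 for the Beta law) the density and survival are 0 and the hazard is
#' reported as `Inf`.
#'
#' @param dist A [wt_dist][wt_weibull] object.
#' @param x Vector of non-negative ages.
#' @return Numeric vector, or for `wt_eval()` a tibble with columns `x`,
#'   `density`, `survival`, `hazard`.
#' @export
wt_density <- function(dist, x) {
  check_wt(dist); check_nonneg_x(x)
  p <- dist$params
  switch(dist$family,
    weibull = stats::dweibull(x, p$shape, p$scale),
    exponential = stats::dexp(x, p$rate),
    beta_sigma1 = ifelse(x < 1, p$gamma * (1 - x)^(p$gamma - 1), 0)
  )
}

#' @rdname wt_density
#' @export
wt_survival <- function(dist, x) {
  check_wt(dist); check_nonneg_x(x)
  p <- dist$params
  switch(dist$family,
    weibull = exp(-(x / p$scale)^p$shape),
    exponential = exp(-p$rate * x),
    beta_sigma1 = ifelse(x < 1, (1 - x)^p$gamma, 0)
  )
}

#' @rdname wt_density
#' @export
wt_hazard <- function(dist, x) {
  check_wt(dist); check_nonneg_x(x)
  p <- dist$params
  switch(dist$family,
    weibull = {
      h <- (p$shape / p$scale) * (x / p$scale)^(p$shape - 1)
      # shape < 1 diverges at 0; shape = 1 gives the constant 1/scale
      ifelse(x == 0 & p$shape < 1, Inf, h)
    },
    exponential = rep_len(p$rate, length(x)),
    beta_sigma1 = ifelse(x < 1, p$gamma / (1 - x), Inf)
  )
}

#' @rdname wt_density
#' @export
wt_eval <- function(dist, x) {
  tibble::tibble(
    x = x,
    density = wt_density(dist, x),
    survival = wt_survival(dist, x),
    hazard = wt_hazard(dist, x)
  )
}

#' Inverse-survival sampling of waiting times
#'
#' `wt_quantile()` solves \eqn{\Psi(\kappa) = u} for \eqn{\kappa}: given a
#' uniform variate `u` in (0, 1] it returns the waiting time whose survival
#' probability equals `u`. All three families have closed forms
#' (Weibull: \eqn{\kappa = \beta (\ln 1/u)^{1/\alpha}}; Beta(1, gamma):
#' \eqn{\kappa = 1 - u^{1/\gamma}}; exponential: \eqn{\kappa = \ln(1/u)/b}).
#' `wt_sample()` draws `n` waiting times using the current R random stream.
#'
#' @param dist A [wt_dist][wt_weibull] object.
#' @param u Uniform variates in (0, 1].
#' @param n Number of draws.
#' @return Numeric vector of waiting times.
#' @examples
#' wt_quantile(wt_weibull(1, 1), exp(-1))  # 1
#' set.seed(1); wt_sample(wt_beta(2), 5)
#' @export
wt_quantile <- function(dist, u) {
  check_wt(dist)
  if (any(!is.finite(u)) || any(u <= 0) || any(u > 1)) {
    stop("`u` must lie in (0, 1]", call. = FALSE)
  }
  p <- dist$params
  switch(dist$family,
    weibull = p$scale * log(1 / u)^(1 / p$shape),
    exponential = log(1 / u) / p$rate,
    beta_sigma1 = 1 - u^(1 / p$gamma)
  )
}

#' @rdname wt_quantile
#' @export
wt_sample <- function(dist, n) {
  check_wt(dist)
  stopifnot(n >= 0)
  u <- stats::runif(n)
  # runif never returns exactly 0 or 1, so u is a valid survival level
  wt_quantile(dist, u)
}

#' Laplace transform of the waiting-time density
#'
#' Evaluates \eqn{\hat\psi(s) = \int_0^\infty \psi(x) e^{-sx} dx} for real
#' \eqn{s \ge 0}. The exponential family uses the closed form
#' \eqn{b/(b+s)}; the others use adaptive quadrature.
#'
#' @param dist A [wt_dist][wt_weibull] object.
#' @param s Non-negative transform variable(s).
#' @param abs_tol Absolute quadrature tolerance.
#' @return Numeric vector of transform values (1 at `s = 0`).
#' @export
wt_laplace <- function(dist, s, abs_tol = wt_quad_tol()) {
  check_wt(dist)
  if (any(!is.finite(s)) || any(s < 0)) stop("`s` must be non-negative", call. = FALSE)
  if (dist$family == "exponential") {
    return(dist$params$rate / (dist$params$rate + s))
  }
  upper <- if (is.finite(dist$support_upper)) dist$support_upper else Inf
  vapply(s, function(si) {
    stats::integrate(function(x) wt_density(dist, x) * exp(-si * x),
                     lower = 0, upper = upper,
                     abs.tol = abs_tol, rel.tol = abs_tol, subdivisions = 500L)$value
  }, numeric(1))
}

#' Mean waiting time as the integral of the survival function
#'
#' Returns \eqn{\int_0^{x_{\max}} \Psi(x) dx}, the mean of the law, by closed
#' form (Weibull: \eqn{\beta\,\Gamma(1 + 1/\alpha)}; Beta(1, gamma):
#' \eqn{1/(\gamma+1)}; exponential: \eqn{1/b}). The reciprocal of this
#' quantity applied to the recovery law is the effective recovery rate.
#'
#' @param dist A [wt_dist][wt_weibull] object.
#' @return The mean waiting time.
#' @export
wt_mean <- function(dist) {
  check_wt(dist)
  p <- dist$params
  switch(dist$family,
    weibull = p$scale * gamma(1 + 1 / p$shape),
    exponential = 1 / p$rate,
    beta_sigma1 = 1 / (p$gamma + 1)
  )
}

#' @keywords internal
wt_quad_tol <- function() 1e-10

#' Parse a compact distribution specification string
#'
#' Accepts `"weibull:shape,scale"`, `"beta:gamma"` and `"exp:rate"` (used by
#' the command-line helpers and experiment configs).
#'
#' @param spec A specification string, or a list with a `family` element and
#'   named parameters (e.g. `list(family = "weibull", shape = 2, scale = 1)`).
#' @return A [wt_dist][wt_weibull] object.
#' @export
wt_parse <- function(spec) {
  if (is_wt_dist(spec)) return(spec)
  if (is.list(spec)) {
    fam <- spec$family
    return(switch(fam,
      weibull = wt_weibull(spec$shape, spec$scale),
      beta = ,
      beta_sigma1 = wt_beta(spec$gamma),
      exp = ,
      exponential = wt_exponential(spec$rate),
      stop("unknown distribution family: ", fam, call. = FALSE)
    ))
  }
  stopifnot(is.character(spec), length(spec) == 1)
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("expected 'family:par1[,par2]'", call. = FALSE)
  vals <- as.numeric(strsplit(parts[2], ",", fixed = TRUE)[[1]])
  switch(parts[1],
    weibull = wt_weibull(vals[1], vals[2]),
    beta = wt_beta(vals[1]),
    exp = ,
    exponential = wt_exponential(vals[1]),
    stop("unknown distribution family: ", parts[1], call. = FALSE)
  )
}
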