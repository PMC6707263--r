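#' Renewal intensity of the infection process
#'
#' For a renewal process whose inter-event times are iid with density
#' \eqn{\psi_{\mathrm{inf}}}, the renewal intensity \eqn{\eta(\tau)} is the
#' expected event rate at elapsed time \eqn{\tau} since the last reset. It
#' solves the Volterra equation of the second kind
#' \deqn{\eta(\tau) = \int_0^\tau \eta(\tau')\,\psi_{\mathrm{inf}}(\tau -
#'   \tau')\,d\tau' + \psi_{\mathrm{inf}}(\tau).}
#' Numerically the equivalent renewal-function equation
#' \eqn{M(t) = F(t) + \int_0^t M(t-s)\,dF(s)} (with \eqn{F = 1 - \Psi} and
#' \eqn{M' = \eta}) is discretized in Riemann–Stieltjes form on a uniform
#' grid, which only evaluates the cdf and therefore handles laws whose
#' density diverges at the origin (Weibull shape < 1). The returned
#' intensity is the cell-average \eqn{(M(b\Delta) - M((b-1)\Delta))/\Delta},
#' reported at cell centers.
#'
#' For constant hazard (exponential law) \eqn{\eta \equiv} rate; for any law
#' with finite mean, \eqn{\eta(\tau) \to 1/\mathrm{mean}} as
#' \eqn{\tau \to \infty} (renewal theorem).
#'
#' @param dist A [wt_dist][wt_weibull] object (the infection law).
#' @param delta Age step of the grid.
#' @param tau_max Upper end of the grid (rounded up to a multiple of
#'   `delta`).
#' @return A tibble with columns `tau` (cell centers) and `eta`, with the
#'   node-grid renewal function in attribute `renewal_function`.
#' @examples
#' renewal_intensity(wt_exponential(2), delta = 0.01, tau_max = 1)
#' @export
renewal_intensity <- function(dist, delta, tau_max) {
  check_wt(dist)
  stopifnot(delta > 0, tau_max > delta)
  if (delta > 0.1 * wt_mean(dist)) {
    warning("grid step exceeds a tenth of the mean waiting time; ",
            "the renewal intensity may be under-resolved", call. = FALSE)
  }
  n <- ceiling(tau_max / delta)
  M <- renewal_mass(dist, delta, n)
  tibble::tibble(
    tau = (seq_len(n) - 0.5) * delta,
    eta = diff(M) / delta
  ) -> out
  attr(out, "renewal_function") <- M
  out
}

# renewal function M on nodes 0..n of step delta
renewal_mass <- function(dist, delta, n) {
  Fgrid <- 1 - wt_survival(dist, (0:n) * delta)
  .renewal_mass_cpp(Fgrid)
}
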