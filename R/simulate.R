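#' Event-driven stochastic SIS simulation
#'
#' Runs one exact realization of SIS dynamics with general waiting-time
#' laws on a network. Each infected node holds an absolute recovery time
#' drawn from the recovery law; each active directed edge holds an absolute
#' transmission time drawn from the infection law; a min-heap over these
#' event times advances the process event by event (no time discretization).
#'
#' The `mechanism` argument selects how directed edges acquire transmission
#' clocks:
#' * `"type1"`: edge \eqn{i \leftarrow j} is active only while \eqn{j} is
#'   infected and \eqn{i} is susceptible; a state change at either end
#'   resets or removes the clock.
#' * `"type2"`: edge \eqn{i \leftarrow j} is active while \eqn{j} is
#'   infected, regardless of \eqn{i}; the clock re-arms with age 0 after
#'   every firing.
#'
#' With exponential infection times (constant hazard) the two mechanisms
#' define the same process in law.
#'
#' @param graph An igraph object (simple, undirected).
#' @param mechanism `"type1"` or `"type2"`.
#' @param infection,recovery [wt_dist][wt_weibull] objects (or spec strings
#'   accepted by [wt_parse()]).
#' @param rho0 Initial infected fraction; `ceiling(rho0 * N)` seed nodes are
#'   drawn without replacement, all with infection age 0.
#' @param t_max Time horizon.
#' @param sample_times Increasing times in `[0, t_max]` at which the
#'   infected density is recorded (step-function interpolation of the jump
#'   process). Default: 201 equispaced points.
#' @param seed Optional integer seed (deterministic trajectory given the
#'   seed).
#' @param seed_nodes Optional explicit 0-based seed node ids (overrides
#'   `rho0`).
#' @param max_events Safety cap on the number of processed events.
#' @param audit Run a full state/heap consistency check every 1000 events
#'   (slower; raises an internal error on any inconsistency).
#' @return A tibble with columns `time` and `infected` (density in
#'   \eqn{[0,1]}), of class `sis_trajectory`, with attributes
#'   `extinct_time` (`NA` if the epidemic survived to `t_max`), `n_events`,
#'   and `ever_infected` (logical per node).
#' @examples
#' g <- generate_network("er", 300, mean_degree = 8, seed = 1)
#' tr <- sis_simulate(g, "type2", wt_weibull(2, 1), wt_weibull(2, 0.5),
#'                    rho0 = 0.05, t_max = 10, seed = 42)
#' tail(tr)
#' @export
sis_simulate <- function(graph, mechanism = c("type1", "type2"),
                         infection, recovery,
                         rho0 = 0.01, t_max, sample_times = NULL,
                         seed = NULL, seed_nodes = NULL,
                         max_events = 5e8, audit = FALSE) {
  mechanism <- match.arg(mechanism)
  infection <- wt_parse(infection)
  recovery <- wt_parse(recovery)
  n <- igraph::vcount(graph)
  if (n == 0) stop("empty graph", call. = FALSE)
  if (is.null(sample_times)) sample_times <- seq(0, t_max, length.out = 201)
  stopifnot(!is.unsorted(sample_times), all(sample_times >= 0), all(sample_times <= t_max))

  el <- igraph::as_edgelist(graph, names = FALSE) - 1L
  res <- with_seed_if(seed, {
    if (is.null(seed_nodes)) {
      stopifnot(rho0 > 0, rho0 <= 1)
      n_seed <- ceiling(rho0 * n)
      seed_nodes <- sample.int(n, n_seed) - 1L
    } else {
      seed_nodes <- as.integer(seed_nodes)
      stopifnot(length(seed_nodes) >= 1, all(seed_nodes >= 0), all(seed_nodes < n))
    }
    .sis_run_cpp(n, as.integer(el[, 1]), as.integer(el[, 2]),
                 if (mechanism == "type1") 1L else 2L,
                 wt_family_code(infection), wt_par_vec(infection),
                 wt_family_code(recovery), wt_par_vec(recovery),
                 seed_nodes, t_max, as.numeric(sample_times), max_events, audit)
  })
  if (isTRUE(res$hit_event_cap)) {
    warning("event cap reached before t_max; trajectory truncated", call. = FALSE)
  }
  out <- tibble::tibble(time = as.numeric(sample_times), infected = res$infected)
  attr(out, "extinct_time") <- res$extinct_time
  attr(out, "n_events") <- res$n_events
  attr(out, "ever_infected") <- as.logical(res$ever_infected)
  class(out) <- c("sis_trajectory", class(out))
  out
}

wt_family_code <- function(dist) {
  switch(dist$family, weibull = 1L, beta_sigma1 = 2L, exponential = 3L)
}

wt_par_vec <- function(dist) {
  switch(dist$family,
    weibull = c(dist$params$shape, dist$params$scale),
    beta_sigma1 = c(dist$params$gamma, 0),
    exponential = c(dist$params$rate, 0)
  )
}

#' Ensemble of SIS realizations
#'
#' Runs `n_realizations` independent seeded realizations of
#' [sis_simulate()] and returns the per-time ensemble mean and standard
#' error of the infected density. Averages are unconditional: realizations
#' that go extinct contribute zeros from their extinction time onward.
#'
#' @inheritParams sis_simulate
#' @param n_realizations Number of independent realizations.
#' @param seed Master seed; per-realization seeds are drawn from it so the
#'   whole ensemble is reproducible.
#' @return A tibble of class `sis_ensemble` with columns `time`,
#'   `infected_mean`, `infected_se`, plus attributes `runs` (time-by-
#'   realization matrix of densities), `extinct_times` and
#'   `n_realizations`.
#' @export
sis_ensemble <- function(graph, mechanism = c("type1", "type2"),
                         infection, recovery,
                         rho0 = 0.01, t_max, sample_times = NULL,
                         n_realizations = 50, seed = NULL,
                         max_events = 5e8) {
  mechanism <- match.arg(mechanism)
  stopifnot(n_realizations >= 1)
  if (is.null(sample_times)) sample_times <- seq(0, t_max, length.out = 201)
  seeds <- with_seed_if(seed, sample.int(.Machine$integer.max - 1L, n_realizations))
  runs <- matrix(NA_real_, nrow = length(sample_times), ncol = n_realizations)
  extinct <- numeric(n_realizations)
  for (r in seq_len(n_realizations)) {
    tr <- sis_simulate(graph, mechanism, infection, recovery,
                       rho0 = rho0, t_max = t_max, sample_times = sample_times,
                       seed = seeds[r], max_events = max_events)
    runs[, r] <- tr$infected
    extinct[r] <- attr(tr, "extinct_time") %||% NA_real_
  }
  m <- rowMeans(runs)
  se <- if (n_realizations == 1) {
    rep(0, nrow(runs))
  } else {
    apply(runs, 1, stats::sd) / sqrt(n_realizations)
  }
  out <- tibble::tibble(time = as.numeric(sample_times),
                        infected_mean = m, infected_se = se)
  attr(out, "runs") <- runs
  attr(out, "extinct_times") <- extinct
  attr(out, "n_realizations") <- n_realizations
  class(out) <- c("sis_ensemble", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stationary infected density from a trajectory
#'
#' Time-averages the infected density over the sample times in
#' `(burn_in, t_max]` and attaches a batch-means standard error (the
#' post-burn-in samples are split into `n_batches` contiguous batches; the
#' standard error is the spread of the batch means), which accounts for the
#' autocorrelation of the stationary fluctuations.
#'
#' @param traj A trajectory tibble with columns `time` and `infected` (a
#'   `sis_trajectory`, or any tibble shaped like one).
#' @param burn_in Time before which samples are discarded.
#' @param n_batches Number of batches for the standard error.
#' @return A tibble with columns `mean`, `se` and `n_samples`.
#' @export
stationary_density <- function(traj, burn_in, n_batches = 10) {
  col <- if ("infected" %in% names(traj)) "infected" else "infected_mean"
  keep <- traj$time > burn_in
  if (!any(keep)) stop("no samples after `burn_in`", call. = FALSE)
  x <- traj[[col]][keep]
  nb <- max(2L, min(n_batches, length(x)))
  groups <- cut(seq_along(x), nb, labels = FALSE)
  bm <- tapply(x, groups, mean)
  se <- if (stats::sd(x) == 0) 0 else stats::sd(bm) / sqrt(nb)
  tibble::tibble(mean = mean(x), se = as.numeric(se), n_samples = length(x))
}

#' Stationary density of an ensemble
#'
#' Applies the post-burn-in time average to each realization of a
#' [sis_ensemble()] result and aggregates across realizations: the mean of
#' the per-realization stationary densities with the standard error across
#' realizations.
#'
#' @param ens A `sis_ensemble` tibble.
#' @param burn_in Time before which samples are discarded.
#' @return A tibble with columns `mean`, `se` and `n_realizations`.
#' @export
ensemble_stationary <- function(ens, burn_in) {
  runs <- attr(ens, "runs")
  if (is.null(runs)) stop("`ens` must come from sis_ensemble()", call. = FALSE)
  keep <- ens$time > burn_in
  if (!any(keep)) stop("no samples after `burn_in`", call. = FALSE)
  per_run <- colMeans(runs[keep, , drop = FALSE])
  tibble::tibble(
    mean = mean(per_run),
    se = stats::sd(per_run) / sqrt(length(per_run)),
    n_realizations = length(per_run)
  )
}
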