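#' Run a canned comparison experiment
#'
#' Drives the simulator, the mean-field integrator and the steady-state
#' theory through the standard study designs at configurable scale and
#' returns a tidy comparison table. Four experiment kinds are available:
#'
#' * `"threshold_check"`: generates the network and reports the spectral
#'   epidemic threshold \eqn{1/\Lambda_{\max}}.
#' * `"transients"`: for each Weibull infection shape `alpha_I` and both
#'   activation mechanisms, the ensemble-simulated infected density
#'   \eqn{I(t)} next to the mean-field prediction.
#' * `"equivalence_type2"`: a \eqn{\beta_I} sweep at fixed `alpha_I` values,
#'   parameterized by the effective infection rate; at each point the
#'   stationary density from (i) non-Markovian type-II simulation, (ii)
#'   Markovian simulation with the matched effective rates and (iii) the
#'   quenched mean-field fixed point.
#' * `"approx_equivalence_type1"`: Beta(1, gamma)-infection sweeps under
#'   type-I activation against the Markovian prediction at
#'   \eqn{\lambda_{\mathrm{eff}} \approx \gamma/\delta_{\mathrm{eff}}}.
#'
#' @param config A list (or path to a YAML file) with elements
#'   `experiment`, `network` (passed to [generate_network()]), `seed`, an
#'   optional `out_dir`, and experiment-specific fields (see the defaults
#'   in [experiment_config()]).
#' @return A list of class `nmsis_experiment` with elements `comparison`
#'   (tibble), `config`, and experiment-specific extras (e.g.
#'   `trajectories`). If `out_dir` is set, `comparison.tsv` and
#'   `summary.json` are written there.
#' @export
run_experiment <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- experiment_config(config)
  if (!is.null(cfg$network$n) && cfg$network$n < 50) {
    stop("network size below the supported minimum (50)", call. = FALSE)
  }
  graph <- do.call(generate_network, c(cfg$network, list(seed = cfg$seed)))
  out <- switch(cfg$experiment,
    threshold_check = experiment_threshold(graph, cfg),
    transients = experiment_transients(graph, cfg),
    equivalence_type2 = experiment_equivalence_type2(graph, cfg),
    approx_equivalence_type1 = experiment_type1(graph, cfg)
  )
  out$config <- cfg
  class(out) <- "nmsis_experiment"
  if (!is.null(cfg$out_dir)) write_experiment(out, cfg$out_dir)
  out
}

#' Experiment configuration with study defaults
#'
#' Fills an experiment config with the standard parameter choices
#' (Weibull recovery with shape 2 and scale 0.5, infection scale 1, 1%
#' seeds) and desk-scale defaults (N = 1000, 50 realizations). Scale fields
#' can be overridden to restore the full-size study.
#'
#' @param config A partial config list; `experiment` is required.
#' @return A completed config list.
#' @export
experiment_config <- function(config) {
  stopifnot(is.list(config), !is.null(config$experiment))
  config$experiment <- match.arg(config$experiment,
    c("threshold_check", "transients", "equivalence_type2", "approx_equivalence_type1"))
  defaults <- list(
    network = list(model = "er", n = 1000, mean_degree = 10),
    seed = 1L,
    rho0 = 0.01,
    alpha_R = 2, beta_R = 0.5,
    beta_I = 1,
    alpha_I_grid = c(0.5, 1, 2),
    lambda_factors = c(0.5, 1, 2, 3),
    gamma_targets = c(0.2, 0.4, 0.6, 0.8),
    alpha_R_grid = c(0.5, 2, 4),
    n_realizations = 50,
    t_max = 12, delta = 0.02,
    stationary_t_max = 60, burn_in = 30,
    stationary_realizations = 8,
    stationary_rho0 = 0.1,
    out_dir = NULL
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config
}

experiment_threshold <- function(graph, cfg) {
  lam <- leading_eigenvalue(graph)
  list(comparison = tibble::tibble(
    estimator = "analytic",
    leading_eigenvalue = lam,
    threshold = 1 / lam,
    n = igraph::vcount(graph),
    mean_degree = mean(igraph::degree(graph)),
    seed = cfg$seed
  ))
}

experiment_transients <- function(graph, cfg) {
  rec <- wt_weibull(cfg$alpha_R, cfg$beta_R)
  sample_times <- seq(0, cfg$t_max, length.out = 49)
  grids <- tidyr::expand_grid(mechanism = c("type1", "type2"),
                              alpha_I = cfg$alpha_I_grid)
  traj <- purrr::pmap(grids, function(mechanism, alpha_I) {
    inf <- wt_weibull(alpha_I, cfg$beta_I)
    ens <- sis_ensemble(graph, mechanism, inf, rec, rho0 = cfg$rho0,
                        t_max = cfg$t_max, sample_times = sample_times,
                        n_realizations = cfg$n_realizations,
                        seed = cfg$seed + round(1000 * alpha_I) +
                          1e5 * (mechanism == "type2"))
    mf <- mean_field_sis(graph, mechanism, inf, rec, rho0 = cfg$rho0,
                         t_max = cfg$t_max, delta = cfg$delta,
                         sample_times = sample_times)
    dplyr::bind_rows(
      tibble::tibble(mechanism = mechanism, alpha_I = alpha_I,
                     estimator = "simulation", time = ens$time,
                     infected = ens$infected_mean, se = ens$infected_se),
      tibble::tibble(mechanism = mechanism, alpha_I = alpha_I,
                     estimator = "mean_field", time = mf$time,
                     infected = mf$infected, se = 0)
    )
  })
  traj <- dplyr::bind_rows(traj)
  comparison <- traj |>
    dplyr::filter(.data$estimator == "simulation") |>
    dplyr::group_by(.data$mechanism, .data$alpha_I) |>
    dplyr::summarise(final_density = .data$infected[dplyr::n()], .groups = "drop") |>
    dplyr::mutate(seed = cfg$seed, n_realizations = cfg$n_realizations)
  list(comparison = comparison, trajectories = traj)
}

experiment_equivalence_type2 <- function(graph, cfg) {
  rec <- wt_weibull(cfg$alpha_R, cfg$beta_R)
  d_eff <- delta_eff(rec)
  thr <- epidemic_threshold(graph)
  grid <- tidyr::expand_grid(alpha_I = cfg$alpha_I_grid, factor = cfg$lambda_factors)
  rows <- purrr::pmap(grid, function(alpha_I, factor) {
    lam <- factor * thr
    beta_I <- beta_for_lambda(lam, alpha_I, rec)
    inf <- wt_weibull(alpha_I, beta_I)
    run_seed <- cfg$seed + round(1e4 * factor) + round(100 * alpha_I)
    nm <- sis_ensemble(graph, "type2", inf, rec, rho0 = cfg$stationary_rho0,
                       t_max = cfg$stationary_t_max,
                       n_realizations = cfg$stationary_realizations,
                       seed = run_seed)
    ref <- markovian_reference(d_eff, lam)
    mk <- sis_ensemble(graph, "type2", ref$infection, ref$recovery,
                       rho0 = cfg$stationary_rho0, t_max = cfg$stationary_t_max,
                       n_realizations = cfg$stationary_realizations,
                       seed = run_seed + 7L)
    qmf <- qmf_fixed_point(graph, lam)
    sn <- ensemble_stationary(nm, cfg$burn_in)
    sm <- ensemble_stationary(mk, cfg$burn_in)
    tibble::tibble(
      alpha_I = alpha_I, lambda_eff = lam, beta_I = beta_I,
      estimator = c("simulation", "markovian_simulation", "analytic"),
      mean = c(sn$mean, sm$mean, qmf$network_density),
      se = c(sn$se, sm$se, 0),
      seed = run_seed,
      n_realizations = c(rep(cfg$stationary_realizations, 2), NA)
    )
  })
  list(comparison = dplyr::bind_rows(rows), threshold = thr, delta_eff = d_eff)
}

experiment_type1 <- function(graph, cfg) {
  k_mean <- mean(igraph::degree(graph))
  rows <- purrr::map(cfg$alpha_R_grid, function(alpha_R) {
    rec <- wt_weibull(alpha_R, cfg$beta_R)
    d_eff <- delta_eff(rec)
    purrr::map(cfg$gamma_targets, function(target) {
      # pick gamma so the Markovian prediction on this graph hits `target`
      lam <- 1 / (k_mean * (1 - target))
      gam <- lam * d_eff
      inf <- wt_beta(gam)
      run_seed <- cfg$seed + round(1e4 * target) + round(100 * alpha_R)
      nm <- sis_ensemble(graph, "type1", inf, rec, rho0 = cfg$stationary_rho0,
                         t_max = cfg$stationary_t_max,
                         n_realizations = cfg$stationary_realizations,
                         seed = run_seed)
      sn <- ensemble_stationary(nm, cfg$burn_in)
      qmf <- qmf_fixed_point(graph, lam)
      tibble::tibble(
        alpha_R = alpha_R, gamma = gam, lambda_eff = lam,
        target_density = target,
        estimator = c("simulation", "analytic"),
        mean = c(sn$mean, qmf$network_density),
        se = c(sn$se, 0),
        seed = run_seed,
        n_realizations = c(cfg$stationary_realizations, NA)
      )
    }) |> dplyr::bind_rows()
  })
  list(comparison = dplyr::bind_rows(rows))
}

write_experiment <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(out$comparison, file.path(dir, "comparison.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- out$config
  summary <- list(
    experiment = cfg$experiment,
    seed = cfg$seed,
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"), auto_unbox = TRUE)
  if (!is.null(out$trajectories)) {
    utils::write.table(out$trajectories, file.path(dir, "trajectories.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @export
#' @method print nmsis_experiment
print.nmsis_experiment <- function(x, ...) {
  cat("<nmsis experiment: ", x$config$experiment, ">\n", sep = "")
  print(x$comparison)
  invisible(x)
}

#' Write small deterministic network fixtures
#'
#' Writes a set of small edge-list files (a 3-node path, the complete graph
#' on 11 nodes, a 100-leaf star, a 10-regular graph on 200 nodes and a
#' seeded Erdős–Rényi graph on 200 nodes) plus a YAML file of canned
#' distribution parameter sets. Regeneration is byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(graph, name) {
    p <- file.path(out_dir, name)
    write_edge_list(graph, p)
    paths <<- c(paths, p)
  }
  put(igraph::make_graph(~ 1 - 2 - 3), "path3.edgelist")
  put(igraph::make_full_graph(11), "k11.edgelist")
  put(igraph::make_star(101, mode = "undirected"), "star101.edgelist")
  put(generate_network("regular", 200, k = 10, seed = 11), "regular10_200.edgelist")
  put(generate_network("er", 200, mean_degree = 10, seed = 7), "er200.edgelist")
  dist_file <- file.path(out_dir, "distributions.yaml")
  yaml::write_yaml(list(
    weibull_recovery = list(family = "weibull", shape = 2, scale = 0.5),
    weibull_infection = list(family = "weibull", shape = 1, scale = 1),
    beta_infection = list(family = "beta", gamma = 1.5),
    markovian = list(family = "exponential", rate = 1)
  ), dist_file)
  invisible(c(paths, dist_file))
}
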