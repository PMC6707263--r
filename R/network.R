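#' Generate the networks the epidemic runs on
#'
#' Wraps the igraph generators behind the models used in the experiments.
#' All outputs are simple undirected graphs.
#'
#' * `"er"`: Erdős–Rényi \eqn{G(N, p)} with \eqn{p = \langle k\rangle/(N-1)}
#'   so the mean degree equals `mean_degree` in expectation.
#' * `"ba"`: Barabási–Albert preferential attachment with `m` edges added
#'   per new node (mean degree tends to \eqn{2m}).
#' * `"powerlaw_config"`: configuration model with degrees drawn
#'   proportionally to \eqn{k^{-\gamma}} for \eqn{k \ge k_{\min}}, wired into
#'   a simple graph (self-loops and multi-edges rejected).
#' * `"regular"`: random k-regular graph (used for the homogeneous
#'   steady-state experiments).
#'
#' @param model One of `"er"`, `"ba"`, `"powerlaw_config"`, `"regular"`.
#' @param n Number of nodes (at least 2).
#' @param mean_degree Target mean degree (ER).
#' @param m Attachments per new node (BA).
#' @param exponent,k_min Power-law exponent and lower degree cutoff
#'   (configuration model).
#' @param k Degree (regular graph).
#' @param seed Optional integer seed; the construction is deterministic
#'   given the seed.
#' @return An igraph object.
#' @examples
#' g <- generate_network("er", n = 200, mean_degree = 8, seed = 1)
#' epidemic_threshold(g)
#' @export
generate_network <- function(model = c("er", "ba", "powerlaw_config", "regular"),
                             n, mean_degree = NULL, m = NULL,
                             exponent = NULL, k_min = NULL, k = NULL,
                             seed = NULL) {
  model <- match.arg(model)
  stopifnot(n >= 2)
  with_seed_if(seed, {
    g <- switch(model,
      er = {
        stopifnot(!is.null(mean_degree), mean_degree > 0)
        igraph::sample_gnp(n, p = mean_degree / (n - 1))
      },
      ba = {
        stopifnot(!is.null(m), m >= 1)
        igraph::sample_pa(n, m = m, directed = FALSE)
      },
      powerlaw_config = {
        stopifnot(!is.null(exponent), !is.null(k_min), k_min >= 1)
        sample_powerlaw_config(n, exponent, k_min)
      },
      regular = {
        stopifnot(!is.null(k), k >= 1)
        igraph::sample_k_regular(n, k)
      }
    )
    igraph::simplify(g)
  })
}

# degrees ~ k^(-exponent) on [k_min, k_cap], then simple configuration wiring
sample_powerlaw_config <- function(n, exponent, k_min) {
  k_cap <- max(k_min, floor(sqrt(n)))  # structural cutoff keeps the graph simple
  ks <- k_min:k_cap
  degs <- sample(ks, n, replace = TRUE, prob = ks^(-exponent))
  if (sum(degs) %% 2 == 1) degs[which.max(degs)] <- degs[which.max(degs)] + 1
  for (attempt in 1:100) {
    g <- try(igraph::sample_degseq(degs, method = "fast.heur.simple"), silent = TRUE)
    if (!inherits(g, "try-error") && igraph::is_simple(g)) return(g)
  }
  stop("could not realize a simple graph from the degree sequence", call. = FALSE)
}

# run `expr` under a temporary seed, restoring the caller's RNG state
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Read and write whitespace-separated edge lists
#'
#' `read_edge_list()` accepts one integer pair per line, `#`-prefixed
#' comment lines, arbitrary integer node labels (remapped to a dense
#' 0-based index kept in the vertex attribute `label`), and collapses
#' duplicate and reversed pairs to one undirected edge. Self-loops are
#' dropped with a warning. `write_edge_list()` writes the 0-based internal
#' ids, one edge per line, so that a write/read round trip reproduces the
#' edge set exactly.
#'
#' @param path File path.
#' @param graph An igraph object.
#' @return `read_edge_list()` returns an igraph object;
#'   `write_edge_list()` returns `path` invisibly.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) < 2 || !all(grepl("^[-+]?[0-9]+$", tk[1:2]))) {
      stop("parse error at line ", idx[i], ": expected two integer node ids",
           call. = FALSE)
    }
  }
  a <- vapply(toks, function(tk) as.integer(tk[1]), integer(1))
  b <- vapply(toks, function(tk) as.integer(tk[2]), integer(1))
  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
    a <- a[!loops]; b <- b[!loops]
  }
  labels <- sort(unique(c(a, b)))
  ia <- match(a, labels); ib <- match(b, labels)
  # collapse duplicates and reversed pairs
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  keep_e <- !duplicated(cbind(lo, hi))
  g <- igraph::make_empty_graph(n = length(labels), directed = FALSE)
  g <- igraph::add_edges(g, rbind(lo[keep_e], hi[keep_e]))
  igraph::V(g)$label <- labels
  g
}

#' @rdname read_edge_list
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = FALSE) - 1L
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' Leading adjacency eigenvalue and spectral epidemic threshold
#'
#' `leading_eigenvalue()` computes the largest eigenvalue \eqn{\Lambda_{\max}}
#' of the (sparse, symmetric 0/1) adjacency matrix by power iteration with a
#' Rayleigh-quotient estimate, to relative tolerance `tol`.
#' `epidemic_threshold()` returns the quenched mean-field outbreak threshold
#' \eqn{\lambda_c = 1/\Lambda_{\max}}: the effective infection rate above
#' which the endemic state exists.
#'
#' @param graph An igraph object with at least one edge.
#' @param tol Relative convergence tolerance.
#' @param max_iter Iteration cap.
#' @return A scalar.
#' @export
leading_eigenvalue <- function(graph, tol = 1e-8, max_iter = 10000L) {
  n <- igraph::vcount(graph)
  if (n == 0) stop("empty graph", call. = FALSE)
  if (igraph::ecount(graph) == 0) stop("graph has no edges", call. = FALSE)
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  A <- methods::as(A, "generalMatrix")
  v <- igraph::degree(graph) + 1
  v <- v / sqrt(sum(v^2))
  lam <- 0
  # iterate on A + I: the shift breaks the +/-Lambda_max degeneracy of
  # bipartite graphs (stars, even cycles) without changing the eigenvector
  for (it in seq_len(max_iter)) {
    w <- as.numeric(A %*% v) + v
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("power iteration collapsed", call. = FALSE)
    w <- w / nw
    lam_new <- as.numeric(crossprod(w, as.numeric(A %*% w)))
    # the Rayleigh quotient settles before its increments do; the safety
    # factor keeps the eigenvalue error itself below `tol`
    if (abs(lam_new - lam) <= 0.01 * tol * max(abs(lam_new), .Machine$double.eps)) {
      return(lam_new)
    }
    lam <- lam_new
    v <- w
  }
  warning("power iteration did not converge to the requested tolerance")
  lam
}

#' @rdname leading_eigenvalue
#' @export
epidemic_threshold <- function(graph, tol = 1e-8) {
  1 / leading_eigenvalue(graph, tol = tol)
}
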