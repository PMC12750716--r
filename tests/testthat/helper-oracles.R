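# Independent oracles used to validate the graph algorithms and model
# fits. These deliberately use brute force (path enumeration, subset
# search, normal equations, finite differences) and share no code with
# the implementation under test.

# --- d-separation by exhaustive path enumeration ----------------------

# All simple undirected paths between a and b, as node sequences.
oracle_all_paths <- function(dag, a, b) {
  nbrs <- function(v) unique(c(dag$parents[[v]], dag$children[[v]]))
  paths <- list()
  walk <- function(path) {
    tail_v <- path[length(path)]
    if (tail_v == b) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (w in setdiff(nbrs(tail_v), path)) walk(c(path, w))
  }
  walk(a)
  paths
}

# A path is blocked given Z iff some triple on it blocks it.
oracle_path_blocked <- function(dag, path, given) {
  if (length(path) < 3L) return(FALSE)
  desc_cache <- new.env()
  has_conditioned_desc <- function(v) {
    key <- v
    if (!is.null(desc_cache[[key]])) return(desc_cache[[key]])
    res <- length(intersect(dag_descendants(dag, v), given)) > 0L
    desc_cache[[key]] <- res
    res
  }
  for (i in 2:(length(path) - 1L)) {
    u <- path[i - 1L]; v <- path[i]; w <- path[i + 1L]
    into_v_from_u <- v %in% dag$children[[u]]
    into_v_from_w <- v %in% dag$children[[w]]
    collider <- into_v_from_u && into_v_from_w
    if (collider) {
      if (!has_conditioned_desc(v)) return(TRUE)
    } else {
      if (v %in% given) return(TRUE)
    }
  }
  FALSE
}

oracle_d_separated <- function(dag, a, b, given = character()) {
  for (path in oracle_all_paths(dag, a, b)) {
    if (!oracle_path_blocked(dag, path, given)) return(FALSE)
  }
  TRUE
}

# --- minimal adjustment sets by brute force ---------------------------

oracle_strip_outgoing <- function(dag, from) {
  keep <- dag$edges[, 1L] != from
  causal_dag_unsafe(dag$edges[keep, , drop = FALSE], dag)
}

# rebuild a dag list without re-validating roles (oracle internal)
causal_dag_unsafe <- function(edges, template) {
  nodes <- template$nodes
  structure(list(
    nodes = nodes, edges = edges,
    parents = lapply(stats::setNames(nodes, nodes),
                     function(v) sort(edges[edges[, 2L] == v, 1L])),
    children = lapply(stats::setNames(nodes, nodes),
                      function(v) sort(edges[edges[, 1L] == v, 2L])),
    exposure = template$exposure, mediator = template$mediator,
    outcome = template$outcome, latent = template$latent),
    class = "causal_dag")
}

oracle_minimal_adjustment_sets <- function(dag, from, to,
                                           forbidden = character()) {
  eligible <- sort(setdiff(dag$nodes,
                           c(from, to, forbidden, dag$latent,
                             dag_descendants(dag, from))))
  stripped <- oracle_strip_outgoing(dag, from)
  sufficient <- function(z) {
    if (length(intersect(z, dag_descendants(dag, from))) > 0L) return(FALSE)
    oracle_d_separated(stripped, from, to, z)
  }
  all_sufficient <- list()
  idx <- seq_along(eligible)
  for (k in 0:length(eligible)) {
    combos <- if (k == 0L) list(character()) else
      utils::combn(eligible, k, simplify = FALSE)
    for (z in combos) {
      if (sufficient(z)) all_sufficient[[length(all_sufficient) + 1L]] <- z
    }
  }
  # keep minimal ones only
  keep <- vapply(seq_along(all_sufficient), function(i) {
    zi <- all_sufficient[[i]]
    !any(vapply(seq_along(all_sufficient), function(j) {
      j != i && length(all_sufficient[[j]]) < length(zi) &&
        all(all_sufficient[[j]] %in% zi)
    }, logical(1L)))
  }, logical(1L))
  all_sufficient[keep]
}

# --- random DAG generator (for property suites) -----------------------

random_dag <- function(n_nodes, edge_prob = 0.3) {
  labels <- c("X", "M", "Y", paste0("C", seq_len(max(0L, n_nodes - 3L))))
  # random topological order, but keep X before M before Y
  ord <- sample(labels)
  ord <- ord[!(ord %in% c("X", "M", "Y"))]
  pos <- sort(sample(seq_len(n_nodes), 3L))
  full <- character(n_nodes)
  full[pos] <- c("X", "M", "Y")
  full[-pos] <- ord
  edges <- matrix(character(), ncol = 2L)
  for (i in seq_len(n_nodes - 1L)) {
    for (j in (i + 1L):n_nodes) {
      # never point into X from M or Y (role invariant)
      if (full[j] == "X") next
      if (stats::runif(1L) < edge_prob) {
        edges <- rbind(edges, c(full[i], full[j]))
      }
    }
  }
  causal_dag(edges, exposure = "X", mediator = "M", outcome = "Y",
             nodes = labels)
}

# --- regression oracles -----------------------------------------------

# least squares through the normal equations
oracle_normal_equations <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}

# logistic log-likelihood Hessian at beta by central finite differences
# with one step of Richardson extrapolation (error O(h^4))
oracle_logistic_hessian <- function(X, y, beta, h = 1e-3) {
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  p <- length(beta)
  fd <- function(step) {
    H <- matrix(0, p, p)
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        e_i <- e_j <- rep(0, p)
        e_i[i] <- step; e_j[j] <- step
        H[i, j] <- (ll(beta + e_i + e_j) - ll(beta + e_i - e_j) -
                      ll(beta - e_i + e_j) + ll(beta - e_i - e_j)) /
          (4 * step^2)
      }
    }
    H
  }
  (4 * fd(h / 2) - fd(h)) / 3
}

# --- misc -------------------------------------------------------------

analysis_cols_for_test <- function(df) {
  intersect(c("x_helpful", "bses_total", "m_bses_high", "y_exclusive",
              "maternal_age", "infant_age", "parity", "delivery_mode",
              "education", "employment", "assets", "hiv", "hps_high",
              "hsi_high"), names(df))
}

# small mediation dataset from an arbitrary congenial DGP (for fast
# unit tests that do not need the full study-calibrated generator)
tiny_mediation_data <- function(n, seed, b_xm = 1, g_m = 1, g_x = 1) {
  set.seed(seed)
  c1 <- stats::rnorm(n)
  x <- stats::rbinom(n, 1L, stats::plogis(0.3 * c1))
  m <- 1 + b_xm * x + 0.5 * c1 + stats::rnorm(n)
  y <- stats::rbinom(n, 1L, stats::plogis(-0.5 + g_x * x + g_m * m + 0.4 * c1))
  data.frame(x_helpful = x, bses_total = m, c1 = c1, y_exclusive = y)
}
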