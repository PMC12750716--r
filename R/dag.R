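# Causal DAG handling: construction from an edge-list text dialect,
# d-separation (moralised ancestral graph reachability), and minimal
# sufficient adjustment sets by exhaustive search (graphs here are
# small, < 15 nodes, so enumeration is exact and fast).

#' Construct a causal DAG
#'
#' @param edges two-column character matrix or data frame of
#'   (parent, child) pairs; may have zero rows.
#' @param exposure,mediator,outcome node names for the designated roles.
#' @param nodes optional character vector of node names (isolated nodes
#'   allowed); defaults to every name appearing in `edges` plus the roles.
#' @param latent character vector of unobserved node names (excluded from
#'   adjustment sets).
#' @return An object of class `causal_dag` with parent/child adjacency
#'   lists.
#' @export
causal_dag <- function(edges, exposure, mediator, outcome,
                       nodes = NULL, latent = character()) {
  em <- if (length(edges)) {
    matrix(as.character(as.matrix(edges)), ncol = 2L)
  } else {
    matrix(character(), ncol = 2L)
  }
  all_nodes <- unique(c(nodes, as.vector(em), exposure, mediator, outcome))
  for (role in c(exposure, mediator, outcome)) {
    gc_assert(role %in% all_nodes,
              sprintf("role node '%s' absent from the graph", role))
  }
  gc_assert(length(unique(c(exposure, mediator, outcome))) == 3L,
            "exposure, mediator and outcome must be three distinct nodes")
  gc_assert(!any(duplicated(paste(em[, 1L], em[, 2L], sep = "\r"))),
            "duplicate edges in DAG")
  gc_assert(!any(em[, 1L] == em[, 2L]), "self-loop edge in DAG")

  parents <- lapply(stats::setNames(all_nodes, all_nodes),
                    function(v) sort(em[em[, 2L] == v, 1L]))
  children <- lapply(stats::setNames(all_nodes, all_nodes),
                     function(v) sort(em[em[, 1L] == v, 2L]))

  dag <- structure(
    list(nodes = all_nodes, edges = em, parents = parents,
         children = children, exposure = exposure, mediator = mediator,
         outcome = outcome, latent = intersect(latent, all_nodes)),
    class = "causal_dag")

  cyc <- find_cycle(dag)
  if (!is.null(cyc)) {
    gc_stop(sprintf("graph is cyclic: %s", paste(cyc, collapse = " -> ")),
            "gcompmed_dag_error")
  }
  bad_into_x <- intersect(dag$parents[[exposure]], c(mediator, outcome))
  gc_assert(length(bad_into_x) == 0L,
            "mediator/outcome cannot be a parent of the exposure")
  dag
}

# Returns one directed cycle as a node sequence, or NULL if acyclic.
find_cycle <- function(dag) {
  state <- stats::setNames(rep(0L, length(dag$nodes)), dag$nodes) # 0 new 1 open 2 done
  path <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return(invisible(NULL))
    state[v] <<- 1L
    path <<- c(path, v)
    for (w in dag$children[[v]]) {
      if (!is.null(found)) break
      if (state[w] == 1L) {
        i <- match(w, path)
        found <<- c(path[i:length(path)], w)
      } else if (state[w] == 0L) {
        visit(w)
      }
    }
    state[v] <<- 2L
    path <<- path[-length(path)]
  }
  for (v in dag$nodes) if (state[v] == 0L) visit(v)
  found
}

#' @export
print.causal_dag <- function(x, ...) {
  cat(sprintf("causal_dag: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  cat(sprintf("  exposure: %s   mediator: %s   outcome: %s\n",
              x$exposure, x$mediator, x$outcome))
  if (length(x$latent)) cat("  latent:", paste(x$latent, collapse = ", "), "\n")
  invisible(x)
}

#' Read a causal DAG from an edge-list text file
#'
#' The dialect is one `Parent -> Child` statement per line (several may
#' share a line separated by `;`), `#` comments, and role lines
#' `exposure: X`, `mediator: M`, `outcome: Y`; optional `latent: A, B`.
#'
#' @param path file path, or a character vector of lines via `text=`.
#' @param text optional character scalar/vector of the DAG source.
#' @return A [causal_dag()].
#' @export
read_dag <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else
    unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  stmts <- trimws(unlist(strsplit(lines, ";", fixed = TRUE)))
  stmts <- stmts[nzchar(stmts)]

  roles <- list()
  latent <- character()
  edges <- matrix(character(), ncol = 2L)
  nodes <- character()
  for (s in stmts) {
    if (grepl("^(exposure|mediator|outcome)\\s*:", s)) {
      key <- sub("\\s*:.*$", "", s)
      roles[[key]] <- trimws(sub("^[^:]*:", "", s))
    } else if (grepl("^latent\\s*:", s)) {
      latent <- c(latent, trimws(strsplit(sub("^[^:]*:", "", s), ",")[[1L]]))
    } else if (grepl("->", s, fixed = TRUE)) {
      pair <- trimws(strsplit(s, "->", fixed = TRUE)[[1L]])
      gc_assert(length(pair) == 2L && all(nzchar(pair)),
                sprintf("cannot parse edge statement: '%s'", s))
      edges <- rbind(edges, pair)
    } else if (grepl("^node\\s*:", s)) {
      nodes <- c(nodes, trimws(strsplit(sub("^[^:]*:", "", s), ",")[[1L]]))
    } else {
      gc_stop(sprintf("cannot parse DAG statement: '%s'", s),
              "gcompmed_dag_error")
    }
  }
  for (key in c("exposure", "mediator", "outcome")) {
    if (is.null(roles[[key]])) {
      gc_stop(sprintf("DAG file is missing the '%s:' role line", key),
              "gcompmed_dag_error")
    }
  }
  causal_dag(edges, exposure = roles$exposure, mediator = roles$mediator,
             outcome = roles$outcome, nodes = nodes, latent = latent)
}

reachable_directed <- function(adj, start) {
  seen <- character()
  frontier <- start
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  unique(seen)
}

#' Ancestors / descendants of a node set
#'
#' @param dag a [causal_dag()].
#' @param nodes character vector of node names.
#' @param include_self include the query nodes themselves (default TRUE).
#' @return Character vector of node names.
#' @export
dag_ancestors <- function(dag, nodes, include_self = TRUE) {
  out <- reachable_directed(dag$parents, nodes)
  if (include_self) out else setdiff(out, nodes)
}

#' @rdname dag_ancestors
#' @export
dag_descendants <- function(dag, nodes, include_self = TRUE) {
  out <- reachable_directed(dag$children, nodes)
  if (include_self) out else setdiff(out, nodes)
}

#' Test d-separation
#'
#' `a` and `b` are d-separated given `given` iff every path between them
#' is blocked: a chain or fork is blocked when its middle node is
#' conditioned on; a collider blocks unless it or one of its descendants
#' is conditioned on. Implemented by reachability in the moralised
#' ancestral graph of `{a, b} union given`.
#'
#' @param dag a [causal_dag()].
#' @param a,b node names, distinct.
#' @param given character vector of conditioning nodes (may be empty).
#' @return TRUE iff `a` and `b` are d-separated given `given`.
#' @export
d_separated <- function(dag, a, b, given = character()) {
  given <- unique(as.character(given))
  unknown <- setdiff(c(a, b, given), dag$nodes)
  if (length(unknown)) {
    gc_stop(sprintf("unknown node(s): %s", paste(unknown, collapse = ", ")),
            "gcompmed_dag_error")
  }
  gc_assert(a != b, "d-separation query needs two distinct nodes")
  gc_assert(!(a %in% given) && !(b %in% given),
            "conditioning set may not contain the query nodes")

  anc <- dag_ancestors(dag, c(a, b, given))
  # moralise the ancestral subgraph: undirected skeleton + married parents
  nbr <- lapply(stats::setNames(anc, anc), function(v) character())
  add <- function(u, v) {
    nbr[[u]] <<- c(nbr[[u]], v)
    nbr[[v]] <<- c(nbr[[v]], u)
  }
  for (v in anc) {
    pa <- intersect(dag$parents[[v]], anc)
    for (p in pa) add(p, v)
    if (length(pa) > 1L) {
      for (i in seq_len(length(pa) - 1L)) {
        for (j in (i + 1L):length(pa)) add(pa[i], pa[j])
      }
    }
  }
  # delete conditioned nodes, test connectivity a -- b
  live <- setdiff(anc, given)
  seen <- a
  frontier <- a
  while (length(frontier)) {
    nxt <- setdiff(intersect(unique(unlist(nbr[frontier], use.names = FALSE)),
                             live), seen)
    if (b %in% nxt) return(FALSE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  TRUE
}

# DAG with all edges out of `from` removed: backdoor-path skeleton.
strip_outgoing <- function(dag, from) {
  keep <- dag$edges[, 1L] != from
  d <- dag
  d$edges <- dag$edges[keep, , drop = FALSE]
  d$children[[from]] <- character()
  d$parents <- lapply(stats::setNames(dag$nodes, dag$nodes),
                      function(v) sort(d$edges[d$edges[, 2L] == v, 1L]))
  d
}

# Backdoor sufficiency of Z for the effect of `from` on `to`:
# Z contains no descendant of `from` and d-separates `from` and `to`
# in the graph with the edges out of `from` deleted.
backdoor_sufficient <- function(dag, from, to, z) {
  if (length(intersect(z, dag_descendants(dag, from))) > 0L) return(FALSE)
  d_separated(strip_outgoing(dag, from), from, to, z)
}

#' Minimal sufficient adjustment sets
#'
#' Enumerates all minimal sets of observed, non-forbidden nodes that
#' block every non-causal (backdoor) path from `from` to `to`, i.e. sets
#' Z with no descendant of `from` such that `from` and `to` are
#' d-separated by Z once the edges out of `from` are removed. Search is
#' exhaustive over subsets in order of increasing size, keeping only
#' sets with no sufficient proper subset.
#'
#' @param dag a [causal_dag()].
#' @param from,to node names (cause and effect).
#' @param forbidden nodes never allowed in an adjustment set, in
#'   addition to `from`, `to`, latent nodes and descendants of `from`.
#' @return A list of character vectors (each sorted), ordered by size
#'   then lexicographically; `list(character(0))` when the empty set is
#'   sufficient; `list()` when no sufficient set exists.
#' @export
minimal_adjustment_sets <- function(dag, from, to, forbidden = character()) {
  eligible <- setdiff(dag$nodes,
                      c(from, to, forbidden, dag$latent,
                        dag_descendants(dag, from)))
  eligible <- sort(eligible)
  found <- list()
  is_superset_of_found <- function(z) {
    for (f in found) if (all(f %in% z)) return(TRUE)
    FALSE
  }
  for (k in 0:length(eligible)) {
    combos <- if (k == 0L) list(character()) else
      utils::combn(eligible, k, simplify = FALSE)
    for (z in combos) {
      if (is_superset_of_found(z)) next
      if (backdoor_sufficient(dag, from, to, z)) found[[length(found) + 1L]] <- z
    }
  }
  found
}

#' Adjustment sets for the mediator and outcome equations
#'
#' For the mediator equation the mediator is treated as the (temporary)
#' outcome and the minimal backdoor sets for exposure -> mediator are
#' returned. For the outcome equation, which regresses the outcome on
#' both exposure and mediator, a set Z must block the backdoor paths
#' exposure -> outcome *and*, jointly with the exposure, the backdoor
#' paths mediator -> outcome; minimal such Z are returned.
#'
#' When several minimal sets exist the pipeline uses the smallest,
#' breaking ties lexicographically on the sorted node names.
#'
#' @param dag a [causal_dag()].
#' @return A list with `for_mediator_equation` and
#'   `for_outcome_equation` (lists of candidate sets) and `chosen`
#'   (the deterministic picks used downstream).
#' @export
mediation_adjustment_sets <- function(dag) {
  x <- dag$exposure; m <- dag$mediator; y <- dag$outcome
  sets_m <- minimal_adjustment_sets(dag, x, m)
  # outcome equation: exhaustive over observed non-descendants of X
  # (the mediator itself is in the model by construction)
  eligible <- sort(setdiff(dag$nodes,
                           c(x, m, y, dag$latent, dag_descendants(dag, x))))
  suff_y <- function(z) {
    backdoor_sufficient(dag, x, y, z) &&
      {
        g <- strip_outgoing(dag, m)
        # conditioning on X is implicit: the Y model includes the exposure
        d_separated(g, m, y, unique(c(z, x)))
      }
  }
  sets_y <- list()
  for (k in 0:length(eligible)) {
    combos <- if (k == 0L) list(character()) else
      utils::combn(eligible, k, simplify = FALSE)
    for (z in combos) {
      if (any(vapply(sets_y, function(f) all(f %in% z), logical(1L)))) next
      if (suff_y(z)) sets_y[[length(sets_y) + 1L]] <- z
    }
  }
  pick <- function(sets) {
    if (!length(sets)) return(NULL)
    sizes <- lengths(sets)
    cand <- sets[sizes == min(sizes)]
    keys <- vapply(cand, function(s) paste(sort(s), collapse = "\r"),
                   character(1L))
    cand[[order(keys)[1L]]]
  }
  list(for_mediator_equation = sets_m,
       for_outcome_equation = sets_y,
       chosen = list(mediator = pick(sets_m), outcome = pick(sets_y)))
}
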