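# Independent oracles: brute-force implementations used only to check the
# package, sharing no code with it.

# All simple paths s -> t by DFS; returns minimum cost and the minimum
# restricted to paths with >= 2 edges (NA when none exists).
oracle_min_cost <- function(adj, cost, s, t) {
  best <- Inf
  best2 <- Inf
  rec <- function(v, acc, nedges, visited) {
    if (v == t && nedges > 0L) {
      if (acc < best) best <<- acc
      if (nedges >= 2L && acc < best2) best2 <<- acc
      return(invisible())
    }
    for (w in adj[[v]]) {
      if (!visited[w]) {
        visited[w] <- TRUE
        rec(w, acc + cost[[v]][[w]], nedges + 1L, visited)
        visited[w] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, length(adj))
  names(visited) <- names(adj)
  visited[s] <- TRUE
  rec(s, 0, 0L, visited)
  c(any = best, ge2 = best2)
}

# Adjacency structures for the oracles, from an igraph with a cost edge
# attribute.
oracle_adj <- function(g) {
  nodes <- sort(igraph::V(g)$name)
  el <- igraph::ends(g, igraph::E(g), names = TRUE)
  cs <- igraph::E(g)$cost
  adj <- stats::setNames(lapply(nodes, function(x) character(0)), nodes)
  cost <- stats::setNames(lapply(nodes, function(x) list()), nodes)
  for (i in seq_len(nrow(el))) {
    adj[[el[i, 1L]]] <- c(adj[[el[i, 1L]]], el[i, 2L])
    cost[[el[i, 1L]]][[el[i, 2L]]] <- cs[i]
  }
  list(nodes = nodes, adj = adj, cost = cost)
}

# Full distance matrix by repeated edge relaxation (Bellman-Ford style).
oracle_distances <- function(g) {
  nodes <- sort(igraph::V(g)$name)
  n <- length(nodes)
  el <- igraph::ends(g, igraph::E(g), names = TRUE)
  cs <- igraph::E(g)$cost
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  if (nrow(el)) {
    ui <- match(el[, 1L], nodes); vi <- match(el[, 2L], nodes)
    for (k in seq_len(max(1L, n - 1L))) {
      for (i in seq_along(ui)) {
        cand <- D[, ui[i]] + cs[i]
        upd <- cand < D[, vi[i]]
        D[upd, vi[i]] <- cand[upd]
      }
    }
  }
  D
}

# Reachability by boolean transitive closure (repeated squaring).
oracle_reach <- function(g) {
  nodes <- sort(igraph::V(g)$name)
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  el <- igraph::ends(g, igraph::E(g), names = TRUE)
  if (nrow(el)) A[cbind(match(el[, 1], nodes), match(el[, 2], nodes))] <- TRUE
  R <- A
  repeat {
    R2 <- R | (R %*% R > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# Ripple-centrality vector from the relaxation distance matrix and the
# transitive closure, mirroring the definitions independently.
oracle_ripple <- function(g) {
  D <- oracle_distances(g)
  R <- oracle_reach(g)
  diag(D) <- Inf
  n <- nrow(D)
  r <- rowSums(R & !diag(TRUE, n))
  s <- vapply(seq_len(n), function(i) sum(D[i, is.finite(D[i, ])]),
              numeric(1))
  raw <- ifelse(s > 0, 1 / s, 0)
  cl <- if (n > 1L) raw * r^2 / (n - 1) else raw * 0
  if (max(cl) > 0) cl <- cl / max(cl)
  ro <- if (n > 1L) r / (n - 1) else r * 0
  stats::setNames(cl * ro, rownames(D))
}

# Unweighted BFS distances, plain R, for hop-count checks.
oracle_bfs_dist <- function(g, root, mode) {
  nodes <- igraph::V(g)$name
  el <- igraph::ends(g, igraph::E(g), names = TRUE)
  if (mode == "in") el <- el[, 2:1, drop = FALSE]
  d <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  d[root] <- 0L
  frontier <- root
  while (length(frontier)) {
    nxt <- unique(el[el[, 1L] %in% frontier, 2L])
    nxt <- nxt[is.na(d[nxt])]
    d[nxt] <- d[frontier[1L]] + 1L
    frontier <- nxt
  }
  d
}

# Random weighted condition network built through the package's public
# constructors: random digraph + random positive intensities.
random_condition_network <- function(n, p = 0.3, condition = "perturbed") {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[stats::runif(nrow(pairs)) < p, ]
  if (nrow(pairs) == 0L) pairs <- data.frame(from = nodes[1L],
                                             to = nodes[2L])
  net <- suppressMessages(base_network(pairs))
  expr <- expression_profile(
    stats::setNames(stats::rlnorm(n, log(100), 1), nodes), condition)
  suppressMessages(build_condition_network(net, expr))
}

# Synthetic path set (for percentile / conservation checks) built directly
# from sequences and costs.
make_path_set <- function(paths, costs, condition = "perturbed",
                          q = NULL, cutoff = NULL) {
  ps <- structure(list(condition = condition, paths = paths,
                       costs = costs), class = "path_set")
  if (!is.null(q)) {
    ps$q <- q
    ps$cutoff <- if (is.null(cutoff)) max(costs) else cutoff
    class(ps) <- c("hap_set", "path_set")
  }
  ps
}

# Default planted-epicenter case, computed once per test session.
.case_env <- new.env(parent = emptyenv())
default_case <- function() {
  if (is.null(.case_env$case)) .case_env$case <- generate_case()
  .case_env$case
}
default_fit <- function() {
  if (is.null(.case_env$fit)) {
    case <- default_case()
    .case_env$fit <- epitracer(case$network, case$control,
                               case$perturbed)
  }
  .case_env$fit
}

# Minimal hand-built fit for influence-zone tests: base edges + profiles,
# with CSHANs induced from explicitly chosen path sets.
fake_fit <- function(edges, control, perturbed,
                     cshan_perturbed_paths = list(),
                     cshan_control_paths = list()) {
  net <- suppressMessages(base_network(edges))
  ctrl <- expression_profile(control, "control")
  pert <- expression_profile(perturbed, "perturbed")
  nets <- list(control = suppressMessages(build_condition_network(net, ctrl)),
               perturbed = suppressMessages(build_condition_network(net, pert)))
  mk <- function(paths, cond)
    induce_cshan(make_path_set(paths, rep(1, length(paths)), cond),
                 nets[[cond]])
  structure(list(networks = nets,
                 cshans = list(perturbed = mk(cshan_perturbed_paths,
                                              "perturbed"),
                               control = mk(cshan_control_paths,
                                            "control")),
                 profiles = list(control = ctrl, perturbed = pert),
                 analyze = "perturbed"),
            class = "epitracer")
}
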