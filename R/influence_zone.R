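# Deterministic BFS from `root`: neighbors are expanded in lexicographic
# order, so the shortest-path tree (and hence any reported intermediate
# node) is a fixed function of the graph. mode "out" follows edges
# forwards, "in" backwards.
.bfs_tree <- function(g, root, mode = c("out", "in")) {
  mode <- match.arg(mode)
  nodes <- igraph::V(g)$name
  adj <- igraph::adjacent_vertices(g, igraph::V(g), mode = mode)
  adj <- lapply(adj, function(v) sort(v$name, method = "radix"))
  names(adj) <- nodes
  dist <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  parent <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  dist[root] <- 0L
  queue <- root
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in adj[[u]]) {
      if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1L
        parent[v] <- u
        queue <- c(queue, v)
      }
    }
  }
  list(dist = dist, parent = parent)
}

# Path root -> x along a BFS parent tree, as a node vector.
.tree_path <- function(tree, x) {
  p <- x
  while (!is.na(tree$parent[p[1L]])) p <- c(tree$parent[p[1L]], p)
  p
}

.which_network_label <- function(genes, cshan_perturbed, cshan_control) {
  inp <- genes %in% igraph::V(cshan_perturbed)$name
  inc <- genes %in% igraph::V(cshan_control)$name
  ifelse(inp & inc, "common to both CSHANs",
         ifelse(inp, "unique to perturbed CSHAN",
                ifelse(inc, "unique to control CSHAN", "not in any CSHAN")))
}

.zone_columns <- function(hops) {
  base <- c("Node", "Direction", "Num_hops", "Fold_change", "Which_network")
  if (hops < 2L) return(base)
  inter <- as.vector(vapply(seq_len(hops - 1L), function(j)
    paste0(c("Intermediate_node_", "Intermediate_fold_change_",
             "Intermediate_significant_fc_", "Intermediate_which_network_"),
           j), character(4)))
  c(base, inter)
}

# One summary row (as a one-row data frame in the wide schema).
.zone_row <- function(node, direction, nh, path_nodes, fc_map, cutoff,
                      label_fun, hops) {
  fcv <- function(g) unname(fc_map[g])
  row <- data.frame(Node = node, Direction = direction, Num_hops = nh,
                    Fold_change = fcv(node),
                    Which_network = label_fun(node),
                    stringsAsFactors = FALSE)
  if (hops >= 2L) {
    inter <- if (nh > 1L) path_nodes[-c(1L, length(path_nodes))]
             else character(0)
    for (j in seq_len(hops - 1L)) {
      if (j <= length(inter)) {
        m <- inter[j]
        row[[paste0("Intermediate_node_", j)]] <- m
        row[[paste0("Intermediate_fold_change_", j)]] <- fcv(m)
        row[[paste0("Intermediate_significant_fc_", j)]] <-
          !is.na(fcv(m)) && significant_fc(fcv(m), cutoff)
        row[[paste0("Intermediate_which_network_", j)]] <- label_fun(m)
      } else {
        row[[paste0("Intermediate_node_", j)]] <- NA_character_
        row[[paste0("Intermediate_fold_change_", j)]] <- NA_real_
        row[[paste0("Intermediate_significant_fc_", j)]] <- NA
        row[[paste0("Intermediate_which_network_", j)]] <- NA_character_
      }
    }
  }
  row
}

# Rows for one direction on one graph; flagged = genes passing the cutoff.
.zone_direction_rows <- function(g, epicenter, direction, hops, fc_map,
                                 cutoff, label_fun) {
  mode <- if (direction == "down") "out" else "in"
  tree <- .bfs_tree(g, epicenter, mode = mode)
  d <- tree$dist
  cand <- names(d)[!is.na(d) & d >= 1L & d <= hops]
  cand <- cand[!is.na(fc_map[cand]) & significant_fc(fc_map[cand], cutoff)]
  cand <- cand[order(d[cand], cand, method = "radix")]
  if (length(cand) == 0L) return(NULL)
  rows <- lapply(cand, function(x) {
    p <- .tree_path(tree, x)           # epicenter -> x in BFS tree
    if (mode == "in") p <- rev(p)      # travel order: x -> epicenter
    .zone_row(x, paste0(direction, "_", epicenter), unname(d[x]), p,
              fc_map, cutoff, label_fun, hops)
  })
  do.call(rbind, rows)
}

#' Immediate influence zone of an epicenter
#'
#' The immediate influence zone of an epicenter is the set of nodes within
#' \code{hops} unweighted hops upstream or downstream of it (default 2).
#' The report lists, per direction, the zone genes passing a symmetric
#' fold-change cutoff (default 2.0), with their hop distance and, for
#' genes more than one hop away, the intermediate nodes on one unweighted
#' shortest path (deterministic lexicographic BFS). The first row is the
#' input node itself at 0 hops. A gene that is both upstream and
#' downstream within range gets one row per direction.
#'
#' When the zone is computed on a CSHAN, dysregulated genes within range
#' in the full condition network can additionally be pulled in via
#' \code{augment_from_full}: \code{"down"} (default) adds downregulated
#' genes, \code{"up"} upregulated, \code{"both"} either, \code{"none"}
#' disables augmentation; their hop counts and intermediates come from the
#' full network.
#'
#' @param object an [epitracer()] fit.
#' @param epicenter gene identifier; must be present in the chosen graph.
#' @param graph which graph to trace on: \code{"perturbed-cshan"}
#'   (default), \code{"control-cshan"}, or \code{"full"} (the perturbed
#'   condition network).
#' @param hops maximum hop distance, >= 1 (default 2).
#' @param fc_cutoff fold-change cutoff, > 1 (default 2.0).
#' @param augment_from_full see Details; ignored when \code{graph =
#'   "full"}.
#' @return a list of class \code{"influence_zone_report"}: the epicenter,
#'   the zone graph (induced subgraph on the zone's nodes), and the
#'   summary \code{table}.
#' @export
influence_zone <- function(object, epicenter,
                           graph = c("perturbed-cshan", "control-cshan",
                                     "full"),
                           hops = 2, fc_cutoff = 2.0,
                           augment_from_full = c("down", "up", "both",
                                                 "none")) {
  stopifnot(inherits(object, "epitracer"))
  graph <- match.arg(graph)
  augment_from_full <- match.arg(augment_from_full)
  if (!is.numeric(hops) || length(hops) != 1L || hops < 1)
    stop("'hops' must be >= 1")
  hops <- as.integer(hops)
  if (!is.numeric(fc_cutoff) || length(fc_cutoff) != 1L || fc_cutoff <= 1)
    stop("'fc_cutoff' must be > 1")
  g <- switch(graph,
              "perturbed-cshan" = object$cshans$perturbed,
              "control-cshan" = object$cshans$control,
              "full" = object$networks$perturbed)
  full <- object$networks$perturbed
  if (!(epicenter %in% igraph::V(g)$name)) {
    avail <- c("perturbed-cshan", "control-cshan", "full")[
      c(epicenter %in% igraph::V(object$cshans$perturbed)$name,
        epicenter %in% igraph::V(object$cshans$control)$name,
        epicenter %in% igraph::V(full)$name)]
    stop("epicenter '", epicenter, "' is not in graph '", graph, "'",
         if (length(avail)) paste0("; it is present in: ",
                                   paste(avail, collapse = ", "))
         else "; it is present in no available graph")
  }
  fct <- fold_changes(object$profiles$control, object$profiles$perturbed,
                      cutoff = fc_cutoff)
  fc_map <- stats::setNames(fct$fold_change, fct$gene)
  label_fun <- function(genes)
    .which_network_label(genes, object$cshans$perturbed,
                         object$cshans$control)

  rows <- list(.zone_row(epicenter, "input_node", 0L, epicenter, fc_map,
                         fc_cutoff, label_fun, hops))
  zone_nodes <- epicenter
  for (direction in c("down", "up")) {
    r <- .zone_direction_rows(g, epicenter, direction, hops, fc_map,
                              fc_cutoff, label_fun)
    if (!is.null(r)) rows <- c(rows, list(r))
    tree <- .bfs_tree(g, epicenter,
                      mode = if (direction == "down") "out" else "in")
    zone_nodes <- union(zone_nodes, names(tree$dist)[
      !is.na(tree$dist) & tree$dist <= hops])
  }

  if (graph != "full" && augment_from_full != "none" &&
      epicenter %in% igraph::V(full)$name) {
    dir_ok <- function(fc) switch(augment_from_full,
                                  down = fc <= 1 / fc_cutoff,
                                  up = fc >= fc_cutoff,
                                  both = significant_fc(fc, fc_cutoff))
    have <- do.call(rbind, rows)
    for (direction in c("down", "up")) {
      mode <- if (direction == "down") "out" else "in"
      tree <- .bfs_tree(full, epicenter, mode = mode)
      d <- tree$dist
      cand <- names(d)[!is.na(d) & d >= 1L & d <= hops]
      cand <- cand[!is.na(fc_map[cand]) & dir_ok(fc_map[cand])]
      lab <- paste0(direction, "_", epicenter)
      cand <- setdiff(cand, have$Node[have$Direction == lab])
      cand <- cand[order(d[cand], cand, method = "radix")]
      if (length(cand)) {
        r <- lapply(cand, function(x) {
          p <- .tree_path(tree, x)
          if (mode == "in") p <- rev(p)
          .zone_row(x, lab, unname(d[x]), p, fc_map, fc_cutoff, label_fun,
                    hops)
        })
        rows <- c(rows, r)
        zone_nodes <- union(zone_nodes, cand)
      }
    }
  }

  tab <- do.call(rbind, rows)
  tab <- tab[order(match(tab$Direction, c("input_node",
                                          paste0("down_", epicenter),
                                          paste0("up_", epicenter))),
                   tab$Num_hops, tab$Node, method = "radix"), ,
             drop = FALSE]
  rownames(tab) <- NULL
  zone <- igraph::induced_subgraph(g, intersect(igraph::V(g)$name,
                                                zone_nodes))
  structure(list(epicenter = epicenter, graph = graph, hops = hops,
                 fc_cutoff = fc_cutoff, zone = zone, table = tab),
            class = "influence_zone_report")
}

#' @export
print.influence_zone_report <- function(x, ...) {
  cat("Influence zone of ", x$epicenter, " on ", x$graph, " (<= ",
      x$hops, " hops, ", x$fc_cutoff, "-fold cutoff): ",
      igraph::vcount(x$zone), " nodes, ", igraph::ecount(x$zone),
      " edges; ", nrow(x$table) - 1L, " dysregulated gene row(s)\n",
      sep = "")
  invisible(x)
}

#' Combined influence zone of several epicenters
#'
#' Takes the union of the per-epicenter influence zones, records for each
#' node which epicenters reach it, and optionally prunes the combined
#' graph to a keep-list plus the minimal connector nodes (nodes on one
#' unweighted shortest path between each connected ordered pair of kept
#' nodes).
#'
#' @inheritParams influence_zone
#' @param epicenters character vector of epicenter genes (>= 1 present in
#'   the chosen graph).
#' @param keep optional character vector of nodes to retain; connectors
#'   needed to link them are kept too. NULL (default) disables pruning.
#' @return a list of class \code{"combined_influence_zone"}: per-epicenter
#'   \code{reports}, the combined \code{zone} graph, and a
#'   \code{provenance} data frame (node, comma-separated epicenters).
#' @export
combined_influence_zone <- function(object, epicenters,
                                    graph = c("perturbed-cshan",
                                              "control-cshan", "full"),
                                    hops = 2, fc_cutoff = 2.0,
                                    augment_from_full = c("down", "up",
                                                          "both", "none"),
                                    keep = NULL) {
  graph <- match.arg(graph)
  augment_from_full <- match.arg(augment_from_full)
  stopifnot(length(epicenters) >= 1L)
  reports <- lapply(epicenters, function(e)
    influence_zone(object, e, graph = graph, hops = hops,
                   fc_cutoff = fc_cutoff,
                   augment_from_full = augment_from_full))
  names(reports) <- epicenters
  zone_sets <- lapply(reports, function(r) igraph::V(r$zone)$name)
  all_nodes <- sort(unique(unlist(zone_sets)), method = "radix")
  prov <- vapply(all_nodes, function(n)
    paste(epicenters[vapply(zone_sets, function(s) n %in% s, logical(1))],
          collapse = ","), character(1))
  g <- switch(graph,
              "perturbed-cshan" = object$cshans$perturbed,
              "control-cshan" = object$cshans$control,
              "full" = object$networks$perturbed)
  zone <- igraph::induced_subgraph(g, intersect(igraph::V(g)$name,
                                                all_nodes))
  if (!is.null(keep)) {
    keep <- intersect(keep, igraph::V(zone)$name)
    retained <- keep
    for (a in keep) {
      tree <- .bfs_tree(zone, a, mode = "out")
      for (b in setdiff(keep, a)) {
        if (!is.na(tree$dist[b]))
          retained <- union(retained, .tree_path(tree, b))
      }
    }
    zone <- igraph::induced_subgraph(zone, retained)
    all_nodes <- sort(retained, method = "radix")
    prov <- prov[all_nodes]
  }
  structure(list(reports = reports, zone = zone,
                 provenance = data.frame(node = all_nodes,
                                         epicenters = unname(prov),
                                         stringsAsFactors = FALSE)),
            class = "combined_influence_zone")
}

#' Write / read an influence-zone summary table as TSV
#'
#' Column order follows the report schema: Node, Direction, Num_hops,
#' Fold_change, Which_network, then per intermediate slot its node, fold
#' change, significance flag and network label.
#'
#' @param report an [influence_zone()] result.
#' @param path output (input) file path.
#' @return \code{write_influence_zone}: the path, invisibly;
#'   \code{read_influence_zone}: the table as a data frame with the same
#'   column types.
#' @export
write_influence_zone <- function(report, path) {
  stopifnot(inherits(report, "influence_zone_report"))
  tab <- report$table
  num <- vapply(tab, is.numeric, logical(1)) &
    !vapply(tab, is.integer, logical(1))
  for (j in which(num)) {
    v <- tab[[j]]
    tab[[j]] <- ifelse(is.na(v), NA_character_,
                       format(v, digits = 17, trim = TRUE,
                              scientific = FALSE))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_influence_zone
#' @export
read_influence_zone <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = "", colClasses = "character")
  tab[tab == ""] <- NA   # trailing empty intermediate slots
  for (j in grep("^(Num_hops)$", names(tab))) tab[[j]] <- as.integer(tab[[j]])
  for (j in grep("Fold_change|fold_change", names(tab)))
    tab[[j]] <- as.numeric(tab[[j]])
  for (j in grep("significant_fc", names(tab)))
    tab[[j]] <- as.logical(tab[[j]])
  tab
}
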