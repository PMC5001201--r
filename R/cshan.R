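.path_keys <- function(ps) {
  vapply(ps$paths, paste, character(1), collapse = "|")
}

#' Condition-specific highest-activity paths
#'
#' Paths that are highly active in both conditions are uninformative about
#' the perturbation: any path whose exact ordered node sequence appears in
#' both sets is discarded from both (even though its cost differs between
#' conditions). The remainders are the condition-specific highest-activity
#' paths (CSHAPs).
#'
#' @param haps_A,haps_B \code{"hap_set"}s for the two conditions, computed
#'   at the same percentile.
#' @param allow_mismatched_q proceed (with a warning) when the two sets
#'   were filtered at different percentiles.
#' @return a list with \code{unique_A} and \code{unique_B} (\code{hap_set}s
#'   restricted to condition-specific paths) and \code{n_common}, the
#'   number of discarded shared sequences.
#' @export
condition_specific_paths <- function(haps_A, haps_B,
                                     allow_mismatched_q = FALSE) {
  stopifnot(inherits(haps_A, "path_set"), inherits(haps_B, "path_set"))
  qa <- haps_A$q; qb <- haps_B$q
  if (!is.null(qa) && !is.null(qb) && !isTRUE(all.equal(qa, qb))) {
    msg <- paste0("path sets were filtered at different percentiles (",
                  qa, " vs ", qb, ")")
    if (!allow_mismatched_q) stop(msg)
    warning(msg)
  }
  ka <- .path_keys(haps_A)
  kb <- .path_keys(haps_B)
  ia <- !(ka %in% kb)
  ib <- !(kb %in% ka)
  sub <- function(h, keep) {
    h$paths <- h$paths[keep]
    h$costs <- h$costs[keep]
    h
  }
  list(unique_A = sub(haps_A, ia), unique_B = sub(haps_B, ib),
       n_common = sum(!ia))
}

#' Induce the condition-specific highest-activity network (CSHAN)
#'
#' The edges used by a condition's specific paths induce a subgraph of that
#' condition's weighted network. Every edge records how many paths support
#' it; nodes are exactly the endpoints of included edges, so isolated nodes
#' cannot occur.
#'
#' @param paths a \code{"path_set"} (typically \code{unique_A} or
#'   \code{unique_B} from [condition_specific_paths()]).
#' @param network the [build_condition_network()] the paths were computed
#'   on.
#' @return an igraph graph of class \code{c("cshan", "igraph")} with vertex
#'   attribute \code{weight}, edge attributes \code{cost} and
#'   \code{n_paths}, graph attributes \code{condition} and
#'   \code{provenance} (list mapping "u|v" to supporting path indices).
#' @export
induce_cshan <- function(paths, network) {
  stopifnot(inherits(paths, "path_set"), inherits(network, "igraph"))
  np <- length(paths$paths)
  from <- character(0); to <- character(0); pid <- integer(0)
  for (i in seq_len(np)) {
    p <- paths$paths[[i]]
    if (length(p) < 2L) stop("path ", i, " has fewer than 2 nodes")
    from <- c(from, p[-length(p)])
    to <- c(to, p[-1L])
    pid <- c(pid, rep.int(i, length(p) - 1L))
  }
  key <- paste(from, to, sep = "|")
  ukey <- sort(unique(key), method = "radix")
  prov <- lapply(ukey, function(k) sort(unique(pid[key == k])))
  names(prov) <- ukey
  uk <- strsplit(ukey, "|", fixed = TRUE)
  uf <- vapply(uk, `[[`, character(1), 1L)
  ut <- vapply(uk, `[[`, character(1), 2L)
  vn <- igraph::V(network)$name
  if (!all(c(uf, ut) %in% vn))
    stop("path references node(s) absent from the network")
  eid <- suppressWarnings(
    igraph::get_edge_ids(network, rbind(uf, ut), error = FALSE))
  if (length(eid) && any(eid == 0))
    stop("path references edge(s) absent from the network")
  nodes <- sort(unique(c(uf, ut)), method = "radix")
  g <- igraph::graph_from_data_frame(
    data.frame(from = uf, to = ut,
               cost = if (length(eid)) igraph::E(network)$cost[eid]
                      else numeric(0),
               n_paths = lengths(prov), stringsAsFactors = FALSE),
    directed = TRUE, vertices = nodes)
  if (length(nodes))
    igraph::V(g)$weight <-
      igraph::V(network)$weight[match(nodes, vn)]
  g <- igraph::set_graph_attr(g, "condition", paths$condition)
  g <- igraph::set_graph_attr(g, "provenance", prov)
  class(g) <- unique(c("cshan", class(g)))
  g
}

#' @export
print.cshan <- function(x, ...) {
  cat("Condition-specific highest-activity network [",
      igraph::graph_attr(x, "condition"), "]: ",
      igraph::vcount(x), " nodes, ", igraph::ecount(x), " edges\n",
      sep = "")
  invisible(x)
}

#' Export a CSHAN edge list as TSV
#'
#' Columns: condition, source, target, cost, n_supporting_paths.
#'
#' @param cshan a [induce_cshan()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_cshan <- function(cshan, path) {
  stopifnot(inherits(cshan, "cshan"))
  el <- igraph::ends(cshan, igraph::E(cshan), names = TRUE)
  df <- data.frame(condition = rep(igraph::graph_attr(cshan, "condition"),
                                   nrow(el)),
                   source = el[, 1L], target = el[, 2L],
                   cost = igraph::E(cshan)$cost,
                   n_supporting_paths = igraph::E(cshan)$n_paths,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
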