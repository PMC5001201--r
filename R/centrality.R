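# Weighted distance matrix of a CSHAN, rows = sources, outward direction.
.cshan_dist <- function(cshan) {
  nodes <- sort(igraph::V(cshan)$name, method = "radix")
  d <- igraph::distances(cshan, v = nodes, to = nodes, mode = "out",
                         weights = igraph::E(cshan)$cost,
                         algorithm = "dijkstra")
  d[nodes, nodes, drop = FALSE]
}

#' Outward closeness centrality on a CSHAN
#'
#' The raw closeness of node u is the reciprocal of the summed
#' shortest-path costs from u to every node it can reach,
#' \deqn{C(u) = 1 / \sum_v \sigma(u, v),}
#' with sigma the minimum path cost; a node that reaches nothing scores 0.
#' Because edge costs are inverse activities, a node with highly active
#' outgoing paths scores high.
#'
#' On a directed graph where many nodes reach only part of the network,
#' the raw reciprocal sum is dominated by nodes that reach a single cheap
#' neighbor. The normalized score therefore applies the standard
#' Wasserman-Faust correction for partially reachable digraphs -- the
#' reciprocal of the mean cost to the r nodes actually reached, scaled by
#' the reached fraction r/(N-1) -- and is then divided by its maximum so
#' scores lie in [0, 1]:
#' \deqn{C_{norm}(u) \propto \frac{r_u}{\bar\sigma_u} \cdot
#'   \frac{r_u}{N - 1}.}
#' This is the normalization used by standard network libraries for
#' directed closeness.
#'
#' @param cshan an [induce_cshan()] result (any igraph with edge costs).
#' @param normalized return the corrected, max-scaled score (default) or
#'   the raw reciprocal sum.
#' @return named numeric vector over all nodes, lexicographic order.
#' @export
closeness_out <- function(cshan, normalized = TRUE) {
  d <- .cshan_dist(cshan)
  diag(d) <- Inf
  fin <- is.finite(d)
  s <- rowSums(ifelse(fin, d, 0))
  r <- rowSums(fin)
  raw <- ifelse(s > 0, 1 / s, 0)
  names(raw) <- rownames(d)
  if (!normalized) return(raw)
  n <- nrow(d)
  val <- if (n > 1L) raw * r * r / (n - 1L) else raw * 0
  m <- max(val)
  if (m > 0) val / m else val
}

#' Outward reachability on a CSHAN
#'
#' The raw score of node u is the number of nodes v != u with a directed
#' path from u to v; normalized by N - 1 (N = node count), so a node
#' reaching the whole network scores 1.
#'
#' @inheritParams closeness_out
#' @return named numeric vector over all nodes, lexicographic order.
#' @export
outward_reachability <- function(cshan, normalized = TRUE) {
  d <- .cshan_dist(cshan)
  diag(d) <- Inf
  raw <- rowSums(is.finite(d))
  names(raw) <- rownames(d)
  if (!normalized) return(raw)
  n <- nrow(d)
  if (n > 1L) raw / (n - 1L) else raw * 0
}

#' Ripple centrality of every CSHAN node
#'
#' Ripple centrality is a logical AND of activity and spread: the product
#' of normalized outward closeness and normalized outward reachability,
#' \deqn{ripple(u) = C_{norm}(u) \cdot R_{out,norm}(u).}
#' A node with highly active paths to only a few targets, or with wide
#' reach only through weak paths, scores low; an effective epicenter needs
#' both.
#'
#' @param cshan an [induce_cshan()] result.
#' @return a data frame with columns \code{gene}, \code{closeness},
#'   \code{reachability} (both normalized), \code{ripple}, in lexicographic
#'   gene order.
#' @export
ripple_centrality <- function(cshan) {
  if (igraph::vcount(cshan) == 0L) stop("empty network")
  cl <- closeness_out(cshan)
  ro <- outward_reachability(cshan)
  data.frame(gene = names(cl), closeness = as.numeric(cl),
             reachability = as.numeric(ro),
             ripple = as.numeric(cl) * as.numeric(ro),
             stringsAsFactors = FALSE)
}

# Competition ranking of scores sorted descending; scores equal within
# relative tolerance `tol` (chained) share one rank and the next rank skips
# the group size. Ties in sort order are broken by gene name so the listing
# is deterministic.
.rank_with_ties <- function(genes, scores, tol = 1e-9) {
  o <- order(-scores, genes, method = "radix")
  genes <- genes[o]; scores <- scores[o]
  n <- length(scores)
  rank <- integer(n)
  if (n == 0L) return(data.frame(rank = integer(0), gene = character(0),
                                 score = numeric(0)))
  grp_start <- 1L
  rank[1L] <- 1L
  for (i in seq_len(n)[-1L]) {
    ref <- scores[grp_start]
    if (abs(ref - scores[i]) <= tol * max(abs(ref), abs(scores[i]), 1e-300)) {
      rank[i] <- rank[grp_start]
    } else {
      rank[i] <- i
      grp_start <- i
    }
  }
  data.frame(rank = rank, gene = genes, score = scores,
             stringsAsFactors = FALSE)
}

#' Rank CSHAN nodes and split them into specific and global epicenters
#'
#' Ripple centrality is computed on the analyzed CSHAN and the scored nodes
#' are split into (a) nodes absent from the other condition's CSHAN --
#' candidates specific to the analyzed condition -- and (b) nodes present
#' in both CSHANs -- global epicenters, which participate in different
#' paths in each condition (re-wired). Competition ranks are assigned
#' within each list (near-equal scores share a rank and the next rank
#' skips), and each list is truncated at rank <= \code{top_k}, keeping
#' whole tie groups, so a list may contain more than \code{top_k} genes.
#'
#' @param cshan_analyzed the CSHAN to score.
#' @param cshan_other the other condition's CSHAN (may be empty).
#' @param top_k rank cutoff for the returned lists (default 10).
#' @param tie_tol relative tolerance under which two scores tie.
#' @return a list of class \code{"epicenter_ranking"} with data frames
#'   \code{specific} and \code{global} (columns \code{rank}, \code{gene},
#'   \code{ripple}, \code{closeness}, \code{reachability},
#'   \code{membership}) and \code{scores}, the full ripple table.
#' @export
get_epicenters <- function(cshan_analyzed, cshan_other, top_k = 10,
                           tie_tol = 1e-9) {
  if (!is.numeric(top_k) || length(top_k) != 1L || top_k < 1)
    stop("'top_k' must be >= 1")
  if (igraph::vcount(cshan_analyzed) == 0L)
    stop("analyzed CSHAN is empty; consider a larger percentile cutoff")
  sc <- ripple_centrality(cshan_analyzed)
  other_nodes <- if (is.null(cshan_other)) character(0)
                 else igraph::V(cshan_other)$name
  memb <- ifelse(sc$gene %in% other_nodes, "global", "specific")
  one <- function(which) {
    sel <- memb == which
    r <- .rank_with_ties(sc$gene[sel], sc$ripple[sel], tol = tie_tol)
    r <- r[r$rank <= top_k, , drop = FALSE]
    i <- match(r$gene, sc$gene)
    data.frame(rank = r$rank, gene = r$gene, ripple = r$score,
               closeness = sc$closeness[i],
               reachability = sc$reachability[i],
               membership = rep(which, nrow(r)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(specific = one("specific"), global = one("global"),
                 scores = sc, top_k = top_k,
                 condition = igraph::graph_attr(cshan_analyzed, "condition")),
            class = "epicenter_ranking")
}

#' @export
print.epicenter_ranking <- function(x, ...) {
  cat("Epicenter ranking [", x$condition, "], top_k = ", x$top_k, "\n",
      sep = "")
  cat("Specific epicenters (", nrow(x$specific), " genes):\n", sep = "")
  print(utils::head(x$specific, 15), row.names = FALSE)
  cat("Global epicenters (", nrow(x$global), " genes):\n", sep = "")
  print(utils::head(x$global, 15), row.names = FALSE)
  invisible(x)
}

#' Largest strongly connected component membership of ranked nodes
#'
#' Epicenters are empirically found inside the largest strongly connected
#' component (LSCC) of the highest-activity network under study; this
#' report annotates a ranking with LSCC membership and the LSCC/graph
#' sizes.
#'
#' @param cshan the CSHAN the ranking was computed on.
#' @param ranking an [get_epicenters()] result, or NULL to annotate every
#'   node.
#' @return a data frame \code{gene}, \code{in_lscc} (plus ranking columns
#'   when a ranking is given) with attributes \code{lscc_size} and
#'   \code{graph_size}.
#' @export
lscc_report <- function(cshan, ranking = NULL) {
  comp <- igraph::components(cshan, mode = "strong")
  lscc_id <- which.max(comp$csize)
  # a trivial "component" of one node is not a strongly connected core
  members <- if (length(comp$csize) && max(comp$csize) >= 2)
    igraph::V(cshan)$name[comp$membership == lscc_id]
  else character(0)
  if (is.null(ranking)) {
    genes <- sort(igraph::V(cshan)$name, method = "radix")
    out <- data.frame(gene = genes, in_lscc = genes %in% members,
                      stringsAsFactors = FALSE)
  } else {
    stopifnot(inherits(ranking, "epicenter_ranking"))
    tab <- rbind(ranking$specific, ranking$global)
    out <- cbind(tab, in_lscc = tab$gene %in% members)
  }
  structure(out, lscc_size = max(comp$csize),
            graph_size = igraph::vcount(cshan),
            class = c("lscc_report", "data.frame"))
}
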