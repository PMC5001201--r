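# CSR view of a condition network with vertices in lexicographic order,
# as consumed by the compiled Dijkstra kernel.
.cn_csr <- function(net) {
  stopifnot(inherits(net, "igraph"))
  nodes <- sort(igraph::V(net)$name, method = "radix")
  n <- length(nodes)
  el <- igraph::ends(net, igraph::E(net), names = TRUE)
  cost <- igraph::E(net)$cost
  if (is.null(cost)) stop("network has no edge costs; build it with ",
                          "build_condition_network()")
  if (nrow(el) > 0L) {
    from <- match(el[, 1L], nodes)
    to <- match(el[, 2L], nodes)
    o <- order(from, to, method = "radix")
    from <- from[o]; to <- to[o]; cost <- cost[o]
    ptr <- c(0L, cumsum(tabulate(from, nbins = n)))
  } else {
    from <- integer(0); to <- integer(0); cost <- numeric(0)
    ptr <- integer(n + 1L)
  }
  list(nodes = nodes, n = n, ptr = as.integer(ptr),
       adj = as.integer(to - 1L), w = as.numeric(cost))
}

.path_set <- function(paths, costs, condition) {
  structure(list(condition = condition, paths = paths,
                 costs = as.numeric(costs)),
            class = "path_set")
}

#' All-pairs highest-activity paths of a condition network
#'
#' For every ordered pair of nodes (s, t), s != t, computes the single
#' minimum-cost directed path from s to t by Dijkstra's algorithm and
#' retains it when it has at least 2 edges (single-edge paths carry no
#' ripple information). Cost ties are broken deterministically: vertices
#' are indexed in lexicographic order and the relaxation keeps the first
#' strictly-better path, so repeated runs return identical paths.
#'
#' The path cost is the sum of its edge costs,
#' \deqn{pathcost = \sum_i c_i,} so minimum cost means highest activity.
#'
#' @param net a [build_condition_network()] result.
#' @return a \code{"path_set"}: list with \code{condition}, \code{paths}
#'   (list of character vectors of node names) and \code{costs}.
#' @seealso [highest_activity_paths()] for the percentile-filtered set
#'   without materializing all pairs.
#' @export
all_pairs_highest_activity <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  csr <- .cn_csr(net)
  res <- cpp_hap_paths(csr$n, csr$ptr, csr$adj, csr$w, Inf)
  paths <- lapply(res$paths, function(ix) csr$nodes[ix])
  .path_set(paths, res$costs, igraph::graph_attr(net, "condition"))
}

.percentile_cutoff <- function(costs, q) {
  n <- length(costs)
  k <- ceiling(q / 100 * n)
  sort(costs, method = "radix")[k]
}

#' Retain the paths inside a percentile cost threshold
#'
#' Given all candidate highest-activity paths, retains those whose cost
#' falls inside the q-th percentile of the ascending cost ranking: with N
#' paths, the realized cutoff is the k-th smallest cost, k = ceiling(q/100
#' * N), and every path with cost <= cutoff is kept (boundary ties are all
#' retained, so at least k paths survive). The conservative default used
#' throughout is q = 0.1.
#'
#' @param paths a \code{"path_set"} from [all_pairs_highest_activity()].
#' @param q percentile in (0, 100].
#' @return a \code{"hap_set"}: a path set sorted ascending by cost, with
#'   elements \code{q} and \code{cutoff} (the realized cost cutoff).
#' @export
percentile_filter <- function(paths, q = 0.1) {
  if (!inherits(paths, "path_set")) stop("'paths' must be a path_set")
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q > 100)
    stop("'q' must be a percentile in (0, 100]")
  if (length(paths$costs) == 0L)
    stop("no candidate paths: the network may be too sparse or ",
         "disconnected (no pair is >= 2 hops apart)")
  cutoff <- .percentile_cutoff(paths$costs, q)
  keep <- which(paths$costs <= cutoff)
  kp <- paths$paths[keep]
  kc <- paths$costs[keep]
  key <- vapply(kp, paste, character(1), collapse = "|")
  o <- order(kc, key, method = "radix")
  structure(list(condition = paths$condition, paths = kp[o],
                 costs = kc[o], q = q, cutoff = cutoff),
            class = c("hap_set", "path_set"))
}

#' Highest-activity paths at a percentile cutoff (streamed)
#'
#' Equivalent to \code{percentile_filter(all_pairs_highest_activity(net),
#' q)} but never materializes all O(V^2) paths: a first sweep streams only
#' the per-pair path costs, the realized percentile cutoff is computed, and
#' a second sweep reconstructs just the paths at or below it.
#'
#' @inheritParams all_pairs_highest_activity
#' @inheritParams percentile_filter
#' @return a \code{"hap_set"} (see [percentile_filter()]).
#' @export
highest_activity_paths <- function(net, q = 0.1) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q > 100)
    stop("'q' must be a percentile in (0, 100]")
  if (igraph::vcount(net) == 0L) stop("empty network")
  csr <- .cn_csr(net)
  costs <- cpp_hap_costs(csr$n, csr$ptr, csr$adj, csr$w)
  if (length(costs) == 0L)
    stop("no candidate paths: the network may be too sparse or ",
         "disconnected (no pair is >= 2 hops apart)")
  cutoff <- .percentile_cutoff(costs, q)
  res <- cpp_hap_paths(csr$n, csr$ptr, csr$adj, csr$w, cutoff)
  kp <- lapply(res$paths, function(ix) csr$nodes[ix])
  kc <- res$costs
  key <- vapply(kp, paste, character(1), collapse = "|")
  o <- order(kc, key, method = "radix")
  structure(list(condition = igraph::graph_attr(net, "condition"),
                 paths = kp[o], costs = kc[o], q = q, cutoff = cutoff),
            class = c("hap_set", "path_set"))
}

#' @export
print.path_set <- function(x, ...) {
  cat(if (inherits(x, "hap_set")) "Highest-activity path set"
      else "Path set",
      " [", x$condition, "]: ", length(x$paths), " paths", sep = "")
  if (!is.null(x$q))
    cat(", percentile ", x$q, ", realized cutoff ",
        format(x$cutoff, digits = 6), sep = "")
  cat("\n")
  invisible(x)
}

#' Write / read a highest-activity path set as TSV
#'
#' One path per line: \code{condition<TAB>cost<TAB>node1|node2|...}.
#'
#' @param haps a \code{"hap_set"} or \code{"path_set"}.
#' @param path output (input) file path.
#' @return \code{write_hap_set}: the path, invisibly; \code{read_hap_set}:
#'   a \code{"path_set"}.
#' @export
write_hap_set <- function(haps, path) {
  stopifnot(inherits(haps, "path_set"))
  lines <- paste(haps$condition,
                 format(haps$costs, digits = 17, trim = TRUE,
                        scientific = FALSE),
                 vapply(haps$paths, paste, character(1), collapse = "|"),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hap_set
#' @export
read_hap_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) stop("malformed path-set file: ", path)
  .path_set(paths = lapply(parts, function(p)
                           strsplit(p[3L], "|", fixed = TRUE)[[1L]]),
            costs = as.numeric(vapply(parts, `[[`, character(1), 2L)),
            condition = parts[[1L]][1L])
}
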