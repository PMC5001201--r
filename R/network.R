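#' Cost of a directed interaction between two expressed genes
#'
#' Under a mass-action view of network activity, the activity of an
#' interaction is proportional to the abundance of its participants, here
#' approximated by normalized signal intensities on the linear scale. The
#' cost of the directed edge (u, v) is the inverse of the geometric mean of
#' the endpoint intensities,
#' \deqn{c(u, v) = 1 / \sqrt{w_u \, w_v},}
#' so that a highly active interaction has a very low cost and minimum-cost
#' paths are highest-activity paths.
#'
#' @param w_u,w_v strictly positive numeric vectors of node weights
#'   (normalized linear-scale signal intensities); recycled to a common
#'   length.
#' @return numeric vector of edge costs, finite and strictly positive.
#' @examples
#' edge_cost(4, 9)      # 1/6
#' edge_cost(100, 100)  # 0.01
#' @export
edge_cost <- function(w_u, w_v) {
  if (!is.numeric(w_u) || !is.numeric(w_v))
    stop("node weights must be numeric")
  if (any(!is.finite(w_u)) || any(!is.finite(w_v)) ||
      any(w_u <= 0) || any(w_v <= 0))
    stop("node weights must be finite and strictly positive")
  1 / sqrt(w_u * w_v)
}

#' Construct an expression profile for one condition
#'
#' An expression profile maps gene identifiers to normalized signal
#' intensities on the linear scale. Intensities must be strictly positive
#' (edge costs diverge at zero); non-positive values are rejected, or
#' floored to \code{min(positive) * 1e-3} when \code{floor_nonpositive}.
#'
#' @param values named numeric vector, one intensity per gene.
#' @param condition condition label, e.g. \code{"control"}.
#' @param floor_nonpositive replace non-positive intensities by a small
#'   positive floor instead of raising an error.
#' @return a named numeric vector of class \code{"expression_profile"} with
#'   a \code{condition} attribute.
#' @export
expression_profile <- function(values, condition, floor_nonpositive = FALSE) {
  if (!is.numeric(values) || is.null(names(values)) ||
      any(!nzchar(names(values))) || anyNA(names(values)))
    stop("'values' must be a numeric vector named by gene identifiers")
  if (anyDuplicated(names(values)))
    stop("duplicate gene identifiers in expression profile")
  if (!is.character(condition) || length(condition) != 1L || !nzchar(condition))
    stop("'condition' must be a non-empty string")
  if (anyNA(values)) stop("missing intensities are not allowed")
  bad <- values <= 0
  if (any(bad)) {
    if (!floor_nonpositive)
      stop(sum(bad), " non-positive intensities; intensities must be > 0 ",
           "(use floor_nonpositive = TRUE to floor them)")
    eps <- min(values[values > 0]) * 1e-3
    if (!is.finite(eps) || eps <= 0)
      stop("cannot floor: no positive intensities present")
    values[bad] <- eps
  }
  structure(values, condition = condition, class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("Expression profile [", attr(x, "condition"), "]: ", length(x),
      " genes, intensity range ", format(min(x), digits = 4), "-",
      format(max(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Read an expression table
#'
#' Reads a tab-separated table with a header line, gene identifiers in the
#' first column and sample intensities in the remaining columns. Replicate
#' columns belonging to the condition are collapsed by their arithmetic
#' mean. Intensities are expected on the linear scale; set
#' \code{unlog2 = TRUE} for log2-scale input.
#'
#' @param path path to the TSV file.
#' @param condition condition label attached to the returned profile.
#' @param columns column names or indices (into the sample columns) to use;
#'   default all sample columns.
#' @param unlog2 if TRUE, intensities are transformed by \code{2^x} before
#'   averaging.
#' @param floor_nonpositive passed to [expression_profile()].
#' @return an [expression_profile()].
#' @export
read_expression <- function(path, condition, columns = NULL, unlog2 = FALSE,
                            floor_nonpositive = FALSE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs >= 2 columns: ", path)
  genes <- as.character(tab[[1L]])
  vals <- tab[, -1L, drop = FALSE]
  if (!is.null(columns)) vals <- vals[, columns, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1))))
    stop("non-numeric intensity column in ", path)
  m <- as.matrix(vals)
  if (unlog2) m <- 2^m
  expression_profile(stats::setNames(rowMeans(m), genes), condition,
                     floor_nonpositive = floor_nonpositive)
}

#' Construct a base interaction network
#'
#' Builds the directed base network from an edge table. Self-loops and
#' duplicate directed edges are dropped (with a message reporting the
#' counts); node identifiers are opaque, case-sensitive, non-empty strings.
#'
#' @param edges a two- or three-column data frame or character matrix:
#'   source, target, optional interaction-type label.
#' @return an igraph directed graph of class \code{c("base_network",
#'   "igraph")}, with graph attributes \code{dropped_self_loops} and
#'   \code{dropped_duplicate_edges}.
#' @export
base_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) stop("empty edge list")
  if (ncol(edges) < 2L) stop("edge table needs at least source and target")
  src <- as.character(edges[[1L]])
  tgt <- as.character(edges[[2L]])
  if (anyNA(src) || anyNA(tgt) || any(!nzchar(src)) || any(!nzchar(tgt)))
    stop("node identifiers must be non-empty strings")
  type <- if (ncol(edges) >= 3L) as.character(edges[[3L]]) else NULL
  loops <- src == tgt
  n_loops <- sum(loops)
  if (n_loops > 0L)
    message("dropped ", n_loops, " self-loop(s)")
  keep_nodes <- sort(unique(c(src, tgt)), method = "radix")
  src2 <- src[!loops]; tgt2 <- tgt[!loops]
  if (!is.null(type)) type <- type[!loops]
  dup <- duplicated(paste(src2, tgt2, sep = "\r"))
  n_dup <- sum(dup)
  if (n_dup > 0L)
    message("dropped ", n_dup, " duplicate directed edge(s)")
  df <- data.frame(from = src2[!dup], to = tgt2[!dup],
                   stringsAsFactors = FALSE)
  if (!is.null(type)) df$type <- type[!dup]
  g <- igraph::graph_from_data_frame(df, directed = TRUE,
                                     vertices = keep_nodes)
  g <- igraph::set_graph_attr(g, "dropped_self_loops", n_loops)
  g <- igraph::set_graph_attr(g, "dropped_duplicate_edges", n_dup)
  class(g) <- unique(c("base_network", class(g)))
  g
}

#' Read a directed network from a TSV or SIF edge list
#'
#' TSV format: \code{source<TAB>target[<TAB>type]}, one directed edge per
#' line, no header. SIF format: \code{source<TAB>relation<TAB>target}.
#' Comment lines starting with \code{#} are ignored.
#'
#' @param path path to the file.
#' @param format \code{"tsv"} (default) or \code{"sif"}.
#' @return a [base_network()].
#' @export
read_edge_list <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty edge-list file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  min_fields <- if (format == "sif") 3L else 2L
  bad <- which(nf < min_fields)
  if (length(bad))
    stop("malformed line ", bad[1L], " in ", path, ": expected >= ",
         min_fields, " tab-separated fields")
  get <- function(i) vapply(parts, `[[`, character(1), i)
  if (format == "sif") {
    edges <- data.frame(from = get(1L), to = get(3L), type = get(2L),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = get(1L), to = get(2L),
                        stringsAsFactors = FALSE)
    if (all(nf >= 3L)) edges$type <- get(3L)
  }
  base_network(edges)
}

#' Map an expression profile onto the base network
#'
#' Produces the weighted network for one condition: nodes are the base
#' nodes with an expression value (unmapped nodes are dropped with their
#' incident edges, counts reported), node weight is the intensity, and each
#' directed edge carries cost \code{1/sqrt(w_u * w_v)} ([edge_cost()]).
#'
#' @param base a [base_network()].
#' @param expr an [expression_profile()].
#' @return an igraph graph of class \code{c("condition_network", "igraph")}
#'   with vertex attribute \code{weight}, edge attribute \code{cost}, and
#'   graph attributes \code{condition}, \code{dropped_nodes},
#'   \code{dropped_edges}.
#' @export
build_condition_network <- function(base, expr) {
  stopifnot(inherits(base, "igraph"), inherits(expr, "expression_profile"))
  nodes <- igraph::V(base)$name
  mapped <- intersect(nodes, names(expr))
  if (length(mapped) == 0L)
    stop("no overlap between expression genes and network nodes")
  n_drop_nodes <- length(nodes) - length(mapped)
  g <- igraph::induced_subgraph(base, mapped)
  n_drop_edges <- igraph::ecount(base) - igraph::ecount(g)
  if (n_drop_nodes > 0L)
    message("dropped ", n_drop_nodes, " node(s) without expression (",
            n_drop_edges, " incident edge(s))")
  w <- as.numeric(expr[igraph::V(g)$name])
  igraph::V(g)$weight <- w
  el <- igraph::ends(g, igraph::E(g), names = FALSE)
  if (nrow(el) > 0L) {
    igraph::E(g)$cost <- edge_cost(w[el[, 1L]], w[el[, 2L]])
  } else {
    g <- igraph::set_edge_attr(g, "cost", value = numeric(0))
  }
  g <- igraph::set_graph_attr(g, "condition", attr(expr, "condition"))
  g <- igraph::set_graph_attr(g, "dropped_nodes", n_drop_nodes)
  g <- igraph::set_graph_attr(g, "dropped_edges", n_drop_edges)
  class(g) <- unique(c("condition_network", setdiff(class(g), "base_network")))
  g
}

#' Is a fold change significant at a symmetric cutoff?
#'
#' A fold change f is called significant at cutoff c when f >= c or
#' f <= 1/c (at least c-fold up or down).
#'
#' @param fc numeric vector of fold changes (> 0).
#' @param cutoff fold-change cutoff, > 1.
#' @return logical vector.
#' @export
significant_fc <- function(fc, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 1)
    stop("'cutoff' must be a single number > 1")
  fc >= cutoff | fc <= 1 / cutoff
}

#' Fold changes between two conditions
#'
#' Computes per-gene fold change perturbed/control on the shared gene set,
#' a direction flag, and a significance flag at a symmetric cutoff
#' (default 1.5, the usual differential-expression annotation cutoff;
#' influence-zone summaries use 2.0).
#'
#' @param control,perturbed [expression_profile()]s sharing >= 1 gene.
#' @param cutoff fold-change cutoff, > 1.
#' @return a data frame of class \code{"fold_change_table"} with columns
#'   \code{gene}, \code{fold_change}, \code{direction} (up/down),
#'   \code{significant}; the cutoff is kept as attribute \code{cutoff}.
#' @export
fold_changes <- function(control, perturbed, cutoff = 1.5) {
  stopifnot(inherits(control, "expression_profile"),
            inherits(perturbed, "expression_profile"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 1)
    stop("'cutoff' must be a single number > 1")
  shared <- intersect(names(control), names(perturbed))
  if (length(shared) == 0L) stop("profiles share no genes")
  shared <- sort(shared, method = "radix")
  fc <- as.numeric(perturbed[shared]) / as.numeric(control[shared])
  out <- data.frame(gene = shared, fold_change = fc,
                    direction = ifelse(fc >= 1, "up", "down"),
                    significant = significant_fc(fc, cutoff),
                    stringsAsFactors = FALSE)
  structure(out, cutoff = cutoff,
            class = c("fold_change_table", "data.frame"))
}

#' Export a graph as GraphML
#'
#' @param graph any igraph-based graph produced by this package.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "igraph"))
  g <- graph
  class(g) <- "igraph"
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
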