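#' Trace epicenters in a condition-specific interaction network
#'
#' Runs the full epicenter-detection pipeline on a directed interaction
#' network and a control/perturbed pair of expression profiles:
#' \enumerate{
#'   \item each profile is mapped onto the network, giving one weighted
#'     network per condition with edge cost \code{1/sqrt(w_u * w_v)};
#'   \item all-pairs highest-activity (minimum-cost) paths with at least
#'     2 edges are extracted per condition and filtered at the
#'     \code{percentile} cost cutoff (default 0.1, conservative);
#'   \item paths whose exact node sequence occurs in both conditions are
#'     discarded; the remaining condition-specific paths induce each
#'     condition's highest-activity network (CSHAN);
#'   \item CSHAN nodes are scored by ripple centrality (normalized
#'     outward closeness x normalized outward reachability) and split
#'     into epicenters specific to the analyzed condition and global
#'     (re-wired) epicenters, truncated at rank \code{top_k}.
#' }
#' Analyzing the perturbed CSHAN suits upregulation-type perturbations;
#' for a knockdown, the control CSHAN shows the regulators that lost
#' influence. With \code{analyze = "both"} both are ranked.
#'
#' @param network a [base_network()] (or any igraph directed graph with
#'   named vertices).
#' @param control,perturbed [expression_profile()]s for the two
#'   conditions.
#' @param percentile path-cost percentile retained per condition, in
#'   (0, 100].
#' @param top_k rank cutoff for the epicenter lists (default 10).
#' @param analyze which CSHAN to rank: \code{"perturbed"} (default),
#'   \code{"control"}, or \code{"both"}.
#' @param deg_cutoff fold-change cutoff used for the differential
#'   expression annotation attached to the fit (default 1.5).
#' @param verbose print per-stage progress messages.
#' @return an object of class \code{"epitracer"}: a list with
#'   \code{networks} and \code{haps} (per condition), \code{cshaps}
#'   (condition-specific path sets), \code{cshans}, \code{rankings} (per
#'   analyzed condition: \code{specific}, \code{global}, \code{scores}),
#'   \code{lscc} (per analyzed condition), \code{fold_changes},
#'   \code{profiles}, \code{params}, and \code{call}.
#' @examples
#' case <- generate_case(N = 60, seed = 7)
#' fit <- epitracer(case$network, case$control, case$perturbed,
#'                  percentile = 2)
#' fit
#' @export
epitracer <- function(network, control, perturbed, percentile = 0.1,
                      top_k = 10,
                      analyze = c("perturbed", "control", "both"),
                      deg_cutoff = 1.5, verbose = FALSE) {
  analyze <- match.arg(analyze)
  cl <- match.call()
  say <- function(...) if (verbose) message(...)

  say("mapping expression onto the network")
  nets <- list(
    control = suppressMessages(build_condition_network(network, control)),
    perturbed = suppressMessages(build_condition_network(network,
                                                         perturbed)))
  say("extracting highest-activity paths (percentile ", percentile, ")")
  haps <- lapply(nets, highest_activity_paths, q = percentile)
  say("  retained ", length(haps$control$paths), " control / ",
      length(haps$perturbed$paths), " perturbed paths")

  csp <- condition_specific_paths(haps$control, haps$perturbed)
  cshaps <- list(control = csp$unique_A, perturbed = csp$unique_B)
  say("  ", length(cshaps$control$paths), " control-specific and ",
      length(cshaps$perturbed$paths), " perturbed-specific paths (",
      csp$n_common, " common, discarded)")

  cshans <- list(
    control = induce_cshan(cshaps$control, nets$control),
    perturbed = induce_cshan(cshaps$perturbed, nets$perturbed))
  say("  CSHAN sizes: control ", igraph::vcount(cshans$control),
      " nodes, perturbed ", igraph::vcount(cshans$perturbed), " nodes")

  dirs <- if (analyze == "both") c("perturbed", "control") else analyze
  rankings <- list(); lscc <- list()
  for (dr in dirs) {
    other <- setdiff(c("perturbed", "control"), dr)
    rankings[[dr]] <- get_epicenters(cshans[[dr]], cshans[[other]],
                                     top_k = top_k)
    lscc[[dr]] <- lscc_report(cshans[[dr]], rankings[[dr]])
  }

  structure(list(networks = nets, haps = haps, cshaps = cshaps,
                 cshans = cshans, rankings = rankings, lscc = lscc,
                 fold_changes = fold_changes(control, perturbed,
                                             cutoff = deg_cutoff),
                 profiles = list(control = control, perturbed = perturbed),
                 params = list(percentile = percentile, top_k = top_k,
                               analyze = analyze, deg_cutoff = deg_cutoff),
                 analyze = dirs, n_common_paths = csp$n_common,
                 call = cl),
            class = "epitracer")
}

#' @export
print.epitracer <- function(x, ...) {
  cat("Epicenter analysis (percentile ", x$params$percentile,
      ", top_k ", x$params$top_k, ")\n", sep = "")
  cat("  HAPs: ", length(x$haps$control$paths), " control, ",
      length(x$haps$perturbed$paths), " perturbed (",
      x$n_common_paths, " common)\n", sep = "")
  for (dr in x$analyze) {
    sp <- x$rankings[[dr]]$specific
    cat("  top epicenters specific to ", dr, ": ",
        paste(utils::head(sp$gene, 5), collapse = ", "),
        if (nrow(sp) > 5) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Summary of an epicenter analysis
#'
#' Mirrors the pipeline's stage reporting: paths retained per condition,
#' condition-specific path counts, CSHAN sizes, differential-expression
#' counts inside the analyzed CSHAN, and the epicenter lists with LSCC
#' membership.
#'
#' @param object an [epitracer()] fit.
#' @param ... unused.
#' @return an object of class \code{"summary.epitracer"}.
#' @export
summary.epitracer <- function(object, ...) {
  x <- object
  fc <- x$fold_changes
  deg_in <- function(cshan) {
    g <- intersect(igraph::V(cshan)$name, fc$gene[fc$significant])
    d <- fc$direction[match(g, fc$gene)]
    c(down = sum(d == "down"), up = sum(d == "up"))
  }
  out <- list(
    params = x$params,
    n_haps = c(control = length(x$haps$control$paths),
               perturbed = length(x$haps$perturbed$paths)),
    n_cshaps = c(control = length(x$cshaps$control$paths),
                 perturbed = length(x$cshaps$perturbed$paths)),
    n_common = x$n_common_paths,
    cshan_sizes = vapply(x$cshans, function(g)
      c(nodes = igraph::vcount(g), edges = igraph::ecount(g)),
      numeric(2)),
    deg_in_cshan = vapply(x$cshans, deg_in, numeric(2)),
    rankings = x$rankings, lscc = x$lscc, analyze = x$analyze)
  class(out) <- "summary.epitracer"
  out
}

#' @export
print.summary.epitracer <- function(x, ...) {
  cat("Highest-activity paths (percentile ", x$params$percentile, "): ",
      x$n_haps["control"], " control, ", x$n_haps["perturbed"],
      " perturbed\n", sep = "")
  cat("Condition-specific paths: ", x$n_cshaps["control"], " control, ",
      x$n_cshaps["perturbed"], " perturbed (", x$n_common,
      " common paths discarded)\n", sep = "")
  for (cn in colnames(x$cshan_sizes))
    cat("CSHAN [", cn, "]: ", x$cshan_sizes["nodes", cn], " nodes, ",
        x$cshan_sizes["edges", cn], " edges; ",
        x$deg_in_cshan["down", cn], " down / ",
        x$deg_in_cshan["up", cn], " upregulated genes (",
        x$params$deg_cutoff, "-fold)\n", sep = "")
  for (dr in x$analyze) {
    cat("\nEpicenters specific to ", dr, " (LSCC: ",
        attr(x$lscc[[dr]], "lscc_size"), "/",
        attr(x$lscc[[dr]], "graph_size"), " nodes):\n", sep = "")
    print(x$rankings[[dr]]$specific, row.names = FALSE)
    cat("Global epicenters:\n")
    print(x$rankings[[dr]]$global, row.names = FALSE)
  }
  invisible(x)
}

#' Plot the top epicenter scores of a fit
#'
#' Horizontal bars of ripple centrality for the top-ranked specific and
#' global epicenters of the analyzed condition, with the two factors
#' (closeness, reachability) overplotted as points.
#'
#' @param x an [epitracer()] fit.
#' @param which condition to plot (default the first analyzed).
#' @param ... passed to [graphics::barplot()].
#' @return \code{x}, invisibly.
#' @export
plot.epitracer <- function(x, which = x$analyze[1L], ...) {
  rk <- x$rankings[[which]]
  if (is.null(rk)) stop("condition '", which, "' was not analyzed")
  tab <- rbind(rk$specific, rk$global)
  tab <- tab[order(tab$ripple), , drop = FALSE]
  op <- graphics::par(mar = c(4, 7, 2, 1))
  on.exit(graphics::par(op))
  mid <- graphics::barplot(tab$ripple, names.arg = tab$gene, horiz = TRUE,
                           las = 1, xlab = "ripple centrality",
                           col = ifelse(tab$membership == "specific",
                                        "steelblue", "grey70"),
                           main = paste0("Epicenters [", which, "]"), ...)
  graphics::points(tab$closeness, mid, pch = 1)
  graphics::points(tab$reachability, mid, pch = 4)
  graphics::legend("bottomright",
                   legend = c("specific", "global", "closeness",
                              "reachability"),
                   fill = c("steelblue", "grey70", NA, NA),
                   border = c("black", "black", NA, NA),
                   pch = c(NA, NA, 1, 4), bty = "n")
  invisible(x)
}

#' Extract an epicenter ranking table from a fit
#'
#' @param object an [epitracer()] fit.
#' @param which condition (default the first analyzed).
#' @param list \code{"specific"}, \code{"global"}, or \code{"scores"}
#'   (the full unsplit score table).
#' @return a data frame.
#' @export
epicenters <- function(object, which = object$analyze[1L],
                       list = c("specific", "global", "scores")) {
  stopifnot(inherits(object, "epitracer"))
  list <- match.arg(list)
  rk <- object$rankings[[which]]
  if (is.null(rk)) stop("condition '", which, "' was not analyzed")
  rk[[list]]
}

#' Write an epicenter ranking as TSV
#'
#' Columns: rank, gene, ripple, closeness, reachability, membership,
#' in_lscc, fold_change.
#'
#' @param object an [epitracer()] fit.
#' @param path output file path.
#' @param which condition (default the first analyzed).
#' @param list \code{"specific"} or \code{"global"}.
#' @return the path, invisibly.
#' @export
write_ranking <- function(object, path, which = object$analyze[1L],
                          list = c("specific", "global")) {
  stopifnot(inherits(object, "epitracer"))
  list <- match.arg(list)
  tab <- object$rankings[[which]][[list]]
  lr <- object$lscc[[which]]
  tab$in_lscc <- lr$in_lscc[match(tab$gene, lr$gene)]
  fc <- object$fold_changes
  tab$fold_change <- fc$fold_change[match(tab$gene, fc$gene)]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
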