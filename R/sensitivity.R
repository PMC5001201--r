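#' Perturb an expression profile by bounded multiplicative noise
#'
#' Emulates detector variability: each gene's intensity is independently
#' multiplied by (1 + u) (direction \code{"up"}) or (1 - u) (direction
#' \code{"down"}), with u drawn uniformly from [0, \code{max_frac}). Draws
#' come from a counter-based stream keyed by (seed, repetition, direction,
#' condition, gene), so the value a gene receives does not depend on the
#' order genes are stored in.
#'
#' @param expr an [expression_profile()].
#' @param direction \code{"up"} or \code{"down"}.
#' @param max_frac maximum perturbed fraction, in [0, 1).
#' @param seed master seed (integer).
#' @param rep repetition index (integer, default 1).
#' @return a perturbed [expression_profile()] with the same genes and
#'   condition label.
#' @export
perturb_profile <- function(expr, direction = c("up", "down"),
                            max_frac = 0.05, seed = 1L, rep = 1L) {
  stopifnot(inherits(expr, "expression_profile"))
  direction <- match.arg(direction)
  if (!is.numeric(max_frac) || length(max_frac) != 1L || max_frac < 0 ||
      max_frac >= 1)
    stop("'max_frac' must be in [0, 1) (a down-perturbation of 100% or ",
         "more would produce non-positive intensities)")
  genes <- names(expr)
  u <- cpp_keyed_uniform(as.integer(seed), as.integer(rep), direction,
                         attr(expr, "condition"), genes) * max_frac
  factor <- if (direction == "up") 1 + u else 1 - u
  expression_profile(stats::setNames(as.numeric(expr) * factor, genes),
                     attr(expr, "condition"))
}

#' Rank-stability (sensitivity) analysis of epicenter detection
#'
#' Repeats the full pipeline on noise-perturbed inputs and quantifies how
#' stable the epicenter lists are. Per repetition, BOTH condition profiles
#' are independently perturbed by up to \code{max_frac} (default 5%) in
#' the given direction and epicenters are recomputed. Aggregates report,
#' per top-k of interest, the set of genes present in the top k of the
#' specific list in every repetition, and per-gene mean rank and top-k
#' frequency. Given the same master seed the report is reproducible
#' bit-for-bit; repetitions are independent of each other and of
#' evaluation order.
#'
#' @param network a [base_network()].
#' @param control,perturbed the two [expression_profile()]s.
#' @param reps repetitions per direction (default 100).
#' @param direction \code{"up"}, \code{"down"}, or \code{"both"} (reps in
#'   each direction).
#' @param max_frac maximum perturbed fraction (default 0.05).
#' @param top_ks top-k sizes to aggregate over (default c(10, 20)).
#' @param percentile,top_k,analyze passed to [epitracer()].
#' @param seed master seed.
#' @return a list of class \code{"stability_report"}: \code{runs} (per
#'   repetition: direction, rep index, and the specific/global rank
#'   tables), \code{always_in_top_k}, \code{node_stats} (gene, n_present,
#'   mean_rank, and per-k top-k frequencies over the specific lists), and
#'   \code{meta}.
#' @export
sensitivity_run <- function(network, control, perturbed, reps = 100,
                            direction = c("both", "up", "down"),
                            max_frac = 0.05, top_ks = c(10, 20),
                            percentile = 0.1, top_k = 10,
                            analyze = "perturbed", seed = 1L) {
  direction <- match.arg(direction)
  dirs <- if (direction == "both") c("up", "down") else direction
  runs <- list()
  for (dr in dirs) {
    for (r in seq_len(reps)) {
      ctrl_r <- perturb_profile(control, dr, max_frac, seed = seed,
                                rep = r)
      pert_r <- perturb_profile(perturbed, dr, max_frac, seed = seed,
                                rep = r)
      fit <- tryCatch(
        epitracer(network, ctrl_r, pert_r, percentile = percentile,
                  top_k = max(c(top_k, top_ks)), analyze = analyze),
        error = function(e)
          stop("pipeline failed at repetition ", r, " (direction ", dr,
               "): ", conditionMessage(e)))
      rk <- fit$rankings[[analyze]]
      runs[[paste0(dr, "_", r)]] <-
        list(direction = dr, rep = r,
             specific = rk$specific[, c("rank", "gene", "ripple")],
             global = rk$global[, c("rank", "gene", "ripple")])
    }
  }
  spec_tabs <- lapply(runs, `[[`, "specific")
  always <- lapply(top_ks, function(k) {
    sets <- lapply(spec_tabs, function(t) t$gene[t$rank <= k])
    Reduce(intersect, sets)
  })
  names(always) <- paste0("top_", top_ks)
  genes <- sort(unique(unlist(lapply(spec_tabs, `[[`, "gene"))),
                method = "radix")
  stats_df <- data.frame(gene = genes, stringsAsFactors = FALSE)
  ranks <- lapply(genes, function(g)
    unlist(lapply(spec_tabs, function(t) t$rank[t$gene == g])))
  stats_df$n_present <- lengths(ranks)
  stats_df$mean_rank <- vapply(ranks, function(r)
    if (length(r)) mean(r) else NA_real_, numeric(1))
  for (k in top_ks)
    stats_df[[paste0("freq_top_", k)]] <- vapply(ranks, function(r)
      sum(r <= k) / length(spec_tabs), numeric(1))
  structure(list(runs = runs, always_in_top_k = always,
                 node_stats = stats_df,
                 meta = list(direction = direction, max_frac = max_frac,
                             reps = reps, top_ks = top_ks,
                             percentile = percentile, analyze = analyze,
                             seed = seed)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  m <- x$meta
  cat("Stability report: ", length(x$runs), " runs (", m$direction,
      ", max_frac = ", m$max_frac, ", seed = ", m$seed, ")\n", sep = "")
  for (nm in names(x$always_in_top_k))
    cat("  always in ", sub("_", " ", nm), ": ",
        length(x$always_in_top_k[[nm]]), " gene(s)\n", sep = "")
  invisible(x)
}

#' Write a stability report as JSON plus a per-node TSV table
#'
#' @param report a [sensitivity_run()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_stability_report <- function(report, dir) {
  stopifnot(inherits(report, "stability_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    list(meta = report$meta, always_in_top_k = report$always_in_top_k),
    file.path(dir, "stability.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(report$node_stats,
                     file.path(dir, "stability_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
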