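# Run `expr` under a private RNG state seeded by `seed`, restoring the
# caller's state afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Generate a synthetic case with a planted epicenter
#'
#' Builds a directed scale-free interaction network (preferential
#' attachment with randomized edge orientation -- interaction networks are
#' heavy-tailed and epicenter detection depends on hub structure), a
#' log-normal control expression profile, and a perturbed profile in which
#' one well-connected node (the planted epicenter) is overexpressed by a
#' factor \code{f} and the effect cascades downstream: a gene h hops
#' downstream (h <= \code{d}) gets expected ratio 1 + (f - 1) * alpha^h,
#' with a fraction \code{down_fraction} of cascade genes receiving the
#' reciprocal (downregulation) instead -- a local source with mixed-sign
#' downstream effects, as seen after overexpressing a regulator.
#' Multiplicative log-normal noise of spread \code{noise_sd} is applied to
#' every gene except the planted node, whose perturbed/control ratio is
#' exactly \code{f}.
#'
#' The planted node is the node whose \code{d}-hop out-neighborhood is
#' largest, among nodes covering at least 10% of the graph (lexicographic
#' tie-break); an error suggests raising \code{mean_degree} when no node
#' qualifies.
#'
#' @param N node count (>= 10; default 300).
#' @param mean_degree target mean total degree (default 4).
#' @param f overexpression factor of the planted node (> 1; default 8).
#' @param d cascade depth in hops (default 2).
#' @param alpha per-hop effect attenuation in (0, 1] (default 0.5).
#' @param down_fraction fraction of cascade genes downregulated (default
#'   0.35).
#' @param noise_sd sd of the log-normal multiplicative noise (default
#'   0.1).
#' @param seed RNG seed (default 42); same seed, same case, byte for byte.
#' @param meanlog,sdlog log-normal parameters of the control intensities
#'   (defaults log(100) and 1: linear-scale intensities centered near 100
#'   with about a decade of spread, as after standard array
#'   normalization).
#' @return a list of class \code{"synthetic_case"}: \code{network} (a
#'   [base_network()]), \code{control} and \code{perturbed}
#'   ([expression_profile()]s), and \code{manifest} (planted node, cascade
#'   table, parameters).
#' @export
generate_case <- function(N = 300, mean_degree = 4, f = 8, d = 2,
                          alpha = 0.5, down_fraction = 0.35,
                          noise_sd = 0.1, seed = 42,
                          meanlog = log(100), sdlog = 1) {
  if (N < 10) stop("'N' must be >= 10")
  if (f <= 1) stop("'f' must be > 1")
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]")
  if (down_fraction < 0 || down_fraction > 1)
    stop("'down_fraction' must be in [0, 1]")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  .with_seed(seed, {
    g0 <- igraph::sample_pa(N, m = max(1L, ceiling(mean_degree / 2)),
                            directed = TRUE)
    el <- igraph::as_edgelist(g0, names = FALSE)
    flip <- stats::runif(nrow(el)) < 0.5
    el[flip, ] <- el[flip, 2:1]
    names_v <- sprintf("g%0*d", nchar(N), seq_len(N))
    edges <- data.frame(from = names_v[el[, 1L]], to = names_v[el[, 2L]],
                        stringsAsFactors = FALSE)
    net <- suppressMessages(base_network(edges))

    control_v <- stats::setNames(stats::rlnorm(N, meanlog, sdlog), names_v)

    # planted node: largest d-hop out-neighborhood, >= 10% coverage
    # (for a degenerate depth-0 cascade, judge coverage at 1 hop so an
    # epicenter remains geometrically possible)
    dq <- max(1L, d)
    nodes <- sort(igraph::V(net)$name, method = "radix")
    cover <- vapply(nodes, function(v)
      length(igraph::ego(net, order = dq, nodes = v, mode = "out")[[1L]]) -
        1L, integer(1))
    ok <- cover >= 0.1 * N
    if (!any(ok))
      stop("no node's ", dq, "-hop out-neighborhood covers 10% of the ",
           "graph; increase mean_degree")
    planted <- nodes[ok][which.max(cover[ok])]

    # the perturbation target is lowly expressed before induction (an
    # overexpression study re-expresses a silenced/deleted gene): fix its
    # control intensity at the 10th intensity percentile
    control_v[planted] <- stats::qlnorm(0.10, meanlog, sdlog)
    control <- expression_profile(control_v, "control")

    hop <- igraph::distances(net, v = planted, to = nodes, mode = "out",
                             weights = NA)[1L, ]
    cascade <- nodes[is.finite(hop) & hop >= 1 & hop <= d]
    casc_hop <- hop[cascade]
    n_down <- round(down_fraction * length(cascade))
    down_set <- if (length(cascade))
      sample(cascade, n_down) else character(0)

    ratio <- stats::setNames(rep(1, N), names_v)
    r_h <- 1 + (f - 1) * alpha^casc_hop
    ratio[cascade] <- ifelse(cascade %in% down_set, 1 / r_h, r_h)
    noise <- exp(stats::rnorm(N, 0, noise_sd))
    pert_v <- control_v * ratio[names_v] * noise
    pert_v[planted] <- control_v[planted] * f   # ratio exactly f
    perturbed <- expression_profile(pert_v, "perturbed")

    manifest <- list(planted = planted, f = f, d = d, alpha = alpha,
                     down_fraction = down_fraction, noise_sd = noise_sd,
                     seed = seed, N = N, mean_degree = mean_degree,
                     meanlog = meanlog, sdlog = sdlog,
                     cascade = data.frame(
                       gene = cascade, hop = as.integer(casc_hop),
                       direction = ifelse(cascade %in% down_set, "down",
                                          "up"),
                       stringsAsFactors = FALSE))
    structure(list(network = net, control = control,
                   perturbed = perturbed, manifest = manifest),
              class = "synthetic_case")
  })
}

#' @export
print.synthetic_case <- function(x, ...) {
  m <- x$manifest
  cat("Synthetic planted-epicenter case (seed ", m$seed, "): ",
      m$N, " nodes, ", igraph::ecount(x$network), " edges; planted ",
      m$planted, " (f = ", m$f, ", depth ", m$d, ", ",
      nrow(m$cascade), " cascade genes)\n", sep = "")
  invisible(x)
}

#' Write a synthetic case to disk in the standard input formats
#'
#' Writes \code{network.tsv} (edge list), \code{control.tsv} and
#' \code{perturbed.tsv} (expression tables), and \code{manifest.json}.
#'
#' @param case a [generate_case()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "synthetic_case"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  el <- igraph::as_edgelist(case$network, names = TRUE)
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"),
             file.path(dir, "network.tsv"))
  wr <- function(p, f) {
    df <- data.frame(gene = names(p),
                     intensity = format(as.numeric(p), digits = 17,
                                        trim = TRUE, scientific = FALSE),
                     stringsAsFactors = FALSE)
    names(df)[2L] <- attr(p, "condition")
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(case$control, "control.tsv")
  wr(case$perturbed, "perturbed.tsv")
  jsonlite::write_json(case$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Planted-epicenter recovery metrics
#'
#' Locates the planted node in the specific epicenter list of a ranking
#' (or fit) and reports its rank (Inf when absent) and top-k hit flags.
#'
#' @param ranking an [get_epicenters()] result, an [epitracer()] fit
#'   (its analyzed specific list is used), or a data frame with
#'   \code{rank} and \code{gene} columns.
#' @param manifest the \code{manifest} of the [generate_case()] the
#'   ranking was computed from.
#' @param top_ks top-k sizes for the hit flags (default c(1, 3, 10)).
#' @return a list: \code{planted}, \code{rank}, and logical \code{hits}
#'   named \code{top_k}. For a fit, the rank is taken in the full
#'   (untruncated) specific ranking; for a plain ranking table, in the
#'   rows given.
#' @export
score_recovery <- function(ranking, manifest, top_ks = c(1, 3, 10)) {
  tab <- if (inherits(ranking, "epitracer")) {
    dr <- ranking$analyze[1L]
    sc <- ranking$rankings[[dr]]$scores
    other <- setdiff(c("perturbed", "control"), dr)
    spec <- !(sc$gene %in% igraph::V(ranking$cshans[[other]])$name)
    .rank_with_ties(sc$gene[spec], sc$ripple[spec])
  }
  else if (inherits(ranking, "epicenter_ranking")) ranking$specific
  else ranking
  stopifnot(is.data.frame(tab), all(c("rank", "gene") %in% names(tab)))
  i <- match(manifest$planted, tab$gene)
  rank <- if (is.na(i)) Inf else tab$rank[i]
  hits <- stats::setNames(rank <= top_ks, paste0("top_", top_ks))
  list(planted = manifest$planted, rank = rank, hits = hits)
}
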