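#' Validated configuration for a pipeline run
#'
#' Collects and validates every knob of an end-to-end run before any
#' computation starts. The configuration is serialized verbatim into the
#' output directory for provenance.
#'
#' @param network path to the network edge list (TSV or SIF).
#' @param control,perturbed paths to the expression tables.
#' @param network_format \code{"tsv"} or \code{"sif"}.
#' @param control_columns,perturbed_columns sample columns per condition
#'   (NULL = all sample columns of the respective table).
#' @param unlog2 intensities are log2-scale and must be exponentiated.
#' @param percentile path-cost percentile in (0, 100] (default 0.1).
#' @param top_k epicenter rank cutoff (default 10).
#' @param analyze \code{"perturbed"}, \code{"control"}, or \code{"both"}.
#' @param out_dir output directory.
#' @param seed seed recorded for downstream stochastic stages.
#' @return a validated list of class \code{"run_config"}.
#' @export
run_config <- function(network, control, perturbed,
                       network_format = "tsv",
                       control_columns = NULL, perturbed_columns = NULL,
                       unlog2 = FALSE, percentile = 0.1, top_k = 10,
                       analyze = "perturbed", out_dir = "epitracer_out",
                       seed = 1L) {
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      is.na(percentile) || percentile <= 0 || percentile > 100)
    stop("'percentile' must be in (0, 100]")
  if (!is.numeric(top_k) || length(top_k) != 1L || top_k < 1)
    stop("'top_k' must be >= 1")
  if (!analyze %in% c("perturbed", "control", "both"))
    stop("'analyze' must be one of perturbed/control/both")
  if (!network_format %in% c("tsv", "sif"))
    stop("'network_format' must be tsv or sif")
  for (p in c(network, control, perturbed))
    if (!file.exists(p)) stop("input file not found: ", p)
  structure(list(network = network, control = control,
                 perturbed = perturbed, network_format = network_format,
                 control_columns = control_columns,
                 perturbed_columns = perturbed_columns, unlog2 = unlog2,
                 percentile = percentile, top_k = top_k,
                 analyze = analyze, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML key-value file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an
#' error. Values given as function arguments override the file.
#'
#' @param path path to the YAML file.
#' @param ... overrides, as [run_config()] arguments.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, ...) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the 'yaml' package")
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' Run the full pipeline and write its artifacts to disk
#'
#' Executes every stage -- condition networks, highest-activity paths,
#' condition-specific paths, CSHANs, epicenter rankings and LSCC report
#' -- and writes, under \code{config$out_dir}: per-condition HAP sets
#' (\code{haps_<cond>.tsv}), CSHAN edge lists and GraphML
#' (\code{cshan_<cond>.tsv/.graphml}), ranking tables
#' (\code{ranking_<cond>_<specific|global>.tsv}), an LSCC summary, the
#' configuration (\code{config.json}), and a log with stage timings and
#' counts.
#'
#' @param config a [run_config()].
#' @return the [epitracer()] fit, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.txt")
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), "  ", ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           "\n  (check the inputs listed in config.json)", call. = FALSE))
    note(name, " done in ", sprintf("%.2fs", proc.time()[["elapsed"]] - t0))
    r
  }
  jsonlite::write_json(unclass(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  net <- stage("load network",
               read_edge_list(config$network, config$network_format))
  ctrl <- stage("load control profile",
                read_expression(config$control, "control",
                                columns = config$control_columns,
                                unlog2 = config$unlog2))
  pert <- stage("load perturbed profile",
                read_expression(config$perturbed, "perturbed",
                                columns = config$perturbed_columns,
                                unlog2 = config$unlog2))
  fit <- stage("epicenter analysis",
               epitracer(net, ctrl, pert, percentile = config$percentile,
                         top_k = config$top_k, analyze = config$analyze))
  note("paths retained: ", length(fit$haps$control$paths), " control, ",
       length(fit$haps$perturbed$paths), " perturbed; ",
       fit$n_common_paths, " common discarded")
  for (cond in c("control", "perturbed")) {
    write_hap_set(fit$haps[[cond]],
                  file.path(config$out_dir, paste0("haps_", cond, ".tsv")))
    write_cshan(fit$cshans[[cond]],
                file.path(config$out_dir, paste0("cshan_", cond, ".tsv")))
    write_graphml(fit$cshans[[cond]],
                  file.path(config$out_dir,
                            paste0("cshan_", cond, ".graphml")))
    note("CSHAN [", cond, "]: ", igraph::vcount(fit$cshans[[cond]]),
         " nodes, ", igraph::ecount(fit$cshans[[cond]]), " edges")
  }
  for (dr in fit$analyze) {
    for (side in c("specific", "global"))
      write_ranking(fit, file.path(config$out_dir,
                                   paste0("ranking_", dr, "_", side,
                                          ".tsv")),
                    which = dr, list = side)
    lr <- fit$lscc[[dr]]
    utils::write.table(lr, file.path(config$out_dir,
                                     paste0("lscc_", dr, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("LSCC [", dr, "]: ", attr(lr, "lscc_size"), " of ",
         attr(lr, "graph_size"), " nodes")
  }
  writeLines(log_lines, log_path)
  invisible(fit)
}
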