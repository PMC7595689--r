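#' Write pipeline outputs to a directory
#'
#' Emits `report.json` (full machine-readable report), `intersections.tsv`
#' (the Step-4 table: one row per tested combination), `covers.tsv` (node
#' membership of every final cover) and `cohesion.tsv` (Step-6 statistics).
#'
#' @param report A `nims_report` from [run_nims()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_nims_report <- function(report, dir) {
  stopifnot(inherits(report, "nims_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  covers_df <- if (length(report$covers)) do.call(rbind, lapply(
    report$covers, function(cv) data.frame(
      cover = cv$label, node = cv$members,
      constituents = paste(cv$constituents, collapse = "+"),
      stringsAsFactors = FALSE)))
  else data.frame(cover = character(0), node = character(0),
                  constituents = character(0))

  cohesion_df <- if (length(report$cohesion)) do.call(rbind, lapply(
    report$cohesion, function(cr) data.frame(
      cover = cr$cover, W = cr$W, p = cr$p, n_used = cr$n_used,
      method = cr$method, stringsAsFactors = FALSE)))
  else data.frame(cover = character(0), W = numeric(0), p = numeric(0),
                  n_used = integer(0), method = character(0))

  if (!is.null(report$intersections)) {
    write.table(as.data.frame(report$intersections),
                file.path(dir, "intersections.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write.table(covers_df, file.path(dir, "covers.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(cohesion_df, file.path(dir, "cohesion.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  json <- list(
    network = list(n_nodes = report$validation$n_nodes,
                   n_edges = report$validation$n_edges,
                   is_connected = report$validation$is_connected,
                   warnings = report$validation$warnings),
    n_node_level_modules = length(report$modules_raw),
    modules = lapply(report$modules$modules, function(m)
      list(focal = m$focal, members = m$members, score = m$score,
           agreement = m$agreement)),
    trivially_integrated = report$trivially_integrated,
    intersections = if (!is.null(report$intersections))
      as.data.frame(report$intersections),
    merges = report$plan$merges,
    rejected = if (!is.null(report$plan)) report$plan$rejected,
    covers = covers_df,
    cohesion = cohesion_df,
    uncovered = report$uncovered,
    alpha = report$alpha,
    seed = report$seed,
    config = unclass(report$config))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

#' Command-line entry point
#'
#' Thin wrapper used by the bundled `inst/cli/nims.R` script:
#' ```
#' Rscript -e 'nims::nims_main()' --network FILE [--format graphml]
#'   [--gamma 1.0] [--replicates 10] [--seed 1] [--alpha 0.05]
#'   [--interactive] [--out DIR]
#' ```
#' Per-step timings and agreement warnings are logged to stderr.
#'
#' @param args Character vector of command-line arguments; defaults to
#'   [commandArgs()]`(trailingOnly = TRUE)`.
#' @return The `nims_report`, invisibly.
#' @export
nims_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (!length(i)) return(default)
    if (i[1L] == length(args)) stop("missing value for ", flag)
    args[i[1L] + 1L]
  }
  has_flag <- function(flag) flag %in% args
  network <- get_opt("--network")
  if (is.null(network)) stop("usage: nims run --network FILE [--format F] ",
                             "[--gamma F] [--replicates N] [--seed N] ",
                             "[--alpha F] [--interactive] [--out DIR]")
  format <- get_opt("--format", "auto")
  out <- get_opt("--out", "nims-output")
  config <- spinglass_config(
    gamma = as.numeric(get_opt("--gamma", "1.0")),
    replicates = as.integer(get_opt("--replicates", "10")),
    seed = as.integer(get_opt("--seed", "1")))
  alpha <- as.numeric(get_opt("--alpha", "0.05"))

  t0 <- proc.time()[["elapsed"]]
  net <- read_network(network, format)
  message(sprintf("[nims] read %d nodes, %d edges (%.2fs)",
                  n_nodes(net), n_edges(net),
                  proc.time()[["elapsed"]] - t0))
  t0 <- proc.time()[["elapsed"]]
  report <- run_nims(net, config, alpha,
                     interactive = has_flag("--interactive"))
  message(sprintf("[nims] pipeline done (%.2fs): %d covers",
                  proc.time()[["elapsed"]] - t0, length(report$covers)))
  write_nims_report(report, out)
  message("[nims] report written to ", out)
  invisible(report)
}
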