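# End-to-end orchestration from a flat key=value config file, with a run
# manifest recording parameters, input digests and the package version.

#' Read a flat key = value run configuration
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Values are coerced to numeric or logical (`true`/`false`) when possible.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad)) stop("malformed config line(s): ",
                        paste(bad, collapse = "; "))
  out <- lapply(kv, function(m) {
    v <- trimws(m[[3L]])
    if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  stats::setNames(out, vapply(kv, `[[`, "", 2L))
}

config_defaults <- function() {
  list(mode = "spatial", replicates = 1000, alpha = 0.05,
       pseudocount = TRUE, merge_gap = 2000, min_span = 2000,
       max_degree = 20, max_length = 30000, simulate = FALSE,
       n_regions = 2000, degree_lambda = 3, n_factors = 20,
       base_bind_prob = 0.10, attract_boost = 8, repel_damp = 0.125,
       seed = 1)
}

validate_config <- function(cfg) {
  if (cfg$replicates < 1) stop("config error: replicates must be >= 1")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("config error: alpha must be in (0, 1)")
  if (!cfg$mode %in% c("spatial", "sequential", "both"))
    stop("config error: mode must be spatial, sequential or both")
  if (!isTRUE(cfg$simulate)) {
    for (key in c("interactions", "peaks_dir")) {
      if (is.null(cfg[[key]]))
        stop("config error: ", key, " required unless simulate = true")
      if (!file.exists(cfg[[key]]))
        stop("config error: missing input: ", cfg[[key]])
    }
  }
  if (!is.null(cfg$compartments) && !file.exists(cfg$compartments))
    stop("config error: missing input: ", cfg$compartments)
  invisible(cfg)
}

write_manifest <- function(path, cfg, inputs) {
  lines <- c(
    sprintf("tool = chromcooc %s",
            as.character(utils::packageVersion("chromcooc"))),
    sprintf("timestamp = %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    vapply(sort(names(cfg)), function(k)
      sprintf("param.%s = %s", k, paste(cfg[[k]], collapse = ",")), ""),
    vapply(inputs, function(f)
      sprintf("input.%s.md5 = %s", basename(f),
              unname(tools::md5sum(f))), ""))
  writeLines(lines, path)
  invisible(path)
}

write_stats_tsv <- function(stats, path, manifest = "manifest.txt") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# produced-by-manifest: %s", manifest), con)
  utils::write.table(stats, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the co-occurrence pipeline end to end
#'
#' Stages, in dependency order: (optional) synthetic-data generation, network
#' construction from the interaction file, optional compartment edge
#' restriction, peak mapping, co-occurrence randomization test, and TSV
#' export with a run manifest. Re-running with an identical config and
#' inputs reproduces identical statistics tables. Inputs are never mutated.
#'
#' @param config Path to a flat `key = value` config file (see
#'   [read_run_config()]) or an equivalent named list. Recognized keys with
#'   defaults: `mode` (spatial), `replicates` (1000), `alpha` (0.05),
#'   `pseudocount` (true), `merge_gap`/`min_span` (2000),
#'   `max_degree` (20), `max_length` (30000), `seed` (1); inputs
#'   `interactions` (anchor-pair TSV) and `peaks_dir` (directory of
#'   `<factor>.bed`), optional `compartments` (+ `compartment_class`); or
#'   `simulate = true` with `n_regions`, `degree_lambda`, `n_factors`,
#'   `base_bind_prob`, `attract_boost`, `repel_damp`.
#' @param out_dir Output directory (created; default `config$output_dir` or
#'   a tempdir subdirectory).
#' @return Invisibly, a list with the `network`, `binding`, `stats` and the
#'   output `dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  cfg <- utils::modifyList(config_defaults(), cfg)
  validate_config(cfg)
  out_dir <- out_dir %||% cfg$output_dir %||%
    file.path(tempdir(), "chromcooc_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (isTRUE(cfg$simulate)) {
    sc <- synth_config(n_regions = cfg$n_regions,
                       degree_law = list(type = "poisson",
                                         lambda = cfg$degree_lambda),
                       n_factors = cfg$n_factors,
                       attract_boost = cfg$attract_boost,
                       repel_damp = cfg$repel_damp,
                       base_bind_prob = cfg$base_bind_prob,
                       seed = cfg$seed)
    net0 <- simulate_network(sc)
    sim <- simulate_bindings(net0, sc)
    paths <- write_synth_dataset(file.path(out_dir, "inputs"), net0,
                                 sim$binding, sim$truth)
    cfg$interactions <- paths[["interactions"]]
    cfg$peaks_dir <- file.path(out_dir, "inputs")
  }

  pairs <- read_interactions(cfg$interactions)
  network <- build_interaction_network(
    pairs, merge_gap = cfg$merge_gap, min_span = cfg$min_span,
    max_degree = cfg$max_degree, max_length = cfg$max_length)
  message(sprintf("network: %d regions, %d edges after filters",
                  nrow(network$regions), nrow(network$edges)))
  if (!is.null(cfg$compartments)) {
    comp <- read_bed(cfg$compartments)
    network <- restrict_to_compartments(network, comp,
                                        class = cfg$compartment_class)
    message(sprintf("compartment restriction: %d edges kept",
                    nrow(network$edges)))
  }

  bed_files <- list.files(cfg$peaks_dir, pattern = "\\.bed$",
                          full.names = TRUE)
  if (!length(bed_files)) stop("no .bed files in ", cfg$peaks_dir)
  fnames <- sub("^peaks_", "", sub("\\.bed$", "", basename(bed_files)))
  peaks <- stats::setNames(lapply(bed_files, read_peaks), fnames)
  binding <- map_bindings(network, peaks)

  stats <- cooccurrence_test(network, binding, mode = cfg$mode,
                             replicates = as.integer(cfg$replicates),
                             seed = as.integer(cfg$seed),
                             alpha = cfg$alpha,
                             pseudocount = isTRUE(cfg$pseudocount))

  manifest <- file.path(out_dir, "manifest.txt")
  write_manifest(manifest, cfg, c(cfg$interactions, bed_files))
  write_network(network, file.path(out_dir, "network_nodes.tsv"),
                file.path(out_dir, "network_edges.tsv"))
  tables <- if (is.data.frame(stats)) {
    stats::setNames(list(stats), attr(stats, "mode"))
  } else stats
  for (m in names(tables))
    write_stats_tsv(tables[[m]],
                    file.path(out_dir, sprintf("pair_stats_%s.tsv", m)))
  invisible(list(network = network, binding = binding, stats = stats,
                 dir = out_dir))
}
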