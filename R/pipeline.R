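# End-to-end pipeline stages. Each cmd_* writes its outputs under a run
# directory together with a machine-readable manifest (config echo, input
# checksums, seed, stage timings) so a run is self-describing and
# reproducible: identical inputs/config/seed give identical output checksums.

network_export_path <- function(dir, fmt) {
  ext_map <- c(tsv = "edges.tsv", sif = "network.sif",
               graphml = "network.graphml")
  if (!fmt %in% names(ext_map))
    stop_usage("unknown network format '%s'; supported formats: %s",
               fmt, paste(names(ext_map), collapse = ", "))
  file.path(dir, ext_map[[fmt]])
}

check_run_dir <- function(dir, force) {
  manifest <- file.path(dir, "manifest.json")
  if (file.exists(manifest) && !force)
    stop_usage("output directory %s already holds a run (manifest.json); use force = TRUE to overwrite", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  invisible(dir)
}

write_manifest <- function(dir, command, config, inputs, outputs, seed = NULL,
                           timings = NULL) {
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    timings_sec = timings
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a cohort and write the pipeline input files
#'
#' Runs [simulate_cohort()] and writes the five input files plus a run
#' manifest under `out_dir`.
#'
#' @param out_dir Run directory.
#' @param config A [sim_config()].
#' @param force Overwrite an existing run directory.
#' @return Named vector of written paths, invisibly.
#' @export
cmd_simulate <- function(out_dir, config = sim_config(), force = FALSE) {
  check_run_dir(out_dir, force)
  t0 <- proc.time()[["elapsed"]]
  cohort <- simulate_cohort(config)
  paths <- write_cohort(cohort, out_dir)
  write_manifest(out_dir, "simulate", unclass(config), inputs = list(),
                 outputs = as.list(paths), seed = config$seed,
                 timings = list(simulate = proc.time()[["elapsed"]] - t0))
  invisible(paths)
}

#' Run the age-correlation screen on expression files
#'
#' Reads the miRNA matrix, gene matrix and sample metadata, correlates every
#' feature against age in tumor and in normal tissue, classifies both
#' kinds, and writes correlation tables, set lists, the candidate miRNA list
#' and JSON count summaries. The tumor-specific candidate filter is applied
#' to miRNAs; gene screening tables are written without a candidate list by
#' default (`candidate_kinds`).
#'
#' @param mirna_path,gene_path,samples_path Input files
#'   ([read_expression()] / [read_samples()] formats).
#' @param out_dir Run directory.
#' @param screening A [screening_config()].
#' @param candidate_kinds Feature kinds the tumor-specific filter is applied
#'   to (default `"mirna"`).
#' @param force Overwrite an existing run directory.
#' @return List with the two `screening_outcome` objects (`mirna`, `gene`),
#'   invisibly.
#' @export
cmd_screen <- function(mirna_path, gene_path, samples_path, out_dir,
                       screening = screening_config(),
                       candidate_kinds = "mirna", force = FALSE) {
  check_run_dir(out_dir, force)
  t0 <- proc.time()[["elapsed"]]
  samples <- read_samples(samples_path)
  outcomes <- list()
  outputs <- list()
  for (kind in c("mirna", "gene")) {
    path <- if (kind == "mirna") mirna_path else gene_path
    mat <- read_expression(path, kind)
    out <- screen(correlate_matrix(mat, samples, "tumor"),
                  correlate_matrix(mat, samples, "normal"),
                  screening)
    if (!kind %in% candidate_kinds)
      out$tumor_specific_candidates <- character(0)
    outcomes[[kind]] <- out
    outputs <- c(outputs, as.list(write_screening(out, out_dir, kind)))
  }
  write_manifest(out_dir, "screen", unclass(screening),
                 inputs = list(mirna_path, gene_path, samples_path),
                 outputs = outputs,
                 timings = list(screen = proc.time()[["elapsed"]] - t0))
  invisible(outcomes)
}

#' Run the miRNA-mRNA integration on a candidate list
#'
#' Reads the matrices, metadata, candidate list and target table, builds the
#' anti-correlation network and exports it in the requested formats.
#'
#' @inheritParams cmd_screen
#' @param candidates Character vector of candidate miRNA ids, or path to a
#'   one-id-per-line file.
#' @param targets_path Two-column target pair file ([read_targets()]).
#' @param alpha Edge significance level.
#' @param scope `"tumor"` or `"all"` (see [build_integration_network()]).
#' @param formats Export formats, subset of `c("tsv", "sif", "graphml")`.
#' @return The `integration_network`, invisibly.
#' @export
cmd_integrate <- function(mirna_path, gene_path, samples_path, candidates,
                          targets_path, out_dir, alpha = 0.05,
                          scope = "tumor", formats = c("tsv", "sif", "graphml"),
                          force = FALSE) {
  check_run_dir(out_dir, force)
  t0 <- proc.time()[["elapsed"]]
  samples <- read_samples(samples_path)
  mirna <- read_expression(mirna_path, "mirna")
  gene <- read_expression(gene_path, "gene")
  if (length(candidates) == 1L && file.exists(candidates))
    candidates <- readLines(candidates)
  candidates <- candidates[nzchar(candidates)]
  targets <- read_targets(targets_path, gene_universe = rownames(gene))
  net <- build_integration_network(mirna, gene, candidates, targets, samples,
                                   alpha = alpha, scope = scope)
  outputs <- list()
  for (fmt in formats)
    outputs[[fmt]] <- export_network(net, network_export_path(out_dir, fmt), fmt)
  write_manifest(out_dir, "integrate",
                 list(alpha = alpha, scope = scope),
                 inputs = list(mirna_path, gene_path, samples_path, targets_path),
                 outputs = outputs,
                 timings = list(integrate = proc.time()[["elapsed"]] - t0))
  invisible(net)
}

#' Run the full pipeline: simulate (or read), screen, integrate
#'
#' With `sim = sim_config(...)` the inputs are simulated and written first;
#' alternatively pass paths to existing input files. The run manifest under
#' `out_dir` lists every stage's outputs, input checksums, the seed and
#' stage timings.
#'
#' @param out_dir Run directory.
#' @param sim Optional [sim_config()]; when given, inputs are simulated.
#' @param mirna_path,gene_path,samples_path,targets_path Input files, used
#'   when `sim` is `NULL`.
#' @param screening A [screening_config()].
#' @param alpha,scope Integration parameters (see [cmd_integrate()]).
#' @param formats Network export formats.
#' @param force Overwrite an existing run directory.
#' @return List with `screening` (outcomes), `network`, and `paths`,
#'   invisibly.
#' @export
cmd_pipeline <- function(out_dir, sim = NULL,
                         mirna_path = NULL, gene_path = NULL,
                         samples_path = NULL, targets_path = NULL,
                         screening = screening_config(),
                         alpha = 0.05, scope = "tumor",
                         formats = c("tsv", "sif", "graphml"),
                         force = FALSE) {
  check_run_dir(out_dir, force)
  timings <- list()
  if (!is.null(sim)) {
    t0 <- proc.time()[["elapsed"]]
    cohort <- simulate_cohort(sim)
    inp <- write_cohort(cohort, file.path(out_dir, "inputs"))
    mirna_path <- inp[["mirna"]]; gene_path <- inp[["gene"]]
    samples_path <- inp[["samples"]]; targets_path <- inp[["targets"]]
    timings$simulate <- proc.time()[["elapsed"]] - t0
  }
  for (p in c(mirna_path, gene_path, samples_path, targets_path)) {
    if (is.null(p) || !file.exists(p))
      stop_usage("missing input file: %s", if (is.null(p)) "(not given)" else p)
  }
  t0 <- proc.time()[["elapsed"]]
  samples <- read_samples(samples_path)
  mirna <- read_expression(mirna_path, "mirna")
  gene <- read_expression(gene_path, "gene")
  outcomes <- list()
  outputs <- list()
  for (kind in c("mirna", "gene")) {
    mat <- if (kind == "mirna") mirna else gene
    out <- screen(correlate_matrix(mat, samples, "tumor"),
                  correlate_matrix(mat, samples, "normal"),
                  screening)
    if (kind != "mirna") out$tumor_specific_candidates <- character(0)
    outcomes[[kind]] <- out
    outputs <- c(outputs, as.list(write_screening(out, out_dir, kind)))
  }
  timings$screen <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  targets <- read_targets(targets_path, gene_universe = rownames(gene))
  net <- build_integration_network(
    mirna, gene, outcomes$mirna$tumor_specific_candidates, targets, samples,
    alpha = alpha, scope = scope)
  for (fmt in formats)
    outputs[[fmt]] <- export_network(net, network_export_path(out_dir, fmt), fmt)
  timings$integrate <- proc.time()[["elapsed"]] - t0

  write_manifest(out_dir, "pipeline",
                 list(screening = unclass(screening), alpha = alpha,
                      scope = scope,
                      sim = if (!is.null(sim)) unclass(sim)),
                 inputs = list(mirna_path, gene_path, samples_path, targets_path),
                 outputs = outputs,
                 seed = if (!is.null(sim)) sim$seed,
                 timings = timings)
  invisible(list(screening = outcomes, network = net,
                 paths = unlist(outputs)))
}
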