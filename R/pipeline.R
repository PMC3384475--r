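#' Configuration of an end-to-end run
#'
#' Either a synthetic run (generator settings; the default emulates a
#' 6205-probe, four-replicon reference compared against 7 + 9 strains in
#' two content groups plus plasmid-cured validation derivatives) or an
#' ingestion run (`scan_paths` + `annotation_path`). All stochastic stages
#' derive their seeds from the single `seed`.
#'
#' @param outdir Output directory for the result bundle.
#' @param seed Master integer seed.
#' @param genome A [genome_config()] (synthetic mode).
#' @param n_groupI,n_groupII Strains per content group.
#' @param island_presence,plasmid_presence,dropout Passed to
#'   [assign_strain_content()].
#' @param noise A [noise_model()].
#' @param scan_paths Optional character vector of spot-table files
#'   (ingestion mode; validated to exist now).
#' @param annotation_path,genesets_path Optional annotation / gene-set TSVs
#'   (ingestion mode).
#' @param offset,span,iterations Normalization options.
#' @param cutoff Presence cutoff (default 20); `"calibrated"` uses the
#'   cutoff calibrated on the validation derivatives (synthetic mode only).
#' @param fold_mode `"per-spot"` or `"array-background"`.
#' @param n_boot Bootstrap resamples for clustering supports.
#' @param min_genes,max_gap,min_variable_frac,min_absent Island-scan
#'   options.
#' @return A list of class `run_config`.
#' @export
run_config <- function(outdir = tempfile("cgh_run_"), seed = 1L,
                       genome = genome_config(), n_groupI = 7L,
                       n_groupII = 9L, island_presence = c(I = 0.9, II = 0.2),
                       plasmid_presence = c(I = 1.0, II = 0.7),
                       dropout = 0.02, noise = noise_model(),
                       scan_paths = NULL, annotation_path = NULL,
                       genesets_path = NULL,
                       offset = 50, span = 0.3, iterations = 4L,
                       cutoff = 20, fold_mode = "per-spot", n_boot = 1000L,
                       min_genes = 5L, max_gap = 2L, min_variable_frac = 0.8,
                       min_absent = 4L) {
  synthetic <- is.null(scan_paths)
  if (!synthetic) {
    for (p in c(scan_paths, annotation_path, genesets_path))
      if (!file.exists(p)) stopf("input file not found: '%s'", p)
    if (is.null(annotation_path))
      stopf("ingestion mode needs 'annotation_path'")
    if (identical(cutoff, "calibrated"))
      stopf("calibrated cutoff needs synthetic validation derivatives")
  }
  structure(list(outdir = outdir, seed = as.integer(seed), genome = genome,
                 n_groupI = n_groupI, n_groupII = n_groupII,
                 island_presence = island_presence,
                 plasmid_presence = plasmid_presence, dropout = dropout,
                 noise = noise, scan_paths = scan_paths,
                 annotation_path = annotation_path,
                 genesets_path = genesets_path, offset = offset, span = span,
                 iterations = iterations, cutoff = cutoff,
                 fold_mode = fold_mode, n_boot = n_boot,
                 min_genes = min_genes, max_gap = max_gap,
                 min_variable_frac = min_variable_frac,
                 min_absent = min_absent, synthetic = synthetic),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys map to [run_config()] arguments; `genome` and `noise`
#' sub-maps are passed to [genome_config()] / [noise_model()] (the
#' `genome$replicons` entry, if present, must be a list of
#' `name`/`length_bp`/`n_loci` records).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$genome)) {
    if (!is.null(y$genome$replicons))
      y$genome$replicons <- do.call(rbind, lapply(y$genome$replicons,
                                                  as.data.frame))
    if (!is.null(y$genome$islands)) y$genome$islands <- unlist(y$genome$islands)
    y$genome <- do.call(genome_config, y$genome)
  }
  if (!is.null(y$noise)) y$noise <- do.call(noise_model, y$noise)
  for (nm in c("island_presence", "plasmid_presence"))
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  do.call(run_config, y)
}

#' @noRd
pipeline_log <- function(lines, stage, ...) {
  c(lines, sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full CGH analysis pipeline
#'
#' Synthetic mode: generate the genome model, strain contents, validation
#' derivatives and scans; then (both modes) normalize each scan, calibrate
#' and apply the presence cutoff, compute core/shared/occupancy
#' statistics, cluster strains with bootstrap supports, scan for islands,
#' and write the result bundle. Identical config + seed gives identical
#' outputs.
#'
#' @param config A [run_config()].
#' @return List of class `cgh_run` with the in-memory results (`model`,
#'   `matrix`, `core`, `shared`, `occupancy`, `calibration`, `tree`,
#'   `groups`, `islands`, ...), the output `manifest` and the `summary`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  seed <- config$seed

  stage <- "generate"
  res <- tryCatch({
    if (config$synthetic) {
      model <- build_genome_model(config$genome, seed)
      contents <- assign_strain_content(
        model, config$n_groupI, config$n_groupII, config$island_presence,
        config$plasmid_presence, config$dropout, seed + 1L)
      table <- as_gene_table(model)
      ref <- structure(list(strain_id = "REF", group = "I",
                            present = model$loci$locus_tag),
                       class = "strain_content")
      cured <- model$regions$name[model$regions$class == "plasmid-backbone"]
      derivs <- lapply(cured, function(rn)
        make_validation_derivative(ref, rn, model))
      log <- pipeline_log(log, stage,
                          "%d loci, %d strains, %d validation derivative(s)",
                          nrow(model$loci), length(contents), length(derivs))
      scans <- lapply(seq_along(contents), function(i)
        simulate_scan(model, contents[[i]], config$noise, seed + 10L + i))
      dscans <- lapply(seq_along(derivs), function(i)
        simulate_scan(model, derivs[[i]], config$noise, seed + 1000L + i))
      list(model = model, table = table, contents = contents,
           derivs = derivs, scans = scans, dscans = dscans)
    } else {
      table <- read_gene_table(config$annotation_path, config$genesets_path)
      scans <- lapply(config$scan_paths, read_spot_table)
      log <- pipeline_log(log, "ingest", "%d scan(s), %d loci",
                          length(scans), nrow(table$genes))
      list(model = NULL, table = table, contents = NULL, derivs = NULL,
           scans = scans, dscans = list())
    }
  }, error = function(e) stopf("stage '%s' failed: %s", stage,
                               conditionMessage(e)))

  stage <- "normalize"
  norms <- tryCatch(
    lapply(res$scans, normalize_scan, offset = config$offset,
           span = config$span, iterations = config$iterations),
    error = function(e) stopf("stage '%s' failed: %s", stage,
                              conditionMessage(e)))
  log <- pipeline_log(log, stage, "offset=%g span=%g iterations=%d",
                      config$offset, config$span, config$iterations)

  stage <- "call"
  called <- tryCatch({
    folds <- lapply(norms, fold_change, mode = config$fold_mode)
    calibration <- NULL
    cutoff <- config$cutoff
    if (length(res$dscans)) {
      dnorms <- lapply(res$dscans, normalize_scan, offset = config$offset,
                       span = config$span, iterations = config$iterations)
      probe_of <- setNames(res$model$loci$probe_id, res$model$loci$locus_tag)
      dsets <- lapply(seq_along(res$dscans), function(i) {
        truth <- setNames(
          res$model$loci$locus_tag %in% res$derivs[[i]]$present,
          probe_of[res$model$loci$locus_tag])
        list(folds = fold_change(dnorms[[i]], mode = config$fold_mode),
             truth = truth)
      })
      calibration <- calibrate_cutoff(dsets)
      if (identical(cutoff, "calibrated")) cutoff <- calibration$cutoff
    }
    if (!is.numeric(cutoff)) stopf("no numeric cutoff available")
    probe_map <- data.frame(probe_id = res$table$genes$probe_id,
                            locus_tag = res$table$genes$locus_tag,
                            stringsAsFactors = FALSE)
    calls <- lapply(folds, call_presence, cutoff = cutoff,
                    probe_map = probe_map)
    names(calls) <- vapply(res$scans, function(s) s$strain_id, "")
    names(folds) <- names(calls)
    pm <- build_presence_matrix(calls)
    list(matrix = pm, folds = folds, calibration = calibration,
         cutoff = cutoff)
  }, error = function(e) stopf("stage '%s' failed: %s", stage,
                               conditionMessage(e)))
  log <- pipeline_log(log, stage, "cutoff=%g mode=%s", called$cutoff,
                      config$fold_mode)

  stage <- "gene_content"
  content <- tryCatch({
    core <- core_set(called$matrix)
    shared <- pairwise_overlap(called$matrix)
    occupancy <- if (length(res$table$sets))
      region_occupancy(called$matrix, res$table) else NULL
    list(core = core, shared = shared, occupancy = occupancy)
  }, error = function(e) stopf("stage '%s' failed: %s", stage,
                               conditionMessage(e)))
  log <- pipeline_log(log, stage, "core %d/%d (%.1f%%)", content$core$n,
                      nrow(called$matrix$calls), content$core$fraction_pct)

  stage <- "clustering"
  clust <- tryCatch({
    tree <- bootstrap_support(called$matrix, n_boot = config$n_boot,
                              seed = seed + 5L)
    island_occ <- NULL
    if (!is.null(content$occupancy) && !is.null(res$model)) {
      isl_sets <- res$model$regions$name[res$model$regions$class == "island"]
      isl_sets <- intersect(isl_sets, rownames(content$occupancy$percent))
      if (length(isl_sets))
        island_occ <- colMeans(
          content$occupancy$percent[isl_sets, , drop = FALSE], na.rm = TRUE)
    }
    groups <- cut_two_groups(tree, island_occ)
    list(tree = tree, groups = groups, island_occ = island_occ)
  }, error = function(e) stopf("stage '%s' failed: %s", stage,
                               conditionMessage(e)))
  log <- pipeline_log(log, stage, "n_boot=%d, groups %d/%d", config$n_boot,
                      length(clust$groups$I), length(clust$groups$II))

  stage <- "island_scan"
  islands <- tryCatch(
    scan_islands(called$matrix, res$table, min_genes = config$min_genes,
                 max_gap = config$max_gap,
                 min_variable_frac = config$min_variable_frac,
                 groups = clust$groups, min_absent = config$min_absent),
    error = function(e) stopf("stage '%s' failed: %s", stage,
                              conditionMessage(e)))
  log <- pipeline_log(log, stage, "%d candidate island(s)", length(islands))

  stage <- "write_outputs"
  manifest <- tryCatch({
    manifest <- write_outputs(called$matrix, content$occupancy, islands,
                              clust$tree, config$outdir)
    if (!is.null(res$model)) {
      manifest[["truth"]] <- file.path(config$outdir, "truth.tsv")
      utils::write.table(content_truth(res$model, res$contents),
                         manifest[["truth"]], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    manifest[["log"]] <- file.path(config$outdir, "run.log")
    writeLines(log, manifest[["log"]])
    manifest
  }, error = function(e) stopf("stage '%s' failed: %s", stage,
                               conditionMessage(e)))

  run <- structure(list(config = config, model = res$model,
                        table = res$table, contents = res$contents,
                        derivatives = res$derivs, matrix = called$matrix,
                        folds = called$folds,
                        calibration = called$calibration,
                        cutoff = called$cutoff, core = content$core,
                        shared = content$shared,
                        occupancy = content$occupancy, tree = clust$tree,
                        groups = clust$groups,
                        island_occupancy = clust$island_occ,
                        islands = islands, manifest = manifest, log = log),
                   class = "cgh_run")
  run$summary <- summarize_run(run)
  summary_path <- file.path(config$outdir, "summary.json")
  jsonlite::write_json(run$summary, summary_path, auto_unbox = TRUE,
                       digits = NA)
  run$manifest[["summary"]] <- summary_path
  run
}

#' @export
print.cgh_run <- function(x, ...) {
  cat(sprintf("cgh_run: %d genes x %d strains; core %.1f%%; %d island(s)\n",
              nrow(x$matrix$calls), ncol(x$matrix$calls),
              x$core$fraction_pct, length(x$islands)))
  invisible(x)
}

#' Summarize a completed run
#'
#' @param run A `cgh_run`; its output manifest must be complete on disk.
#' @return List: core size and fraction, two-group partition and sizes,
#'   per-group mean island occupancy, island count, calibrated cutoff.
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "cgh_run"))
  missing <- run$manifest[!file.exists(run$manifest)]
  if (length(missing))
    stopf("incomplete manifest; missing: %s", paste(missing, collapse = ", "))
  occ_means <- if (!is.null(run$island_occupancy)) {
    list(group_I = round_half_up(
           mean(run$island_occupancy[run$groups$I], na.rm = TRUE), 1),
         group_II = round_half_up(
           mean(run$island_occupancy[run$groups$II], na.rm = TRUE), 1))
  } else NULL
  list(n_genes = nrow(run$matrix$calls), n_strains = ncol(run$matrix$calls),
       core_size = run$core$n, core_fraction_pct = run$core$fraction_pct,
       group_I = run$groups$I, group_II = run$groups$II,
       island_occupancy_pct = occ_means, n_islands = length(run$islands),
       cutoff = run$cutoff,
       calibrated_cutoff = if (!is.null(run$calibration))
         run$calibration$cutoff else NULL)
}
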