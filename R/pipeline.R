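#' Run the full complex-expression analysis pipeline
#'
#' Orchestrates every stage — complex mapping, detection, formable-complex
#' (PFPC) calling at transcript and gene level, major-isoform assignment,
#' involvement and switching, per-dataset differential expression, and
#' DE-to-complex impact propagation — writing each stage's tabular outputs
#' and a top-level `summary.json` into `outdir`. Inputs are either file paths
#' (a complex table, a mapping table, per-sample expression tables, and
#' case/control count matrices) or a `simulate` block, in which case the
#' synthetic generator produces the whole study first and its files are
#' written beside the results.
#'
#' The configuration is a list (or path to a YAML file) with elements:
#' * `simulate`: optional list of [synth_config()] arguments; when present,
#'   input paths are ignored and a synthetic study is generated;
#' * `complexes`, `mapping`: input TSV paths (file mode);
#' * `expression`: character vector of per-sample expression TSVs (file
#'   mode);
#' * `de_datasets`: named list, one element per dataset, each with `counts`
#'   (TSV of transcripts x samples), `groups` (TSV `sample<TAB>group`) and
#'   optionally `q_min` (file mode). In simulate mode four datasets named
#'   breast, colon, lung and prostate are generated with their conventional
#'   cutoffs (0.9, 0.9, 0.99, 0.8); the lung dataset is generated without
#'   biological replicates and analysed in simulated-technical-replicate
#'   mode;
#' * `sd_max`: posterior-SD detection cutoff (default 1.5);
#' * `outdir`: output directory.
#'
#' A stage failure raises an error naming the stage; outputs of completed
#' stages are left in place.
#'
#' @param config list or path to a YAML file.
#' @param outdir output directory; overrides `config$outdir` when given.
#' @return The summary list (also written as `summary.json`), invisibly.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) .stopf("an output directory is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sd_max <- if (is.null(config$sd_max)) 1.5 else config$sd_max

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  summary <- list()

  # ---- inputs ---------------------------------------------------------
  simulated <- !is.null(config$simulate)
  de_inputs <- list()
  if (simulated) {
    scfg <- stage("simulate", do.call(synth_config, config$simulate))
    universe <- stage("simulate", simulate_universe(scfg))
    synth_expr <- stage("simulate", simulate_expression(scfg, universe))
    write_universe(universe, file.path(outdir, "synth"))
    expr_paths <- write_expression_set(synth_expr$expr,
                                       file.path(outdir, "synth", "expression"))
    cset <- universe$complexes
    mapping <- universe$mapping
    expr <- synth_expr$expr
    datasets <- c("breast", "colon", "lung", "prostate")
    q_mins <- c(breast = 0.9, colon = 0.9, lung = 0.99, prostate = 0.8)
    for (d in datasets) {
      dcfg <- scfg
      if (d == "lung") dcfg$de$n_case <- dcfg$de$n_control <- 1L
      de_inputs[[d]] <- c(simulate_de_counts(dcfg, universe, dataset = d),
                          list(q_min = q_mins[[d]]))
    }
  } else {
    cset <- stage("complex_map", read_complex_table(config$complexes))
    mapping <- stage("complex_map", read_mapping_table(config$mapping))
    expr <- stage("detection",
                  read_expression_set(config$expression, level = "transcript"))
    for (d in names(config$de_datasets)) {
      spec <- config$de_datasets[[d]]
      counts_df <- utils::read.delim(spec$counts, check.names = FALSE)
      counts <- as.matrix(counts_df[, -1, drop = FALSE])
      rownames(counts) <- counts_df[[1]]
      grp <- utils::read.delim(spec$groups, header = TRUE,
                               stringsAsFactors = FALSE)
      de_inputs[[d]] <- list(counts = counts,
                             groups = stats::setNames(grp$group, grp$sample),
                             dataset = d, q_min = spec$q_min, truth = NULL)
    }
  }

  # ---- complex mapping ------------------------------------------------
  resolved <- stage("complex_map", resolve_complexes(cset, mapping))
  stats <- stage("complex_map", complex_stats(resolved, mapping))
  write_complex_table(resolved$kept, file.path(outdir, "complexes_resolved.tsv"))
  write_rejects_report(cset, file.path(outdir, "complex_rejects.tsv"))
  .write_tsv(resolved$dropped, file.path(outdir, "complexes_dropped.tsv"))
  summary$complex_map <- list(
    n_input = nrow(cset$complexes) + nrow(cset$rejects),
    n_after_cleaning = nrow(cset$complexes),
    n_resolved = nrow(resolved$kept),
    n_dropped = nrow(resolved$dropped),
    n_proteins = stats$n_proteins,
    n_genes = stats$n_genes,
    n_transcripts = stats$n_transcripts,
    mean_tx_per_subunit = stats$mean_tx_per_subunit,
    mean_genes_per_subunit = stats$mean_genes_per_subunit,
    frac_subunits_multi_tx = stats$frac_subunits_multi_tx,
    sharing_fraction = stats$sharing_fraction,
    max_complexes_per_protein = stats$max_complexes_per_protein,
    size_hist = as.list(stats$size_hist),
    tx_per_subunit_hist = as.list(stats$tx_per_subunit_hist))

  # ---- detection ------------------------------------------------------
  tx_call <- stage("detection", call_detection(expr, sd_max = sd_max))
  gene_call <- stage("detection", rollup_gene_detection(tx_call, mapping))

  # ---- PFPC -----------------------------------------------------------
  pfpc_tx <- stage("pfpc", call_pfpc(resolved, tx_call, mapping))
  pfpc_gene <- stage("pfpc", call_pfpc(resolved, gene_call, mapping))
  write_pfpc_matrix(pfpc_tx, file.path(outdir, "pfpc_transcript.tsv"))
  write_pfpc_matrix(pfpc_gene, file.path(outdir, "pfpc_gene.tsv"))
  cross <- stage("pfpc", pfpc_cross_sample(pfpc_tx))
  summary$pfpc <- list(
    transcript = list(per_sample = as.list(cross$per_sample),
                      mean_pfpc_fraction = mean(pfpc_tx$summary$pfpc_fraction),
                      mean_gap = mean(pfpc_tx$summary$gap),
                      n_common = length(cross$common),
                      common_fraction = cross$common_fraction,
                      max_sample = cross$max_sample,
                      min_sample = cross$min_sample),
    gene = list(mean_pfpc_fraction = mean(pfpc_gene$summary$pfpc_fraction),
                mean_n_pfpc = mean(pfpc_gene$summary$n_pfpc)))

  # ---- isoform --------------------------------------------------------
  assignment <- stage("isoform", assign_major_isoforms(expr, tx_call, mapping))
  write_major_isoforms(assignment, file.path(outdir, "major_isoforms.tsv"))
  involvement <- stage("isoform",
                       major_involvement(assignment, pfpc_tx, resolved, mapping))
  .write_tsv(involvement, file.path(outdir, "major_involvement.tsv"))
  proteins <- sort(unique(unlist(resolved$kept$subunits, use.names = FALSE)))
  sw <- stage("isoform", switch_matrix(assignment, proteins, mapping))
  sw_df <- data.frame(sample = rownames(sw$fraction), sw$fraction,
                      check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(sw_df, file.path(outdir, "switch_matrix.tsv"))
  off <- sw$fraction[upper.tri(sw$fraction)]
  summary$isoform <- list(
    mean_frac_pfpc_major = mean(involvement$frac_pfpc_major, na.rm = TRUE),
    mean_frac_subunits_major = mean(involvement$frac_subunits_major, na.rm = TRUE),
    n_eligible_components = nrow(sw$eligible),
    switch_min = if (all(is.na(off))) NA else min(off, na.rm = TRUE),
    switch_max = if (all(is.na(off))) NA else max(off, na.rm = TRUE),
    overall_switch_fraction = sw$overall_switch_fraction)

  # ---- differential expression + impact -------------------------------
  impacts <- list()
  summary$de <- list()
  for (d in names(de_inputs)) {
    di <- de_inputs[[d]]
    norm <- stage("de", normalize_median_deviation(di$counts))
    res <- stage("de", noiseq_probability(norm, di$groups))
    de_set <- stage("de", de_call(res, q_min = di$q_min, dataset = d))
    write_de_result(res, file.path(outdir, sprintf("de_%s.tsv", d)),
                    q_min = di$q_min, dataset = d)
    impacts[[d]] <- stage("impact",
                          map_de_to_complexes(de_set, resolved, mapping,
                                              dataset = d))
    summary$de[[d]] <- list(q_min = di$q_min,
                            n_de = length(de_set),
                            n_de_in_complex = length(impacts[[d]]$de_in_complex),
                            n_affected_complexes = length(impacts[[d]]$affected))
  }
  if (length(impacts) >= 2) {
    overlap <- stage("impact", cross_dataset_overlap(impacts))
    write_overlap_matrices(overlap, file.path(outdir, "overlap"))
    amp <- overlap$amplification[upper.tri(overlap$amplification)]
    summary$impact <- list(
      common_complexes = overlap$common_complexes,
      n_common_complexes = length(overlap$common_complexes),
      common_tx = overlap$common_tx,
      n_common_tx = length(overlap$common_tx),
      amplification_range = if (all(is.na(amp))) NULL else
        c(min(amp, na.rm = TRUE), max(amp, na.rm = TRUE)))
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
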