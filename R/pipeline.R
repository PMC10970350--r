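# End-to-end driver: simulate -> sample QC -> variant filters ->
# pathogenicity -> CNV -> phenotype -> cohort summary -> survival,
# writing every declared output file. Also the engine behind the CLI.

#' Run the full analysis pipeline on synthetic data
#'
#' Generates a cohort (variants, coverage, clinical records) from `cfg`,
#' runs every analysis stage, and writes the declared outputs to
#' `out_dir`: simulated inputs (`variants.tsv`, `coverage.tsv`,
#' `manifest.bed`, `blacklist.tsv`, `cohort.tsv`, `truth_labels.tsv`),
#' per-sample QC (`sample_qc.tsv`), filtered and classified variants
#' (`filtered_variants.tsv`, `classified_variants.tsv`), CNV results
#' (`normalized_coverage.tsv`, `amplicon_intervals.tsv`,
#' `cnv_calls.tsv`), phenotypes (`phenotypes.tsv`, LymphGen export
#' files), cohort summaries (`alteration_matrix.tsv`,
#' `gene_frequencies.tsv`, `oncoprint.tsv`, `oncoprint.png` best
#' effort), and survival outputs (`survival_estimates.tsv`,
#' `km_curves.tsv`, `cuminc_curves.tsv`).
#'
#' @param out_dir output directory
#' @param cfg a [sim_config()]
#' @param thresholds an `lbcl_thresholds` object
#' @param group grouping covariate for the survival stage
#' @param quiet suppress progress messages
#' @return invisible list with the in-memory results of every stage and
#'   a `files` vector of written paths
#' @export
run_pipeline <- function(out_dir, cfg = sim_config(),
                         thresholds = default_thresholds(),
                         group = "rituximab", quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) msg(...)
  path <- function(f) file.path(out_dir, f)

  say("simulating inputs (", cfg$n_samples, " samples)")
  manifest <- sim_manifest(cfg)
  vsim <- simulate_variants(cfg, manifest)
  csim <- simulate_coverage(cfg, manifest)
  cohort <- simulate_cohort(cfg)
  write_manifest(manifest, path("manifest.bed"))
  write_variant_table(vsim$variants, path("variants.tsv"))
  write_blacklist(vsim$blacklist, path("blacklist.tsv"))
  write_coverage_matrix(csim$coverage, path("coverage.tsv"))
  utils::write.table(cohort, path("cohort.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(record = seq_len(nrow(vsim$variants)),
               sample_id = vsim$variants$sample_id,
               truth = vsim$variants$truth),
    path("truth_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  say("sample QC")
  qc <- sample_qc(vsim$variants, thresholds)
  utils::write.table(qc, path("sample_qc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  retained <- exclude_failed_samples(vsim$variants, qc)

  say("variant filtering")
  filtered <- apply_filters(retained, thresholds, vsim$blacklist)
  write_variant_table(filtered, path("filtered_variants.tsv"))
  passing <- filtered[filtered$filter_pass, , drop = FALSE]

  say("pathogenicity classification")
  classified <- classify_pathogenic(passing, thresholds, quiet = TRUE)
  write_variant_table(classified, path("classified_variants.tsv"))
  psets <- pathogenic_set(classified)

  say("CNV calling")
  cov <- coverage_sample_qc(csim$coverage, thresholds, quiet = quiet)
  cov <- normalize_coverage(cov, quiet = quiet)
  intervals <- amplicon_intervals(cov, thresholds, quiet = TRUE)
  calls <- call_cnvs(cov, thresholds = thresholds)
  write_coverage_matrix(cov, path("normalized_coverage.tsv"), what = "normalized")
  utils::write.table(intervals, path("amplicon_intervals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(calls, path("cnv_calls.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  say("molecular phenotyping")
  pheno <- phenotype_patients(cohort, thresholds)
  utils::write.table(pheno, path("phenotypes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lg <- lymphgen_export(retained, pheno, out_dir)

  say("cohort summary")
  am <- build_alteration_matrix(psets, cnv_gene_summary(calls), pheno,
                                genes = unique(manifest$gene))
  cells_tab <- data.frame(patient_id = rownames(am$cells), am$cells,
                          check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cells_tab, path("alteration_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  freq <- gene_frequencies(am)
  utils::write.table(freq, path("gene_frequencies.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  onco <- oncoprint_export(am, thresholds)
  utils::write.table(onco$table, path("oncoprint.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  try({
    grDevices::png(path("oncoprint.png"), width = 900, height = 600)
    plot_oncoprint(onco, am)
    grDevices::dev.off()
  }, silent = TRUE)

  say("survival analysis")
  ep <- derive_endpoints(pheno, thresholds)
  surv_out <- list()
  est_rows <- list()
  curves <- list()
  for (endp in c("os", "pfs")) {
    res <- tryCatch(km_and_logrank(ep, endp, group = group),
                    error = function(e) NULL)
    if (is.null(res)) next
    surv_out[[endp]] <- res
    tab <- res$table
    tab$endpoint <- endp
    tab$logrank_p <- res$logrank_p
    est_rows[[endp]] <- tab
    s <- summary(res$fit)
    curves[[endp]] <- data.frame(endpoint = endp,
                                 group = as.character(s$strata %||% "all"),
                                 time = s$time, surv = s$surv,
                                 lower = s$lower, upper = s$upper)
  }
  cr <- tryCatch(competing_risks(ep, group = group), error = function(e) NULL)
  if (length(est_rows))
    utils::write.table(do.call(rbind, est_rows), path("survival_estimates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(curves))
    utils::write.table(do.call(rbind, curves), path("km_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cr)) {
    cif <- if (is.data.frame(cr$cif)) {
      if (nrow(cr$cif)) cbind(group = "all", cr$cif) else NULL
    } else {
      do.call(rbind, lapply(names(cr$cif), function(g) {
        d <- cr$cif[[g]]
        if (nrow(d)) cbind(group = g, d) else NULL
      }))
    }
    if (!is.null(cif))
      utils::write.table(cif, path("cuminc_curves.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }

  files <- list.files(out_dir, full.names = TRUE)
  invisible(list(manifest = manifest, variants = vsim$variants,
                 blacklist = vsim$blacklist, coverage = cov,
                 cnv_truth = csim$truth, cohort = cohort, qc = qc,
                 filtered = filtered, classified = classified,
                 pathogenic_sets = psets, intervals = intervals,
                 cnv_calls = calls, phenotypes = pheno,
                 alteration_matrix = am, frequencies = freq,
                 oncoprint = onco, endpoints = ep, survival = surv_out,
                 competing = cr, lymphgen_files = lg, files = files))
}
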