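# Simulation benchmarks validating the pipeline's operating
# characteristics against the generator's ground truth. These back both
# the package's acceptance checks and reproducibility reporting.

#' FFPE Ts/Tv exclusion rate over simulated samples
#'
#' Simulates single-sample variant tables at a given deamination
#' artifact load and reports the fraction of samples that sample QC
#' excludes for their transition/transversion ratio (or low reads).
#'
#' @param n_seeds number of independent samples simulated
#' @param deamination_load expected C>T/G>A artifacts per sample
#' @param somatic_rate expected true somatic variants per sample
#' @param seed base seed
#' @return fraction of samples excluded
#' @export
benchmark_titv_exclusion <- function(n_seeds = 200, deamination_load = 50,
                                     somatic_rate = 2, seed = 1) {
  excluded <- vapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(n_samples = 1, seed = seed * 1000 + i,
                      deamination_load = deamination_load,
                      somatic_rate = somatic_rate)
    v <- simulate_variants(cfg)$variants
    qc <- sample_qc(v)
    nrow(qc) > 0 && qc$status[1] != "pass"
  }, logical(1))
  mean(excluded)
}

#' CNV recovery benchmark
#'
#' Repeatedly simulates one sequencing run with injected gain/loss
#' events, runs the full CNV stage (coverage QC, normalization,
#' reference intervals, run calling), and scores against truth. A truth
#' event counts as recovered when a call of the same sample, gene and
#' direction overlaps its amplicon span; the false-call rate is the
#' fraction of (sample, gene) pairs without an injected event that
#' receive any call. `contained_calls` counts calls whose run lies
#' entirely inside an event span - with spans below the
#' consecutive-amplicon minimum this is structurally zero, which is the
#' "more than two consecutive amplicons" rule at work.
#'
#' @param n_seeds simulated runs
#' @param n_samples,n_genes,amplicons_per_gene run geometry
#' @param span_amplicons amplicons spanned by each injected event
#' @param n_events injected events per run
#' @param fold_changes candidate fold changes
#' @param noise_sd log2 coverage noise SD
#' @param seed base seed
#' @return list: `recall`, `false_call_rate`, `n_events`,
#'   `n_clean_pairs`, `contained_calls`
#' @export
benchmark_cnv_recovery <- function(n_seeds = 100, n_samples = 16,
                                   n_genes = 20, amplicons_per_gene = 8,
                                   span_amplicons = 4, n_events = 3,
                                   fold_changes = c(0.5, 1.5),
                                   noise_sd = 0.1, seed = 1) {
  hits <- 0L; n_truth <- 0L
  false_calls <- 0L; clean_pairs <- 0L
  contained <- 0L
  for (i in seq_len(n_seeds)) {
    cfg <- sim_config(n_samples = n_samples, n_genes = n_genes,
                      amplicons_per_gene = amplicons_per_gene,
                      coverage_noise_sd = noise_sd,
                      n_cnv_events = n_events,
                      cnv_span_amplicons = span_amplicons,
                      cnv_fold_changes = fold_changes,
                      seed = seed * 1000 + i)
    sim <- simulate_coverage(cfg)
    cov <- coverage_sample_qc(sim$coverage, quiet = TRUE)
    cov <- normalize_coverage(cov, quiet = TRUE)
    calls <- call_cnvs(cov)
    truth <- sim$truth
    n_truth <- n_truth + nrow(truth)
    truth_key <- paste(truth$sample_id, truth$gene)
    for (k in seq_len(nrow(truth))) {
      ov <- calls$sample_id == truth$sample_id[k] &
        calls$gene == truth$gene[k] &
        calls$direction == truth$direction[k] &
        calls$run_start <= truth$amp_end[k] &
        calls$run_end >= truth$amp_start[k]
      if (any(ov)) hits <- hits + 1L
      inside <- ov & calls$run_start >= truth$amp_start[k] &
        calls$run_end <= truth$amp_end[k]
      contained <- contained + sum(inside)
    }
    pair_key <- paste(rep(rownames(cov$raw), times = n_genes),
                      rep(unique(cov$manifest$gene), each = n_samples))
    clean <- setdiff(pair_key, truth_key)
    clean_pairs <- clean_pairs + length(clean)
    call_key <- unique(paste(calls$sample_id, calls$gene))
    false_calls <- false_calls + length(intersect(call_key, clean))
  }
  list(recall = hits / n_truth,
       false_call_rate = false_calls / clean_pairs,
       n_events = n_truth, n_clean_pairs = clean_pairs,
       contained_calls = contained)
}

#' Cox log hazard-ratio recovery benchmark
#'
#' Simulates two-arm cohorts with a known treatment hazard ratio on
#' lymphoma death (no competing cause), derives endpoints, fits the Cox
#' model, and reports the mean log-HR bias across seeds.
#'
#' @param n_seeds number of simulated cohorts
#' @param n patients per cohort
#' @param true_hr true hazard ratio of the treated arm
#' @param seed base seed
#' @return list: `mean_loghr`, `bias` (mean log-HR minus log true HR),
#'   `censor_fraction`, `within` (fraction of per-seed HR estimates in
#'   [1.6, 2.5] when `true_hr` is 2)
#' @export
benchmark_cox_recovery <- function(n_seeds = 200, n = 500, true_hr = 2,
                                   seed = 1) {
  loghr <- numeric(n_seeds)
  censored <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- sim_config(n_samples = n, seed = seed * 1000 + i,
                      hazard_lymphoma = 0.03, hazard_other = 0,
                      hazard_progression = 0.008, censor_rate = 0.012,
                      loghr_lymphoma = c(rituximab = log(true_hr),
                                         myd88_mutation = 0),
                      loghr_progression = c(rituximab = 0, myd88_mutation = 0))
    coh <- simulate_cohort(cfg)
    coh$disease_category <- "primary"
    ep <- derive_endpoints(coh)
    fit <- survival::coxph(survival::Surv(os_time, os_event) ~ rituximab,
                           data = ep, ties = "efron")
    loghr[i] <- unname(stats::coef(fit)[1])
    censored[i] <- mean(ep$os_event == 0)
  }
  list(mean_loghr = mean(loghr),
       bias = mean(loghr) - log(true_hr),
       censor_fraction = mean(censored),
       within = mean(exp(loghr) >= 1.6 & exp(loghr) <= 2.5))
}

#' Null-hypothesis type-I error of the comparative tests
#'
#' Simulates cohorts in which the grouping covariate has no effect on
#' any cause-specific hazard, and reports the rejection rates of the
#' log-rank test (overall survival) and Gray's test (disease-specific
#' mortality) at the 5% level, plus the largest deviation of the
#' cumulative-incidence conservation identity (cause incidences plus
#' all-cause survival must equal one) over all simulated datasets.
#'
#' @param n_reps simulated cohorts
#' @param n patients per cohort
#' @param seed base seed
#' @return list: `logrank_rate`, `gray_rate`, `max_conservation_dev`
#' @export
benchmark_null_type1 <- function(n_reps = 1000, n = 120, seed = 1) {
  lr_rej <- logical(n_reps)
  gray_rej <- rep(NA, n_reps)
  max_dev <- 0
  for (i in seq_len(n_reps)) {
    cfg <- sim_config(n_samples = n, seed = seed * 2000 + i,
                      hazard_lymphoma = 0.012, hazard_other = 0.006,
                      censor_rate = 0.008,
                      loghr_lymphoma = c(rituximab = 0, myd88_mutation = 0),
                      loghr_progression = c(rituximab = 0, myd88_mutation = 0))
    coh <- simulate_cohort(cfg)
    coh$disease_category <- "primary"
    ep <- derive_endpoints(coh)
    sd_ <- survival::survdiff(survival::Surv(os_time, os_event) ~ rituximab,
                              data = ep)
    lr_rej[i] <- stats::pchisq(sd_$chisq, 1, lower.tail = FALSE) < 0.05
    if (sum(ep$dsm_status == 1) > 0 && length(unique(ep$rituximab)) == 2) {
      ci <- cmprsk::cuminc(ftime = ep$dsm_time, fstatus = ep$dsm_status,
                           group = ep$rituximab, cencode = 0)
      gray_rej[i] <- ci$Tests["1", "pv"] < 0.05
    }
    cc <- cuminc_aj(ep$dsm_time, ep$dsm_status)
    if (nrow(cc)) {
      cif_cols <- grep("^cif", names(cc), value = TRUE)
      dev <- max(abs(rowSums(cc[, cif_cols, drop = FALSE]) + cc$surv - 1))
      max_dev <- max(max_dev, dev)
    }
  }
  list(logrank_rate = mean(lr_rej),
       gray_rate = mean(gray_rej, na.rm = TRUE),
       max_conservation_dev = max_dev)
}
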