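#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe
#' a small, fast cohort (28 samples on a 20-gene x 8-amplicon panel)
#' whose artifact structure mimics targeted amplicon sequencing of FFPE
#' lymphoma tissue: true somatic variants, common germline polymorphisms,
#' formalin-deamination C>T/G>A artifacts, strand-biased calls, and
#' homopolymer indel artifacts. Use `full_scale = TRUE` for the
#' full-size panel (128 genes, 3359 amplicons, two pools).
#'
#' @param n_samples number of tumor samples / patients
#' @param n_genes,amplicons_per_gene synthetic panel geometry (ignored
#'   when `full_scale = TRUE`)
#' @param full_scale use the 128-gene / 3359-amplicon panel preset
#' @param somatic_rate expected true pathogenic-track variants per sample
#'   (Poisson)
#' @param germline_common_rate expected common-polymorphism calls per
#'   sample (population frequency > 1% or blacklist members)
#' @param deamination_load expected C>T/G>A deamination artifacts per
#'   sample
#' @param strand_bias_artifact_rate expected strand-biased artifact calls
#'   per sample
#' @param homopolymer_artifact_rate expected homopolymer indel artifacts
#'   per sample
#' @param depth_mean,depth_dispersion negative-binomial read-depth model
#'   per variant (mean reads; dispersion = NB size)
#' @param purity tumor purity; somatic VAFs are Beta-distributed around
#'   `purity / 2`
#' @param ts_prob transition probability of the non-deamination SNV
#'   spectrum
#' @param coverage_mean mean per-sample sequencing scale of the coverage
#'   matrix (reads)
#' @param coverage_noise_sd multiplicative log2-scale noise SD of the
#'   coverage matrix
#' @param n_cnv_events number of copy-number events injected into the
#'   coverage matrix (ignored when `cnv_truth` given)
#' @param cnv_span_amplicons consecutive amplicons spanned by each
#'   injected event
#' @param cnv_fold_changes candidate fold changes for injected events
#'   (values < 1 are losses, > 1 gains)
#' @param cnv_truth optional explicit event table with columns
#'   `sample_id`, `gene`, `fold_change`, `span_amplicons`
#' @param hazard_lymphoma,hazard_other cause-specific exponential hazards
#'   (per month) of lymphoma death and other-cause death
#' @param hazard_progression exponential hazard (per month) of
#'   progression/relapse
#' @param censor_rate exponential random-censoring hazard (per month)
#' @param followup_horizon_months maximum simulated follow-up
#' @param loghr_lymphoma,loghr_progression named numeric vectors of
#'   log hazard ratios applied to the lymphoma-death and progression
#'   hazards; names must be cohort covariates (`rituximab`,
#'   `myd88_mutation`)
#' @param seed master seed; all generator streams derive from it
#' @return a `sim_config` list
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 8, seed = 1)
sim_config <- function(n_samples = 28,
                       n_genes = 20,
                       amplicons_per_gene = 8,
                       full_scale = FALSE,
                       somatic_rate = 6,
                       germline_common_rate = 4,
                       deamination_load = 0,
                       strand_bias_artifact_rate = 1,
                       homopolymer_artifact_rate = 1,
                       depth_mean = 1000,
                       depth_dispersion = 5,
                       purity = 0.7,
                       ts_prob = 0.4,
                       coverage_mean = 500,
                       coverage_noise_sd = 0.1,
                       n_cnv_events = 3,
                       cnv_span_amplicons = 4,
                       cnv_fold_changes = c(0.5, 1.5),
                       cnv_truth = NULL,
                       hazard_lymphoma = 0.0075,
                       hazard_other = 0.0045,
                       hazard_progression = 0.008,
                       censor_rate = 0.005,
                       followup_horizon_months = 120,
                       loghr_lymphoma = c(rituximab = -1.5, myd88_mutation = 0.8),
                       loghr_progression = c(rituximab = -1.0, myd88_mutation = 0.4),
                       seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(cfg$somatic_rate, cfg$germline_common_rate, cfg$deamination_load,
             cfg$strand_bias_artifact_rate, cfg$homopolymer_artifact_rate,
             cfg$hazard_lymphoma, cfg$hazard_other, cfg$hazard_progression,
             cfg$censor_rate)
  if (any(rates < 0)) stop("simulation rates and hazards must be >= 0")
  if (any(cfg$cnv_fold_changes <= 0)) stop("fold changes must be > 0")
  if (cfg$cnv_span_amplicons < 1) stop("CNV span must be >= 1 amplicon")
  if (cfg$purity <= 0 || cfg$purity > 1) stop("purity must lie in (0, 1]")
  structure(cfg, class = "sim_config")
}

# Resolve the manifest implied by a sim_config.
sim_manifest <- function(cfg) {
  if (isTRUE(cfg$full_scale)) full_panel_manifest()
  else build_manifest(cfg$n_genes, cfg$amplicons_per_gene)
}
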