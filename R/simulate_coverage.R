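# Synthetic amplicon coverage matrix for one sequencing run, with
# injected contiguous gene-level gains/losses as CNV truth.

#' Simulate an amplicon coverage matrix with injected CNVs
#'
#' True coverage is separable: an independently drawn per-sample depth
#' scale (log-normal; this is what the sample-median normalization step
#' must remove) times a per-amplicon efficiency (log-normal). Injected
#' copy-number events multiply true coverage by their fold change over a
#' contiguous run of amplicons inside one gene; log-normal noise with
#' `coverage_noise_sd` (log2 scale) is applied on top. If `cfg$cnv_truth`
#' is `NULL`, `cfg$n_cnv_events` events are placed on random
#' (sample, gene) pairs with span `cfg$cnv_span_amplicons` and fold
#' changes drawn from `cfg$cnv_fold_changes`.
#'
#' @param cfg a [sim_config()] object
#' @param manifest optional manifest (defaults to the one implied by `cfg`)
#' @return list with `coverage` (an `amplicon_coverage` object) and
#'   `truth` (data.frame: sample_id, gene, direction, fold_change,
#'   amp_start, amp_end, span_amplicons)
#' @export
#' @examples
#' sim <- simulate_coverage(sim_config(n_samples = 6, seed = 7))
#' sim$truth
simulate_coverage <- function(cfg, manifest = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(manifest)) manifest <- sim_manifest(cfg)
  set.seed(split_seed(cfg$seed, "coverage"))
  sample_ids <- sprintf("S%03d", seq_len(cfg$n_samples))
  n_amp <- nrow(manifest)

  sample_scale <- cfg$coverage_mean * exp(stats::rnorm(cfg$n_samples, 0, 0.5))
  amp_effect <- exp(stats::rnorm(n_amp, 0, 0.4))
  true_cov <- outer(sample_scale, amp_effect)
  dimnames(true_cov) <- list(sample_ids, manifest$amplicon_id)

  truth <- cfg$cnv_truth
  if (is.null(truth)) {
    n_ev <- cfg$n_cnv_events
    if (n_ev > 0) {
      genes <- unique(manifest$gene)
      pairs <- expand.grid(sample_id = sample_ids, gene = genes,
                           stringsAsFactors = FALSE)
      pick <- sample.int(nrow(pairs), min(n_ev, nrow(pairs)))
      truth <- data.frame(
        sample_id = pairs$sample_id[pick],
        gene = pairs$gene[pick],
        fold_change = sample(cfg$cnv_fold_changes, length(pick), replace = TRUE),
        span_amplicons = cfg$cnv_span_amplicons,
        stringsAsFactors = FALSE
      )
    } else {
      truth <- data.frame(sample_id = character(0), gene = character(0),
                          fold_change = numeric(0), span_amplicons = integer(0))
    }
  }

  if (nrow(truth)) {
    truth$amp_start <- NA_integer_
    truth$amp_end <- NA_integer_
    for (i in seq_len(nrow(truth))) {
      idx <- which(manifest$gene == truth$gene[i])
      if (!length(idx))
        stop("CNV truth gene not on panel: ", truth$gene[i])
      span <- truth$span_amplicons[i]
      if (span > length(idx))
        stop("CNV span (", span, ") exceeds amplicon count (", length(idx),
             ") of gene ", truth$gene[i])
      start_off <- sample.int(length(idx) - span + 1L, 1L)
      run <- idx[start_off:(start_off + span - 1L)]
      truth$amp_start[i] <- run[1]
      truth$amp_end[i] <- run[length(run)]
      true_cov[truth$sample_id[i], run] <-
        true_cov[truth$sample_id[i], run] * truth$fold_change[i]
    }
    truth$direction <- ifelse(truth$fold_change < 1, "loss", "gain")
  } else {
    truth$amp_start <- integer(0); truth$amp_end <- integer(0)
    truth$direction <- character(0)
  }

  noisy <- true_cov * 2^stats::rnorm(length(true_cov), 0, cfg$coverage_noise_sd)
  cov <- coverage_matrix(noisy, manifest, run_id = paste0("simrun", cfg$seed))
  list(coverage = cov, truth = truth)
}
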