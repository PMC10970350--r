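# Coverage normalization, reference intervals, and consecutive-amplicon
# CNV calling, with brute-force oracle equivalence.

# coverage object from an explicit matrix on a small panel
cov_from_matrix <- function(m, n_genes = 4, amplicons_per_gene = 5) {
  manifest <- build_manifest(n_genes, amplicons_per_gene)
  stopifnot(ncol(m) == nrow(manifest))
  colnames(m) <- manifest$amplicon_id
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  coverage_matrix(m, manifest)
}

test_that("separable matrices normalize to exactly one everywhere", {
  set.seed(1)
  scales <- exp(rnorm(6, 0, 1))
  effects <- exp(rnorm(20, 0, 0.5))
  cov <- cov_from_matrix(outer(scales, effects) * 300)
  cov <- normalize_coverage(cov, quiet = TRUE)
  expect_equal(max(abs(cov$log2_normalized)), 0, tolerance = 1e-10)

  # scale invariance: multiplying one sample's row changes nothing
  cov2 <- cov_from_matrix(outer(scales, effects) * 300 *
                            ifelse(seq_len(6) == 3, 17, 1))
  cov2 <- normalize_coverage(cov2, quiet = TRUE)
  expect_equal(cov2$log2_normalized, cov$log2_normalized, tolerance = 1e-10)
})

test_that("normalization needs 3 samples and masks zero-median amplicons", {
  set.seed(2)
  m <- matrix(runif(40, 200, 400), nrow = 2)
  expect_error(normalize_coverage(cov_from_matrix(m), quiet = TRUE), ">= 3")

  m3 <- matrix(runif(60, 200, 400), nrow = 3)
  m3[, 7] <- 0
  cov <- normalize_coverage(cov_from_matrix(m3), quiet = TRUE)
  amp7 <- cov$manifest$amplicon_id[7]
  expect_true(amp7 %in% cov$masked_amplicons)
  expect_true(all(is.na(cov$log2_normalized[, 7])))
})

test_that("reference intervals: degenerate columns, override level, calibration", {
  manifest <- build_manifest(15, 4)   # includes CDKN2A among real symbols
  set.seed(3)
  n_s <- 40
  m <- matrix(300 * 2^rnorm(n_s * nrow(manifest), 0, 0.1), nrow = n_s)
  colnames(m) <- manifest$amplicon_id
  rownames(m) <- sprintf("S%02d", seq_len(n_s))
  cov <- normalize_coverage(coverage_matrix(m, manifest), quiet = TRUE)
  iv <- amplicon_intervals(cov, quiet = TRUE)

  expect_identical(unique(iv$ci_level[iv$gene == "CDKN2A"]), 0.95)
  expect_identical(unique(iv$ci_level[iv$gene != "CDKN2A"]), 0.99)
  # widths scale as z(level): CDKN2A intervals narrower by 1.960/2.576
  w <- iv$upper - iv$lower
  sds <- unname(apply(cov$log2_normalized, 2, sd))
  expect_equal(w, ifelse(iv$gene == "CDKN2A", 2 * qnorm(0.975),
                         2 * qnorm(0.995)) * sds, tolerance = 1e-10)

  # a column that is constant on the normalized scale collapses to a point
  sep <- outer(exp(rnorm(6, 0, 1)), exp(rnorm(nrow(manifest), 0, 0.5))) * 300
  colnames(sep) <- manifest$amplicon_id
  rownames(sep) <- sprintf("Z%02d", 1:6)
  cov2 <- normalize_coverage(coverage_matrix(sep, manifest), quiet = TRUE)
  expect_message(iv2 <- amplicon_intervals(cov2), "zero cross-sample SD")
  expect_equal(iv2$lower, iv2$upper, tolerance = 1e-10)

  # percentile alternative stays inside the data range
  ivp <- amplicon_intervals(cov, method = "percentile", quiet = TRUE)
  expect_true(all(ivp$lower >= apply(cov$log2_normalized, 2, min) - 1e-12))
  expect_true(all(ivp$upper <= apply(cov$log2_normalized, 2, max) + 1e-12))
})

test_that("a 99% interval excludes about 1% of fresh standard draws", {
  set.seed(4)
  # many samples so mean/SD estimates are tight, then fresh draws
  n_s <- 500
  manifest <- build_manifest(2, 3)
  m <- matrix(400 * 2^rnorm(n_s * 6, 0, 0.2), nrow = n_s)
  colnames(m) <- manifest$amplicon_id
  rownames(m) <- sprintf("S%03d", seq_len(n_s))
  cov <- normalize_coverage(coverage_matrix(m, manifest), quiet = TRUE)
  iv <- amplicon_intervals(cov, quiet = TRUE)
  j <- 1
  fresh <- rnorm(20000, mean(cov$log2_normalized[, j]),
                 sd(cov$log2_normalized[, j]))
  outside <- mean(fresh < iv$lower[j] | fresh > iv$upper[j])
  expect_gt(outside, 0.005)
  expect_lt(outside, 0.02)
})

test_that("calls require more than two consecutive exceeding amplicons", {
  manifest <- build_manifest(3, 6)
  set.seed(5)
  n_s <- 12
  m <- matrix(500 * 2^rnorm(n_s * 18, 0, 0.05), nrow = n_s)
  colnames(m) <- manifest$amplicon_id
  rownames(m) <- sprintf("S%02d", seq_len(n_s))
  # sample 1: 2 consecutive low amplicons in gene 1 -> no call
  m[1, 1:2] <- m[1, 1:2] * 0.4
  # sample 2: 3 consecutive low amplicons in gene 2 -> loss call
  m[2, 7:9] <- m[2, 7:9] * 0.4
  # sample 3: alternating high/low -> no call
  m[3, 13:18] <- m[3, 13:18] * rep(c(2, 0.4), 3)
  cov <- normalize_coverage(coverage_matrix(m, manifest), quiet = TRUE)
  iv <- amplicon_intervals(cov, quiet = TRUE)
  calls <- call_cnvs(cov, iv)
  expect_false("S01" %in% calls$sample_id)
  expect_false("S03" %in% calls$sample_id)
  s2 <- calls[calls$sample_id == "S02", ]
  expect_identical(nrow(s2), 1L)
  expect_identical(s2$direction, "loss")
  expect_identical(s2$run_start, 7L)
  expect_identical(s2$run_end, 9L)
  expect_identical(s2$gene, manifest$gene[7])

  # every amplicon of every call strictly exceeds its interval
  for (k in seq_len(nrow(calls))) {
    run <- calls$run_start[k]:calls$run_end[k]
    x <- cov$log2_normalized[calls$sample_id[k], run]
    if (calls$direction[k] == "loss") expect_true(all(x < iv$lower[run]))
    else expect_true(all(x > iv$upper[run]))
  }
})

test_that("runs never cross gene boundaries", {
  manifest <- build_manifest(2, 3)
  set.seed(6)
  n_s <- 10
  m <- matrix(500 * 2^rnorm(n_s * 6, 0, 0.05), nrow = n_s)
  colnames(m) <- manifest$amplicon_id
  rownames(m) <- sprintf("S%02d", seq_len(n_s))
  # low run of 4 amplicons straddling the gene 1 / gene 2 boundary (2+2)
  m[1, 2:5] <- m[1, 2:5] * 0.4
  cov <- normalize_coverage(coverage_matrix(m, manifest), quiet = TRUE)
  expect_identical(nrow(call_cnvs(cov)), 0L)
})

test_that("narrower intervals can only add calls (CI monotonicity)", {
  cfg <- sim_config(n_samples = 16, seed = 23, n_cnv_events = 4)
  cov <- normalize_coverage(simulate_coverage(cfg)$coverage, quiet = TRUE)
  th99 <- default_thresholds(); th99$ci_level_overrides <- list()
  th90 <- th99; th90$ci_level_default <- 0.90
  calls99 <- call_cnvs(cov, amplicon_intervals(cov, th99, quiet = TRUE), th99)
  calls90 <- call_cnvs(cov, amplicon_intervals(cov, th90, quiet = TRUE), th90)
  expect_gte(nrow(calls90), nrow(calls99))
  # every 99%-level call survives at 90% (possibly as a longer run)
  for (k in seq_len(nrow(calls99))) {
    match_k <- calls90$sample_id == calls99$sample_id[k] &
      calls90$gene == calls99$gene[k] &
      calls90$direction == calls99$direction[k] &
      calls90$run_start <= calls99$run_start[k] &
      calls90$run_end >= calls99$run_end[k]
    expect_true(any(match_k))
  }
})

test_that("run detection equals the brute-force scanner on random matrices", {
  th <- default_thresholds()
  for (seed in 1:25) {
    set.seed(seed)
    manifest <- build_manifest(sample(2:5, 1), sample(3:7, 1))
    n_s <- sample(6:12, 1)
    n_a <- nrow(manifest)
    m <- matrix(400 * 2^rnorm(n_s * n_a, 0, 0.15), nrow = n_s)
    # sprinkle strong shifts so runs of varied lengths appear
    for (r in seq_len(3)) {
      s <- sample(n_s, 1); a <- sample(n_a - 3, 1)
      span <- a:(a + sample(1:3, 1))
      m[s, span] <- m[s, span] * sample(c(0.3, 3), 1)
    }
    colnames(m) <- manifest$amplicon_id
    rownames(m) <- sprintf("S%02d", seq_len(n_s))
    cov <- normalize_coverage(coverage_matrix(m, manifest), quiet = TRUE)
    iv <- amplicon_intervals(cov, th, quiet = TRUE)
    calls <- call_cnvs(cov, iv, th)
    for (sid in rownames(m)) {
      x <- cov$log2_normalized[sid, ]
      status <- ifelse(x > iv$upper, 1L, ifelse(x < iv$lower, -1L, 0L))
      want <- oracle_scan_runs(status, manifest$gene, th$min_consecutive_amplicons)
      got <- calls[calls$sample_id == sid,
                   c("gene", "run_start", "run_end", "direction")]
      got <- got[order(got$run_start), ]
      want <- want[order(want$start), ]
      expect_identical(unname(as.matrix(got)),
                       unname(as.matrix(want[, c("gene", "start", "end",
                                                 "direction")])))
    }
  }
})

test_that("leave-one-out intervals detect a modest gain reliably", {
  manifest <- build_manifest(6, 8)
  set.seed(77)
  m <- matrix(500 * 2^rnorm(16 * 48, 0, 0.1), nrow = 16)
  colnames(m) <- manifest$amplicon_id
  rownames(m) <- sprintf("S%02d", 1:16)
  g2 <- which(manifest$gene == manifest$gene[9])[1:4]
  m[5, g2] <- m[5, g2] * 1.5          # 1.5x gain over 4 amplicons
  cov <- normalize_coverage(coverage_matrix(m, manifest), quiet = TRUE)
  calls <- call_cnvs(cov)             # leave-one-out default
  hit <- calls$sample_id == "S05" & calls$gene == manifest$gene[9] &
    calls$direction == "gain"
  expect_true(any(hit))
  # leave-one-out and cohort-wide bounds agree on event-free samples
  iv <- amplicon_intervals(cov, quiet = TRUE)
  cohort_calls <- call_cnvs(cov, iv)
  expect_true(all(cohort_calls$sample_id %in% calls$sample_id))
})

test_that("permuting gene blocks neither creates nor destroys calls", {
  cfg <- sim_config(n_samples = 12, seed = 41, n_cnv_events = 3)
  sim <- simulate_coverage(cfg)
  cov <- normalize_coverage(sim$coverage, quiet = TRUE)
  calls <- call_cnvs(cov)
  sig <- function(calls) {
    s <- paste(calls$sample_id, calls$gene, calls$direction, calls$run_length)
    sort(s)
  }
  # reverse the order of gene blocks, keeping genes internally intact
  manifest <- cov$manifest
  blocks <- split(seq_len(nrow(manifest)), manifest$gene)
  perm <- unlist(rev(blocks[unique(manifest$gene)]), use.names = FALSE)
  m2 <- manifest[perm, ]
  rownames(m2) <- NULL
  raw2 <- sim$coverage$raw[, perm]
  # keep manifest valid: reassign coordinates in the new order
  m2$start <- seq_len(nrow(m2)) * 1000
  m2$end <- m2$start + 149
  m2$chrom <- "chr1"
  cov2 <- normalize_coverage(coverage_matrix(raw2, m2), quiet = TRUE)
  expect_identical(sig(call_cnvs(cov2)), sig(calls))
})

test_that("coverage sample QC flags low-coverage and high-dispersion samples", {
  cfg <- sim_config(n_samples = 10, seed = 33, n_cnv_events = 0)
  sim <- simulate_coverage(cfg)
  cov0 <- coverage_sample_qc(sim$coverage, quiet = TRUE)
  expect_length(cov0$qc_excluded, 0)   # clean run: no exclusions

  # degenerate thresholds disable the filters entirely
  th_off <- default_thresholds()
  th_off$cov_qc_min_median <- 0; th_off$cov_qc_max_iqr <- Inf
  expect_length(coverage_sample_qc(sim$coverage, th_off, quiet = TRUE)$qc_excluded, 0)

  # one sample with 10x the multiplicative noise of the rest -> excluded
  noisy <- sim$coverage
  set.seed(99)
  noisy$raw[4, ] <- noisy$raw[4, ] * 2^rnorm(ncol(noisy$raw), 0, 1.0)
  cov1 <- coverage_sample_qc(noisy, quiet = TRUE)
  expect_identical(cov1$qc_excluded, rownames(noisy$raw)[4])

  # one sample with collapsed coverage -> excluded
  low <- sim$coverage
  low$raw[2, ] <- low$raw[2, ] * 0.01
  cov2 <- coverage_sample_qc(low, quiet = TRUE)
  expect_true(rownames(low$raw)[2] %in% cov2$qc_excluded)

  # all samples failing is a hard error
  dead <- sim$coverage
  dead$raw <- dead$raw * 0.001
  expect_error(coverage_sample_qc(dead, quiet = TRUE), "every sample")
})

test_that("gene-level summary reports ambiguous dual-direction genes", {
  calls <- data.frame(
    sample_id = c("A", "A", "A", "B"),
    gene = c("PIM1", "PIM1", "MYC", "PIM1"),
    direction = c("gain", "loss", "gain", "loss"),
    run_start = 1L, run_end = 3L, run_length = 3L,
    ci_level = 0.99, mean_log2 = 0.5, stringsAsFactors = FALSE)
  gs <- cnv_gene_summary(calls)
  gs <- gs[order(gs$sample_id, gs$gene), ]
  expect_identical(gs$direction[gs$sample_id == "A" & gs$gene == "PIM1"],
                   "ambiguous")
  expect_true(gs$ambiguous[gs$sample_id == "A" & gs$gene == "PIM1"])
  expect_identical(gs$direction[gs$sample_id == "B"], "loss")
})
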