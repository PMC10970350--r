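# Alteration matrix construction and descriptive cohort outputs.

small_am <- function() {
  patients <- data.frame(
    patient_id = c("P1", "P2", "P3"),
    disease_category = c("primary", "primary", "relapsed"),
    stringsAsFactors = FALSE)
  psets <- data.frame(sample_id = c("P1", "P1", "P2"),
                      gene = c("PIM1", "MYD88", "PIM1"),
                      stringsAsFactors = FALSE)
  cnv <- data.frame(sample_id = c("P1", "P2"), gene = c("CDKN2A", "PIM1"),
                    direction = c("loss", "gain"), stringsAsFactors = FALSE)
  build_alteration_matrix(psets, cnv, patients,
                          genes = c("PIM1", "MYD88", "CDKN2A", "TP53"))
}

test_that("matrix cells union evidence and keep empty patients", {
  am <- small_am()
  expect_identical(am$cells["P1", "PIM1"], "pathogenic_variant")
  expect_identical(am$cells["P1", "CDKN2A"], "loss")
  expect_identical(sort(strsplit(am$cells["P2", "PIM1"], ";")[[1]]),
                   c("gain", "pathogenic_variant"))   # multi-type cell
  expect_true(all(am$cells["P3", ] == ""))            # zero-alteration patient kept
  expect_identical(am$patients, c("P1", "P2", "P3"))

  bad <- data.frame(sample_id = "P1", gene = "NOT_A_GENE")
  empty_cnv <- data.frame(sample_id = character(0), gene = character(0),
                          direction = character(0))
  expect_error(build_alteration_matrix(bad, empty_cnv,
                                       data.frame(patient_id = "P1"),
                                       genes = c("PIM1")), "unknown gene")
})

test_that("marginals match a brute-force recount of the inputs", {
  cfg <- sim_config(n_samples = 20, seed = 44)
  sim <- simulate_variants(cfg)
  qc <- sample_qc(sim$variants)
  filt <- apply_filters(exclude_failed_samples(sim$variants, qc),
                        blacklist = sim$blacklist)
  cls <- classify_pathogenic(filt[filt$filter_pass, ], quiet = TRUE)
  psets <- pathogenic_set(cls)
  coh <- simulate_cohort(cfg)
  am <- build_alteration_matrix(psets, data.frame(sample_id = character(0),
                                                  gene = character(0),
                                                  direction = character(0)),
                                coh, genes = unique(sim$manifest$gene))
  freq <- gene_frequencies(am)
  for (g in freq$gene) {
    expect_identical(freq$count[freq$gene == g],
                     length(unique(psets$sample_id[psets$gene == g &
                                                     psets$sample_id %in% coh$patient_id])))
  }
  # double-counting identity: sum of gene counts == sum of patient burdens
  burden <- per_patient_burden(am, mode = "variants_only")
  expect_identical(sum(freq$count), as.integer(sum(burden$counts)))
})

test_that("percentages round half away from zero on the printed scale", {
  am <- small_am()
  freq <- gene_frequencies(am)
  expect_identical(freq$n[1], 3L)
  # 4 of 14 -> 29%, 3 of 6 -> 50%, 0 -> 0% on constructed counts
  expect_identical(as.integer(lbclpanel:::round_half_up(100 * 4 / 14)), 29L)
  expect_identical(as.integer(lbclpanel:::round_half_up(100 * 3 / 6)), 50L)
  expect_identical(freq$percent[freq$gene == "TP53"], 0L)
  # half-away-from-zero where round() would go to even
  expect_identical(lbclpanel:::round_half_up(2.5), 3)
  expect_identical(lbclpanel:::round_half_up(-2.5), -3)
  # group filtering uses the group denominator
  f2 <- gene_frequencies(am, group = c("P1", "P2"))
  expect_identical(f2$percent[f2$gene == "PIM1"], 100L)
  expect_error(gene_frequencies(am, group = "NOPE"), "empty")
})

test_that("per-patient burden uses interpolated quartiles", {
  am <- small_am()
  b <- per_patient_burden(am, "variants_and_cnvs")
  # P2's variant and gain hit the same gene, so one distinct altered gene
  expect_identical(unname(b$counts), c(3, 1, 0))
  expect_identical(b$median, 1)
  bv <- per_patient_burden(am, "variants_only")
  expect_identical(unname(bv$counts), c(2, 1, 0))

  # burdens [2,5,9] -> median 5; interpolation oracle computed by hand:
  # type-7 quartiles of (2,5,9) are 3.5 and 7
  counts <- c(2, 5, 9)
  q <- quantile(counts, c(.25, .5, .75), type = 7, names = FALSE)
  expect_identical(q, c(3.5, 5, 7))

  # single patient: median and both quartile endpoints equal its count
  solo <- build_alteration_matrix(
    data.frame(sample_id = "P1", gene = "PIM1"),
    data.frame(sample_id = character(0), gene = character(0),
               direction = character(0)),
    data.frame(patient_id = "P1"), genes = c("PIM1", "TP53"))
  bs <- per_patient_burden(solo)
  expect_identical(c(bs$q1, bs$median, bs$q3), c(1, 1, 1))

  # random burdens match a hand-rolled linear-interpolation oracle
  set.seed(14)
  x <- sort(sample(0:12, 9, replace = TRUE))
  manual_q <- function(p) {
    h <- (length(x) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  expect_equal(quantile(x, c(.25, .75), type = 7, names = FALSE),
               c(manual_q(.25), manual_q(.75)))
})

test_that("burden counts are invariant to patient order permutation", {
  am <- small_am()
  f1 <- gene_frequencies(am)
  am2 <- am
  perm <- c(3, 1, 2)
  am2$patients <- am$patients[perm]
  am2$cells <- am$cells[perm, ]
  expect_identical(gene_frequencies(am2), f1)
})

test_that("oncoprint retains genes strictly above the frequency cutoff", {
  # 28 patients: one gene altered in 1 (3.6%, dropped), one in 2 (7.1%, kept)
  patients <- data.frame(patient_id = sprintf("P%02d", 1:28),
                         disease_category = "primary",
                         stringsAsFactors = FALSE)
  psets <- data.frame(sample_id = c("P01", "P01", "P02"),
                      gene = c("RARE", "COMMON", "COMMON"),
                      stringsAsFactors = FALSE)
  am <- build_alteration_matrix(psets,
                                data.frame(sample_id = character(0),
                                           gene = character(0),
                                           direction = character(0)),
                                patients, genes = c("RARE", "COMMON", "EMPTY"))
  onco <- oncoprint_export(am)
  expect_identical(onco$genes, "COMMON")
  # retained set equals a brute-force threshold scan
  freq <- gene_frequencies(am)
  expect_identical(onco$genes, freq$gene[freq$count / freq$n > 0.05])
  # all genes below the cutoff -> empty output with a warning
  am_empty <- build_alteration_matrix(
    psets[psets$gene == "RARE", ],
    data.frame(sample_id = character(0), gene = character(0),
               direction = character(0)),
    patients, genes = c("RARE"))
  expect_warning(oncoprint_export(am_empty), "no gene")
})
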