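# Sample QC (Ts/Tv, mean reads) and per-variant filters, including the
# boundary semantics and the brute-force oracle equivalence.

test_that("Ts/Tv counts transitions over transversions with sentinels", {
  v <- data.frame(ref = c("C", "G", "A", "C"), alt = c("T", "A", "G", "A"))
  expect_equal(compute_titv(v), 3)

  pure_ts <- data.frame(ref = rep("C", 10), alt = rep("T", 10))
  expect_identical(compute_titv(pure_ts), Inf)

  indels_only <- data.frame(ref = c("AT", "A"), alt = c("A", "AT"))
  expect_identical(compute_titv(indels_only), NA_real_)

  # indels are ignored alongside SNVs
  mixed <- rbind(v, indels_only)
  expect_equal(compute_titv(mixed), 3)
})

test_that("Ts/Tv on uniform random substitutions matches a brute-force recount", {
  set.seed(42)
  pairs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  idx <- sample(nrow(pairs), 500, replace = TRUE)
  v <- pairs[idx, ]
  # independent recount straight from the definition
  ts <- sum((v$ref == "A" & v$alt == "G") | (v$ref == "G" & v$alt == "A") |
              (v$ref == "C" & v$alt == "T") | (v$ref == "T" & v$alt == "C"))
  expect_equal(compute_titv(v), ts / (500 - ts))
  # 4 of 12 substitution types are transitions -> ratio near 0.5
  expect_gt(compute_titv(v), 0.3)
  expect_lt(compute_titv(v), 0.8)
})

test_that("sample QC applies boundary-inclusive exclusions with Ts/Tv precedence", {
  mk_sample <- function(sid, n_ts, n_tv, depth) {
    rbind(
      if (n_ts) do.call(rbind, lapply(seq_len(n_ts), function(i)
        make_variant(sample_id = sid, pos = i, ref = "C", alt = "T", depth = depth))),
      if (n_tv) do.call(rbind, lapply(seq_len(n_tv), function(i)
        make_variant(sample_id = sid, pos = 100 + i, ref = "C", alt = "A", depth = depth)))
    )
  }
  v <- rbind(
    mk_sample("EXACT5", 10, 2, 500),    # titv exactly 5 -> excluded (inclusive)
    mk_sample("LOWREADS", 1, 1, 99.9),  # mean reads < 100 -> excluded
    mk_sample("PASS", 49, 10, 100),     # titv 4.9, reads exactly 100 -> pass
    mk_sample("BOTH", 10, 1, 50)        # titv 10 and low reads -> titv wins
  )
  qc <- sample_qc(v)
  status <- setNames(qc$status, qc$sample_id)
  expect_identical(status[["EXACT5"]], "excluded_titv")
  expect_identical(status[["LOWREADS"]], "excluded_low_reads")
  expect_identical(status[["PASS"]], "pass")
  expect_identical(status[["BOTH"]], "excluded_titv")
  expect_true(qc$repair_candidate[qc$sample_id == "EXACT5"])
  expect_false(qc$repair_candidate[qc$sample_id == "LOWREADS"])

  kept <- exclude_failed_samples(v, qc)
  expect_identical(sort(unique(kept$sample_id)), "PASS")
  expect_identical(nrow(sample_qc(v[0, ])), 0L)
})

test_that("per-variant filters encode the stated boundaries", {
  th <- default_thresholds()
  cases <- rbind(
    make_variant(pos = 1, depth = 100, vaf = 0.10),                   # pass: inclusive
    make_variant(pos = 2, depth = 99, vaf = 0.5),                     # min_depth
    make_variant(pos = 3, depth = 500, vaf = 0.099),                  # min_vaf
    make_variant(pos = 4, population_freq = 0.011),                   # popfreq strict
    make_variant(pos = 5, population_freq = 0.010),                   # 1% exactly passes
    make_variant(pos = 6, alt_forward = 91, alt_reverse = 9),         # bias 0.91 fails
    make_variant(pos = 7, alt_forward = 90, alt_reverse = 10),        # bias 0.90 passes
    make_variant(pos = 8, ref = "A", alt = "AT", homopolymer_context = 5),  # hp indel
    make_variant(pos = 9, ref = "A", alt = "AT", homopolymer_context = 4),  # short run ok
    make_variant(pos = 10, ref = "C", alt = "T", homopolymer_context = 7),  # SNV exempt
    make_variant(pos = 11, in_normal_blacklist = TRUE),               # blacklist
    make_variant(pos = 12, alt_forward = 0, alt_reverse = 0, vaf = 0) # malformed
  )
  out <- apply_filters(cases, th)
  flag <- setNames(out$filter_flags, out$pos)
  expect_identical(flag[["1"]], "")
  expect_identical(flag[["2"]], "min_depth")
  expect_identical(flag[["3"]], "min_vaf")
  expect_identical(flag[["4"]], "population_frequency")
  expect_identical(flag[["5"]], "")
  expect_identical(flag[["6"]], "strand_bias")
  expect_identical(flag[["7"]], "")
  expect_identical(flag[["8"]], "homopolymer_indel")
  expect_identical(flag[["9"]], "")
  expect_identical(flag[["10"]], "")
  expect_identical(flag[["11"]], "normal_blacklist")
  expect_match(flag[["12"]], "malformed")
  expect_identical(out$filter_pass, out$filter_flags == "")

  # flags are cumulative
  multi <- apply_filters(make_variant(depth = 50, vaf = 0.05,
                                      population_freq = 0.3), th)
  expect_identical(strsplit(multi$filter_flags, ";")[[1]],
                   c("min_depth", "min_vaf", "population_frequency"))
})

test_that("a blacklist table flags matching sites like the inline column", {
  v <- rbind(make_variant(pos = 777, in_normal_blacklist = FALSE),
             make_variant(pos = 778, in_normal_blacklist = FALSE))
  bl <- data.frame(chrom = "chr1", pos = 777, ref = "C", alt = "T",
                   stringsAsFactors = FALSE)
  out <- apply_filters(v, blacklist = bl)
  expect_identical(out$filter_flags, c("normal_blacklist", ""))
})

test_that("filtering is idempotent, order-independent, and per-record", {
  v <- random_boundary_variants(200, seed = 5)
  once <- apply_filters(v)
  twice <- apply_filters(once)
  expect_identical(once$filter_flags, twice$filter_flags)

  perm <- sample(nrow(v))
  shuffled <- apply_filters(v[perm, ])
  expect_identical(shuffled$filter_flags, once$filter_flags[perm])

  # removing one sample leaves every other record's flags unchanged
  drop <- v$sample_id != v$sample_id[1]
  expect_identical(apply_filters(v[drop, ])$filter_flags,
                   once$filter_flags[drop])
})

test_that("filters match the brute-force oracle on boundary-spanning records", {
  v <- random_boundary_variants(400, seed = 9)
  expect_identical(apply_filters(v)$filter_pass, oracle_filter_pass(v))
})

test_that("on labeled synthetic data the artifact classes all fail filtering", {
  cfg <- sim_config(n_samples = 12, seed = 31, germline_common_rate = 5,
                    strand_bias_artifact_rate = 3, homopolymer_artifact_rate = 3)
  sim <- simulate_variants(cfg)
  out <- apply_filters(sim$variants, blacklist = sim$blacklist)
  expect_true(all(!out$filter_pass[out$truth %in%
                                     c("germline_common", "strand_bias_artifact",
                                       "homopolymer_artifact")]))
  # true somatic records fail only through depth/VAF, by construction
  ts <- out[out$truth == "true_somatic", ]
  viol <- ts$depth < 100 | ts$vaf < 0.10
  expect_identical(!ts$filter_pass, viol)
})
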