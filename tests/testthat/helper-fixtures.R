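# Fixture builders shared across test files. All fixtures are built in
# code; nothing is read from disk except files the tests write themselves.

# One fully-specified variant record with overridable fields.
make_variant <- function(...) {
  v <- list(
    sample_id = "S001", gene = "MYD88", chrom = "chr1", pos = 1000101,
    ref = "C", alt = "T", depth = 500, vaf = 0.35,
    alt_forward = 88, alt_reverse = 87, population_freq = 0.001,
    in_normal_blacklist = FALSE, homopolymer_context = 0,
    pathogenicity_class = 5, cadd_phred = NA_real_,
    sift = NA_character_, polyphen2_hdiv = NA_character_,
    lrt = NA_character_, mutationtaster = NA_character_
  )
  over <- list(...)
  v[names(over)] <- over
  as.data.frame(v, stringsAsFactors = FALSE)
}

make_variants <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# Random variant records spanning the filter-threshold boundaries,
# used by the filter-oracle equivalence checks.
random_boundary_variants <- function(n, seed) {
  set.seed(seed)
  boundary_or_unif <- function(boundary, lo, hi) {
    pick <- sample(c("boundary", "unif"), n, replace = TRUE, prob = c(0.4, 0.6))
    out <- stats::runif(n, lo, hi)
    b <- sample(boundary, n, replace = TRUE)
    out[pick == "boundary"] <- b[pick == "boundary"]
    out
  }
  depth <- round(boundary_or_unif(c(99, 100, 101), 10, 2000))
  vaf <- boundary_or_unif(c(0.099, 0.10, 0.101), 0, 1)
  alt <- pmin(depth, pmax(0, round(vaf * depth)))
  bias <- boundary_or_unif(c(0.89, 0.90, 0.91), 0.5, 1)
  alt_forward <- round(alt * bias)
  is_indel <- stats::runif(n) < 0.25
  ref <- ifelse(is_indel, "AT", sample(c("A", "C", "G", "T"), n, replace = TRUE))
  alt_allele <- ifelse(is_indel, "A", "G")
  alt_allele[!is_indel & ref == "G"] <- "A"
  data.frame(
    sample_id = sample(sprintf("S%02d", 1:5), n, replace = TRUE),
    gene = sample(c("MYD88", "PIM1", "CDKN2A"), n, replace = TRUE),
    chrom = "chr1",
    pos = sample(1e6:2e6, n, replace = TRUE),
    ref = ref, alt = alt_allele,
    depth = depth, vaf = pmin(1, ifelse(depth > 0, alt / depth, 0)),
    alt_forward = alt_forward, alt_reverse = alt - alt_forward,
    population_freq = boundary_or_unif(c(0.009, 0.010, 0.011), 0, 0.2),
    in_normal_blacklist = stats::runif(n) < 0.1,
    homopolymer_context = sample(c(0, 3, 4, 5, 6), n, replace = TRUE),
    pathogenicity_class = sample(1:5, n, replace = TRUE),
    cadd_phred = NA_real_,
    sift = NA_character_, polyphen2_hdiv = NA_character_,
    lrt = NA_character_, mutationtaster = NA_character_,
    stringsAsFactors = FALSE
  )
}

# Independent brute-force filter written directly against the stated
# rules, record by record: depth >= 100 and VAF >= 10% required;
# popfreq > 1%, blacklist membership, strand bias > 90%, homopolymer
# indels, and zero alt reads excluded.
oracle_filter_pass <- function(v, th = default_thresholds()) {
  pass <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    ok <- TRUE
    if (v$depth[i] < th$min_read_depth) ok <- FALSE
    if (v$vaf[i] < th$min_vaf) ok <- FALSE
    if (!is.na(v$population_freq[i]) && v$population_freq[i] > th$max_population_freq)
      ok <- FALSE
    if (isTRUE(v$in_normal_blacklist[i])) ok <- FALSE
    tot <- v$alt_forward[i] + v$alt_reverse[i]
    if (tot == 0) ok <- FALSE
    else if (max(v$alt_forward[i], v$alt_reverse[i]) / tot > th$max_strand_bias)
      ok <- FALSE
    snv <- nchar(v$ref[i]) == 1 && nchar(v$alt[i]) == 1 &&
      v$ref[i] %in% c("A", "C", "G", "T") && v$alt[i] %in% c("A", "C", "G", "T")
    if (!snv && !is.na(v$homopolymer_context[i]) &&
        v$homopolymer_context[i] >= th$homopolymer_min_run)
      ok <- FALSE
    pass[i] <- ok
  }
  pass
}

# Independent brute-force consecutive-exceedance scanner for CNV runs:
# for one sample's status row (+1 above, -1 below, 0 inside, NA masked),
# enumerate every qualifying window per gene by direct scanning.
oracle_scan_runs <- function(status, gene, min_run) {
  out <- list()
  for (g in unique(gene)) {
    idx <- which(gene == g)
    i <- 1
    while (i <= length(idx)) {
      v <- status[idx[i]]
      if (is.na(v) || v == 0) { i <- i + 1; next }
      j <- i
      while (j < length(idx) && !is.na(status[idx[j + 1]]) &&
             status[idx[j + 1]] == v) j <- j + 1
      if (j - i + 1 >= min_run)
        out[[length(out) + 1]] <- data.frame(
          gene = g, start = idx[i], end = idx[j],
          direction = if (v == 1) "gain" else "loss",
          stringsAsFactors = FALSE)
      i <- j + 1
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(0), start = integer(0), end = integer(0),
               direction = character(0))
}
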