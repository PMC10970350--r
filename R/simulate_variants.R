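# Synthetic variant-table generator with known truth labels. Every
# record carries exactly one label in {true_somatic, germline_common,
# deamination_artifact, strand_bias_artifact, homopolymer_artifact}.

.ts_pairs <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C"),
                    ncol = 2, byrow = TRUE)
.tv_pairs <- matrix(c("A", "C", "C", "A", "A", "T", "T", "A",
                      "C", "G", "G", "C", "G", "T", "T", "G"),
                    ncol = 2, byrow = TRUE)

# draw n SNV ref/alt pairs with the given transition probability
draw_snv <- function(n, ts_prob) {
  ts <- stats::runif(n) < ts_prob
  idx_ts <- sample.int(nrow(.ts_pairs), n, replace = TRUE)
  idx_tv <- sample.int(nrow(.tv_pairs), n, replace = TRUE)
  ref <- ifelse(ts, .ts_pairs[idx_ts, 1], .tv_pairs[idx_tv, 1])
  alt <- ifelse(ts, .ts_pairs[idx_ts, 2], .tv_pairs[idx_tv, 2])
  cbind(ref, alt)
}

# depth / VAF / strand counts for n records; balanced strand split is
# clamped so honest records never trip the >90% strand-bias rule
draw_reads <- function(n, cfg, vaf_mean, vaf_conc = 20, biased = FALSE) {
  depth <- pmax(1, stats::rnbinom(n, mu = cfg$depth_mean, size = cfg$depth_dispersion))
  vaf <- stats::rbeta(n, vaf_mean * vaf_conc, (1 - vaf_mean) * vaf_conc)
  alt <- pmin(depth, pmax(1, round(vaf * depth)))
  if (biased) {
    minor <- floor(alt * 0.05)  # guarantees max-strand fraction >= 0.95
    fwd_major <- stats::runif(n) < 0.5
    alt_forward <- ifelse(fwd_major, alt - minor, minor)
  } else {
    alt_forward <- stats::rbinom(n, alt, 0.5)
    frac <- ifelse(alt > 0, pmax(alt_forward, alt - alt_forward) / alt, 0.5)
    fix <- frac > 0.9
    alt_forward[fix] <- floor(alt[fix] / 2)
  }
  data.frame(depth = depth, vaf = alt / depth,
             alt_forward = alt_forward, alt_reverse = alt - alt_forward)
}

# place n records on random amplicons of the panel
draw_sites <- function(n, manifest) {
  row <- sample.int(nrow(manifest), n, replace = TRUE)
  data.frame(gene = manifest$gene[row],
             chrom = manifest$chrom[row],
             pos = floor(stats::runif(n, manifest$start[row], manifest$end[row] + 1)),
             stringsAsFactors = FALSE)
}

draw_predictors <- function(n, p_path) {
  draw1 <- function() {
    x <- ifelse(stats::runif(n) < p_path, "pathogenic", "benign")
    x[stats::runif(n) < 0.1] <- NA_character_
    x
  }
  data.frame(sift = draw1(), polyphen2_hdiv = draw1(),
             lrt = draw1(), mutationtaster = draw1(),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic panel-of-normals blacklist
#'
#' @param manifest panel manifest
#' @param n_sites number of recurrent technical sites
#' @return blacklist `data.frame` (chrom, pos, ref, alt)
#' @export
simulate_blacklist <- function(manifest, n_sites = 2 * length(unique(manifest$gene))) {
  sites <- draw_sites(n_sites, manifest)
  snv <- draw_snv(n_sites, 0.5)
  data.frame(chrom = sites$chrom, pos = sites$pos,
             ref = snv[, 1], alt = snv[, 2], gene = sites$gene,
             stringsAsFactors = FALSE)
}

#' Simulate a variant call table with truth labels
#'
#' Per sample, draws Poisson numbers of records from five generating
#' classes and labels each row with its class in a `truth` column:
#' \describe{
#'   \item{true_somatic}{clonal somatic variants; VAF Beta around
#'     `purity / 2`, SNV spectrum with transition probability `ts_prob`,
#'     population frequency below 1%, balanced strands, pathogenicity
#'     class 3-5 with CADD/predictor annotations for class 3.}
#'   \item{germline_common}{common polymorphisms: population frequency
#'     above 1%, or low-frequency sites drawn from the generated
#'     panel-of-normals blacklist; VAF near 0.5 or 1.}
#'   \item{deamination_artifact}{formalin-fixation signature: exclusively
#'     C>T or G>A transitions at low VAF.}
#'   \item{strand_bias_artifact}{over 90% of alt reads on one strand.}
#'   \item{homopolymer_artifact}{indels flanked by homopolymer runs of
#'     5-8 bp.}
#' }
#' Deterministic given `cfg$seed` (stream-split, so variants, coverage,
#' and cohort draws are independent).
#'
#' @param cfg a [sim_config()] object
#' @param manifest optional manifest (defaults to the one implied by `cfg`)
#' @return list with elements `variants` (data.frame with `truth`
#'   column), `blacklist` (data.frame), and `manifest`
#' @export
#' @examples
#' sim <- simulate_variants(sim_config(n_samples = 4, seed = 42))
#' table(sim$variants$truth)
simulate_variants <- function(cfg, manifest = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(manifest)) manifest <- sim_manifest(cfg)
  set.seed(split_seed(cfg$seed, "variants"))
  blacklist <- simulate_blacklist(manifest)
  sample_ids <- sprintf("S%03d", seq_len(cfg$n_samples))

  make_class <- function(sid, n, label) {
    if (n == 0) return(NULL)
    sites <- draw_sites(n, manifest)
    base <- data.frame(sample_id = rep(sid, n), sites,
                       stringsAsFactors = FALSE)
    base$in_normal_blacklist <- FALSE
    base$homopolymer_context <- sample(0:3, n, replace = TRUE)
    base$population_freq <- stats::runif(n, 0, 0.008)
    if (label == "true_somatic") {
      indel <- stats::runif(n) < 0.15
      snv <- draw_snv(n, cfg$ts_prob)
      base$ref <- snv[, 1]; base$alt <- snv[, 2]
      ins <- indel & stats::runif(n) < 0.5
      base$alt[ins] <- paste0(base$ref[ins], base$ref[ins])
      del <- indel & !ins
      base$ref[del] <- paste0(base$alt[del], base$alt[del])
      reads <- draw_reads(n, cfg, vaf_mean = cfg$purity / 2)
      base$pathogenicity_class <- sample(3:5, n, replace = TRUE,
                                         prob = c(0.4, 0.25, 0.35))
      base$cadd_phred <- ifelse(base$pathogenicity_class == 3,
                                stats::runif(n, 0, 40), NA_real_)
      pred <- draw_predictors(n, p_path = 0.5)
    } else if (label == "germline_common") {
      snv <- draw_snv(n, cfg$ts_prob)
      base$ref <- snv[, 1]; base$alt <- snv[, 2]
      base$population_freq <- stats::runif(n, 0.011, 0.5)
      use_bl <- stats::runif(n) < 0.3 & nrow(blacklist) > 0
      if (any(use_bl)) {
        pick <- sample.int(nrow(blacklist), sum(use_bl), replace = TRUE)
        base$chrom[use_bl] <- blacklist$chrom[pick]
        base$pos[use_bl] <- blacklist$pos[pick]
        base$ref[use_bl] <- blacklist$ref[pick]
        base$alt[use_bl] <- blacklist$alt[pick]
        base$gene[use_bl] <- blacklist$gene[pick]
        base$in_normal_blacklist[use_bl] <- TRUE
        base$population_freq[use_bl] <- stats::runif(sum(use_bl), 0, 0.009)
      }
      hom <- stats::runif(n) < 0.1
      reads <- draw_reads(n, cfg, vaf_mean = 0.5, vaf_conc = 60)
      reads$vaf[hom] <- pmin(1, reads$vaf[hom] * 2)
      base$pathogenicity_class <- sample(1:2, n, replace = TRUE, prob = c(0.6, 0.4))
      base$cadd_phred <- NA_real_
      pred <- draw_predictors(n, p_path = 0.05)
    } else if (label == "deamination_artifact") {
      ga <- stats::runif(n) < 0.5
      base$ref <- ifelse(ga, "G", "C")
      base$alt <- ifelse(ga, "A", "T")
      reads <- draw_reads(n, cfg, vaf_mean = 0.15)
      base$pathogenicity_class <- sample(2:3, n, replace = TRUE)
      base$cadd_phred <- ifelse(base$pathogenicity_class == 3,
                                stats::runif(n, 0, 9), NA_real_)
      pred <- draw_predictors(n, p_path = 0.1)
    } else if (label == "strand_bias_artifact") {
      snv <- draw_snv(n, cfg$ts_prob)
      base$ref <- snv[, 1]; base$alt <- snv[, 2]
      reads <- draw_reads(n, cfg, vaf_mean = 0.2, biased = TRUE)
      base$pathogenicity_class <- sample(2:3, n, replace = TRUE)
      base$cadd_phred <- ifelse(base$pathogenicity_class == 3,
                                stats::runif(n, 0, 20), NA_real_)
      pred <- draw_predictors(n, p_path = 0.2)
    } else {  # homopolymer_artifact
      b <- sample(c("A", "T"), n, replace = TRUE)
      ins <- stats::runif(n) < 0.5
      base$ref <- ifelse(ins, b, paste0(b, b))
      base$alt <- ifelse(ins, paste0(b, b), b)
      base$homopolymer_context <- sample(5:8, n, replace = TRUE)
      reads <- draw_reads(n, cfg, vaf_mean = 0.15)
      base$pathogenicity_class <- rep(3L, n)
      base$cadd_phred <- stats::runif(n, 0, 15)
      pred <- draw_predictors(n, p_path = 0.2)
    }
    base$depth <- reads$depth
    base$vaf <- reads$vaf
    base$alt_forward <- reads$alt_forward
    base$alt_reverse <- reads$alt_reverse
    base$truth <- label
    cbind(base, pred)
  }

  rates <- c(true_somatic = cfg$somatic_rate,
             germline_common = cfg$germline_common_rate,
             deamination_artifact = cfg$deamination_load,
             strand_bias_artifact = cfg$strand_bias_artifact_rate,
             homopolymer_artifact = cfg$homopolymer_artifact_rate)
  out <- list()
  for (sid in sample_ids) {
    counts <- stats::rpois(length(rates), rates)
    names(counts) <- names(rates)
    for (label in names(rates))
      out[[length(out) + 1L]] <- make_class(sid, counts[[label]], label)
  }
  cols <- c(.variant_required, "in_normal_blacklist", "homopolymer_context", "truth")
  variants <- do.call(rbind, out)
  if (is.null(variants)) {
    variants <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    variants <- variants[, cols]
    rownames(variants) <- NULL
  }
  list(variants = variants, blacklist = blacklist, manifest = manifest)
}
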