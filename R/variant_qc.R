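# Sample-level exclusion and per-variant filtering.
#
# Boundary semantics (encoded one-sidedly, unit-tested at the boundary):
#   depth >= 100 and VAF >= 10% pass (inclusive);
#   Ts/Tv >= 5 excludes the sample (inclusive);
#   mean sample reads < 100 excludes (strict);
#   population frequency > 1% fails (strict);
#   strand bias > 90% fails (strict).
# Ts/Tv is computed on all called SNVs before per-variant filtering.

#' Transition/transversion ratio of one sample's calls
#'
#' Counts transitions (A<->G, C<->T) and transversions among single-base
#' substitutions; indels are ignored. Returns `Inf` when there are
#' transitions but no transversions (the sample is then unquestionably
#' past any exclusion threshold) and `NA` when there are no SNVs at all.
#'
#' @param variants variant `data.frame` (typically one sample's rows)
#' @return a single ratio
#' @export
#' @examples
#' v <- data.frame(ref = c("C", "G", "A", "C"), alt = c("T", "A", "G", "A"))
#' compute_titv(v)  # 3 transitions / 1 transversion
compute_titv <- function(variants) {
  snv <- is_snv(variants$ref, variants$alt)
  if (!any(snv)) return(NA_real_)
  ts <- sum(is_transition(variants$ref[snv], variants$alt[snv]))
  tv <- sum(snv) - ts
  if (tv == 0) {
    if (ts > 0) Inf else NA_real_
  } else {
    ts / tv
  }
}

#' Sample-level quality control
#'
#' One report row per sample. A sample is excluded when its
#' transition/transversion ratio reaches `titv_exclusion` (formalin
#' deamination signature; such samples are flagged `repair_candidate`,
#' modeling the re-prepare-with-DNA-repair-kit-and-re-run path) or when
#' its mean read count falls below `min_sample_mean_reads`; the Ts/Tv
#' exclusion takes precedence when both hold.
#'
#' @param variants variant `data.frame` (all samples)
#' @param thresholds an `lbcl_thresholds` object
#' @return `data.frame`: sample_id, n_variants, titv_ratio,
#'   mean_read_count, status (pass / excluded_titv / excluded_low_reads),
#'   repair_candidate
#' @export
sample_qc <- function(variants, thresholds = default_thresholds()) {
  if (nrow(variants) == 0)
    return(data.frame(sample_id = character(0), n_variants = integer(0),
                      titv_ratio = numeric(0), mean_read_count = numeric(0),
                      status = character(0), repair_candidate = logical(0)))
  ids <- unique(variants$sample_id)
  reports <- lapply(ids, function(sid) {
    v <- variants[variants$sample_id == sid, ]
    titv <- compute_titv(v)
    mean_reads <- mean(v$depth)
    status <- if (!is.na(titv) && titv >= thresholds$titv_exclusion) {
      "excluded_titv"
    } else if (mean_reads < thresholds$min_sample_mean_reads) {
      "excluded_low_reads"
    } else "pass"
    data.frame(sample_id = sid, n_variants = nrow(v), titv_ratio = titv,
               mean_read_count = mean_reads, status = status,
               repair_candidate = status == "excluded_titv",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, reports)
}

#' Drop QC-excluded samples from a variant table
#'
#' @param variants variant `data.frame`
#' @param qc_report output of [sample_qc()]
#' @return the table restricted to passing samples
#' @export
exclude_failed_samples <- function(variants, qc_report) {
  keep <- qc_report$sample_id[qc_report$status == "pass"]
  variants[variants$sample_id %in% keep, , drop = FALSE]
}

#' Per-variant exclusion filters
#'
#' Applies the variant-level rules cumulatively; a record may fail
#' several and passes iff no flag is raised:
#' \itemize{
#'   \item `min_depth`: depth below `min_read_depth` (pass is inclusive
#'     at the threshold);
#'   \item `min_vaf`: variant allele frequency below `min_vaf`;
#'   \item `population_frequency`: population frequency strictly above
#'     `max_population_freq`;
#'   \item `normal_blacklist`: site present in the panel-of-normals
#'     blacklist (healthy-donor DNA mixtures);
#'   \item `strand_bias`: `max(alt_forward, alt_reverse) / (alt_forward +
#'     alt_reverse)` strictly above `max_strand_bias`;
#'   \item `homopolymer_indel`: indel flanked by a homopolymer run of at
#'     least `homopolymer_min_run` bases;
#'   \item `malformed`: no alt-supporting reads (strand bias undefined).
#' }
#'
#' @param variants variant `data.frame` (sample QC already applied)
#' @param thresholds an `lbcl_thresholds` object
#' @param blacklist optional blacklist `data.frame` (chrom, pos, ref,
#'   alt), OR-combined with any `in_normal_blacklist` column
#' @return the table with `filter_flags` (semicolon-joined, `""` when
#'   clean) and logical `filter_pass` columns added
#' @export
apply_filters <- function(variants, thresholds = default_thresholds(),
                          blacklist = NULL) {
  n <- nrow(variants)
  flags <- vector("list", n)
  if (n) flags[] <- list(character(0))
  add <- function(which, flag) {
    for (i in which(which)) flags[[i]] <<- c(flags[[i]], flag)
  }
  if (n) {
    add(variants$depth < thresholds$min_read_depth, "min_depth")
    add(variants$vaf < thresholds$min_vaf, "min_vaf")
    pf <- variants$population_freq
    add(!is.na(pf) & pf > thresholds$max_population_freq, "population_frequency")

    in_bl <- isTRUE_vec(variants$in_normal_blacklist)
    if (!is.null(blacklist) && nrow(blacklist)) {
      key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
      in_bl <- in_bl | key(variants) %in% key(blacklist)
    }
    add(in_bl, "normal_blacklist")

    alt_tot <- variants$alt_forward + variants$alt_reverse
    bias <- ifelse(alt_tot > 0,
                   pmax(variants$alt_forward, variants$alt_reverse) / alt_tot, NA)
    add(!is.na(bias) & bias > thresholds$max_strand_bias, "strand_bias")
    add(alt_tot == 0, "malformed")

    hrun <- variants$homopolymer_context %||% rep(0, n)
    hrun[is.na(hrun)] <- 0
    indel <- !is_snv(variants$ref, variants$alt)
    add(indel & hrun >= thresholds$homopolymer_min_run, "homopolymer_indel")
  }
  variants$filter_flags <- vapply(flags, paste, "", collapse = ";")
  variants$filter_pass <- !nzchar(variants$filter_flags)
  variants
}
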