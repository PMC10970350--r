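# Molecular phenotyping: Hans cell-of-origin, double-expressor status,
# disease categorization, and LymphGen membership handling. IHC inputs
# are percentages of positively stained tumor cells (0-100); cutoffs in
# the thresholds object are fractions and are scaled by 100 here.

#' Hans cell-of-origin classification
#'
#' Immunohistochemical decision tree over CD10, BCL6 and MUM1 with a
#' shared positivity cutoff (default 30% positive tumor cells,
#' boundary-inclusive): CD10+ is GCB; CD10-/BCL6- is non-GCB;
#' CD10-/BCL6+/MUM1+ is non-GCB; CD10-/BCL6+/MUM1- is GCB. The tree is
#' encoded as ordered rules so it is inspectable. Vectorized; a missing
#' marker that the tree needs yields `NA` (unclassifiable).
#'
#' @param cd10_pct,bcl6_pct,mum1_pct percent positive tumor cells (0-100)
#' @param cutoff positivity cutoff as a fraction (default 0.30)
#' @return character vector, `"GCB"` / `"non-GCB"` / `NA`
#' @export
#' @examples
#' hans_classify(30, 0, 0)   # GCB: CD10 positive at the boundary
#' hans_classify(0, 80, 80)  # non-GCB
hans_classify <- function(cd10_pct, bcl6_pct, mum1_pct, cutoff = 0.30) {
  cut_pct <- cutoff * 100
  n <- max(length(cd10_pct), length(bcl6_pct), length(mum1_pct))
  cd10 <- rep_len(cd10_pct, n) >= cut_pct
  bcl6 <- rep_len(bcl6_pct, n) >= cut_pct
  mum1 <- rep_len(mum1_pct, n) >= cut_pct
  # ordered rule list: first match wins; unreachable markers may be missing
  out <- rep(NA_character_, n)
  k <- function(x) !is.na(x) & x          # known and positive
  kn <- function(x) !is.na(x) & !x        # known and negative
  out[k(cd10)] <- "GCB"
  out[kn(cd10) & kn(bcl6)] <- "non-GCB"
  out[kn(cd10) & k(bcl6) & k(mum1)] <- "non-GCB"
  out[kn(cd10) & k(bcl6) & kn(mum1)] <- "GCB"
  out
}

#' Double-expressor status
#'
#' Immunohistochemical co-overexpression of MYC and BCL2, with
#' boundary-inclusive cutoffs (defaults 40% and 50% positive tumor
#' cells). Missing markers yield `NA` (unknown).
#'
#' @param myc_pct,bcl2_pct percent positive tumor cells (0-100)
#' @param thresholds an `lbcl_thresholds` object
#' @return logical vector
#' @export
#' @examples
#' double_expressor(40, 50)    # TRUE at both boundaries
#' double_expressor(39.9, 90)  # FALSE
double_expressor <- function(myc_pct, bcl2_pct,
                             thresholds = default_thresholds()) {
  myc_pct >= thresholds$myc_expr_cutoff * 100 &
    bcl2_pct >= thresholds$bcl2_expr_cutoff * 100
}

#' Disease categorization
#'
#' Assigns each patient exactly one category: patients with a prior
#' lymphoma are `relapsed` - except when the prior diagnosis was
#' untreated small lymphocytic lymphoma bone-marrow involvement without
#' transformation (`prior_sll_untransformed`), which does not count
#' against a primary categorization. Otherwise Ann Arbor stage IE/IIE is
#' `primary` (localized), III/IV is `disseminated`, and unstaged
#' patients are `unstaged`.
#'
#' @param patients `data.frame` with columns `ann_arbor` (IE, IIE, III,
#'   IV, unstaged), `prior_lymphoma`, `prior_sll_untransformed`
#' @return character vector of categories
#' @export
categorize_disease <- function(patients) {
  stage <- patients$ann_arbor
  valid <- c("IE", "IIE", "III", "IV", "unstaged")
  bad <- setdiff(unique(stage), valid)
  if (length(bad))
    stop("invalid Ann Arbor stage value(s): ", paste(bad, collapse = ", "))
  if (any(patients$prior_sll_untransformed & !patients$prior_lymphoma))
    stop("prior_sll_untransformed requires prior_lymphoma")
  relapsed <- patients$prior_lymphoma & !patients$prior_sll_untransformed
  out <- ifelse(relapsed, "relapsed",
                ifelse(stage %in% c("IE", "IIE"), "primary",
                       ifelse(stage %in% c("III", "IV"), "disseminated",
                              "unstaged")))
  out
}

#' LymphGen membership from subtype probabilities
#'
#' Classes with probability strictly above the member threshold (default
#' 0.50) are subtype labels. Exactly one label with probability strictly
#' above the core threshold (default 0.90) makes the tumor a core
#' member; exactly one label at or below it, an extended member; two or
#' more labels, a genetic composite (rendered as the alphabetically
#' ordered `"A/B"` string); no label, `other` (unclassified).
#'
#' @param probabilities named numeric vector of subtype probabilities
#'   (e.g. over MCD, EZB, ST2, BN2, N1, A53)
#' @param thresholds an `lbcl_thresholds` object
#' @return list with `labels` (character), `membership` (`core` /
#'   `extended` / `composite` / `other`), and `label` (display string,
#'   `"other"` when unclassified)
#' @export
#' @examples
#' membership_from_probabilities(c(EZB = 0.95))           # core EZB
#' membership_from_probabilities(c(EZB = 0.6, ST2 = 0.55)) # composite EZB/ST2
membership_from_probabilities <- function(probabilities,
                                          thresholds = default_thresholds()) {
  p <- probabilities
  if (is.null(names(p)) || any(!nzchar(names(p))))
    stop("probabilities must be a named vector")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  labels <- names(p)[!is.na(p) & p > thresholds$lymphgen_member_prob]
  labels <- sort(labels)
  membership <- if (length(labels) == 0) {
    "other"
  } else if (length(labels) >= 2) {
    "composite"
  } else if (p[labels] > thresholds$lymphgen_core_prob) {
    "core"
  } else {
    "extended"
  }
  list(labels = labels, membership = membership,
       label = if (length(labels)) paste(labels, collapse = "/") else "other")
}

#' Per-patient phenotype table
#'
#' Applies [hans_classify()], [double_expressor()],
#' [categorize_disease()] and [membership_from_probabilities()] to a
#' cohort table (as produced by [simulate_cohort()] or read from a
#' clinical TSV with the same columns).
#'
#' @param patients cohort `data.frame`
#' @param thresholds an `lbcl_thresholds` object
#' @return the table with `coo`, `double_expressor`, `disease_category`,
#'   `lymphgen_label`, `lymphgen_membership` columns added
#' @export
phenotype_patients <- function(patients, thresholds = default_thresholds()) {
  patients$coo <- hans_classify(patients$cd10_pct, patients$bcl6_pct,
                                patients$mum1_pct, thresholds$hans_cutoff)
  patients$double_expressor <- double_expressor(patients$myc_pct,
                                                patients$bcl2_pct, thresholds)
  patients$disease_category <- categorize_disease(patients)
  prob_cols <- grep("^p_", names(patients), value = TRUE)
  if (length(prob_cols)) {
    memb <- lapply(seq_len(nrow(patients)), function(i) {
      p <- unlist(patients[i, prob_cols])
      names(p) <- sub("^p_", "", prob_cols)
      membership_from_probabilities(p, thresholds)
    })
    patients$lymphgen_label <- vapply(memb, `[[`, "", "label")
    patients$lymphgen_membership <- vapply(memb, `[[`, "", "membership")
  }
  patients
}

#' Export retained variants in the external subtype classifier's layout
#'
#' Writes the input files for the external genetic-subtype classifier:
#' a per-sample mutation list over all retained variants - including
#' variants of unknown pathogenicity and benign variants, i.e. after
#' sample QC and variant filtering but deliberately before the
#' pathogenicity cascade - and a sample table with BCL2/BCL6
#' rearrangement status propagated verbatim. Copy-number results are
#' intentionally omitted (targeted panels provide limited CNV data).
#'
#' @param variants variant `data.frame` post sample-QC (not
#'   pathogenicity-filtered)
#' @param rearrangements `data.frame` with `patient_id`, `bcl2_rearr`,
#'   `bcl6_rearr`
#' @param out_dir output directory (created if needed)
#' @return invisible list of the two written paths (`mutations`,
#'   `samples`)
#' @export
lymphgen_export <- function(variants, rearrangements, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mut <- data.frame(
    sample_id = variants$sample_id,
    gene = variants$gene,
    chrom = variants$chrom,
    pos = variants$pos,
    ref = variants$ref,
    alt = variants$alt,
    type = ifelse(is_snv(variants$ref, variants$alt), "SNV", "indel"),
    stringsAsFactors = FALSE
  )
  samp <- data.frame(
    sample_id = rearrangements$patient_id,
    bcl2_rearranged = as.integer(rearrangements$bcl2_rearr),
    bcl6_rearranged = as.integer(rearrangements$bcl6_rearr),
    stringsAsFactors = FALSE
  )
  mut_path <- file.path(out_dir, "lymphgen_mutations.tsv")
  samp_path <- file.path(out_dir, "lymphgen_samples.tsv")
  utils::write.table(mut, mut_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(samp, samp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(mutations = mut_path, samples = samp_path))
}
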