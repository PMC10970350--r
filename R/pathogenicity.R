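# Rule cascade deciding which annotated variants count as pathogenic.
#
# Class 4 and 5 are pathogenic outright. Class 3 (unknown significance)
# is upgraded when CADD-PHRED exceeds 25, or when CADD lies in the
# closed band [10, 25] and at least 2 of the four prediction tools
# (SIFT, Polyphen2_HDIV, LRT, MutationTaster) call it pathogenic. The
# two CADD rules partition scores >= 10 with no gap or overlap at 25.
# Classes 1-2 are never pathogenic regardless of annotations.

#' Classify variants as pathogenic
#'
#' Adds logical `pathogenic` and character `pathogenic_reason` columns.
#' Reason codes: `class45`, `cadd_high`, `cadd_mid_votes`,
#' `benign_class`, `class3_insufficient`, `missing_evidence` (class 3
#' with no CADD score; logged).
#'
#' @param variants variant `data.frame` with `pathogenicity_class`,
#'   `cadd_phred`, and the four predictor columns
#' @param thresholds an `lbcl_thresholds` object
#' @param quiet suppress the missing-evidence log message
#' @return the annotated `data.frame`
#' @export
#' @examples
#' v <- data.frame(pathogenicity_class = c(5, 3, 3),
#'                 cadd_phred = c(NA, 26, 15),
#'                 sift = c(NA, NA, "pathogenic"),
#'                 polyphen2_hdiv = c(NA, NA, "pathogenic"),
#'                 lrt = NA_character_, mutationtaster = NA_character_)
#' classify_pathogenic(v)$pathogenic
classify_pathogenic <- function(variants, thresholds = default_thresholds(),
                                quiet = FALSE) {
  n <- nrow(variants)
  if (n == 0) {
    variants$pathogenic <- logical(0)
    variants$pathogenic_reason <- character(0)
    return(variants)
  }
  cls <- variants$pathogenicity_class
  cadd <- variants$cadd_phred
  vote_mat <- vapply(.predictor_cols, function(col) {
    x <- variants[[col]] %||% rep(NA_character_, n)
    !is.na(x) & x == "pathogenic"
  }, logical(n))
  votes <- rowSums(matrix(vote_mat, nrow = n))
  pathogenic <- rep(FALSE, n)
  reason <- rep("class3_insufficient", n)

  high_class <- !is.na(cls) & cls >= 4
  pathogenic[high_class] <- TRUE
  reason[high_class] <- "class45"

  low_class <- !is.na(cls) & cls <= 2
  reason[low_class] <- "benign_class"

  c3 <- !is.na(cls) & cls == 3
  missing_cadd <- c3 & is.na(cadd)
  reason[missing_cadd] <- "missing_evidence"
  if (!quiet && any(missing_cadd))
    msg(sum(missing_cadd), " class-3 variant(s) lack a CADD score; ",
        "treated as not pathogenic (missing_evidence)")

  cadd_high <- c3 & !is.na(cadd) & cadd > thresholds$cadd_high
  pathogenic[cadd_high] <- TRUE
  reason[cadd_high] <- "cadd_high"

  cadd_mid <- c3 & !is.na(cadd) &
    cadd >= thresholds$cadd_low & cadd <= thresholds$cadd_high &
    votes >= thresholds$min_pathogenic_notations
  pathogenic[cadd_mid] <- TRUE
  reason[cadd_mid] <- "cadd_mid_votes"

  variants$pathogenic <- pathogenic
  variants$pathogenic_reason <- reason
  variants
}

#' Per-patient pathogenic gene sets
#'
#' Retains only pathogenic records and deduplicates genes within each
#' patient, so a gene counts once per patient in burden and frequency
#' summaries however many pathogenic variants it carries.
#'
#' @param variants output of [classify_pathogenic()] on a filtered table
#' @return `data.frame` with unique (sample_id, gene) pairs
#' @export
pathogenic_set <- function(variants) {
  if (!"pathogenic" %in% names(variants))
    stop("run classify_pathogenic() first")
  hits <- variants[variants$pathogenic, c("sample_id", "gene"), drop = FALSE]
  out <- unique(hits)
  rownames(out) <- NULL
  out
}
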