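#' Default analysis thresholds
#'
#' Returns the full set of tunable thresholds used across the pipeline,
#' at their standard values: variant calling requires coverage of at
#' least 100 reads and a variant allele frequency of at least 10%;
#' variants with a population frequency above 1%, a strand bias above
#' 90%, or an indel in a homopolymer run are excluded; samples are
#' excluded when the transition/transversion ratio reaches 5 (a
#' formalin-fixation deamination signature) or the mean read count falls
#' below 100; class-3 variants are upgraded to pathogenic at CADD-PHRED
#' above 25, or between 10 and 25 with at least 2 supporting predictor
#' calls; copy-number gains and losses require more than two consecutive
#' amplicons outside the 99% confidence interval (95% for CDKN2A); the
#' Hans cell-of-origin cutoff is 30% positive tumor cells and the
#' double-expressor cutoffs are MYC 40% / BCL2 50%; LymphGen membership
#' requires subtype probability above 50% (core above 90%); survival is
#' administratively censored at 60 months; oncoprints display genes
#' altered in more than 5% of patients.
#'
#' @return an object of class `lbcl_thresholds` (a named list)
#' @seealso [load_thresholds()]
#' @export
#' @examples
#' th <- default_thresholds()
#' th$min_read_depth
default_thresholds <- function() {
  structure(list(
    min_read_depth           = 100,
    min_vaf                  = 0.10,
    max_population_freq      = 0.01,
    max_strand_bias          = 0.90,
    titv_exclusion           = 5.0,
    min_sample_mean_reads    = 100,
    cadd_high                = 25,
    cadd_low                 = 10,
    min_pathogenic_notations = 2,
    ci_level_default         = 0.99,
    ci_level_overrides       = list(CDKN2A = 0.95),
    min_consecutive_amplicons = 3,
    homopolymer_min_run      = 5,
    cov_qc_min_median        = 50,
    cov_qc_max_iqr           = 1.2,
    hans_cutoff              = 0.30,
    myc_expr_cutoff          = 0.40,
    bcl2_expr_cutoff         = 0.50,
    lymphgen_member_prob     = 0.50,
    lymphgen_core_prob       = 0.90,
    admin_censor_months      = 60,
    oncoprint_min_freq       = 0.05
  ), class = "lbcl_thresholds")
}

# keys that must lie in [0, 1]
.fraction_keys <- c(
  "min_vaf", "max_population_freq", "max_strand_bias", "ci_level_default",
  "hans_cutoff", "myc_expr_cutoff", "bcl2_expr_cutoff",
  "lymphgen_member_prob", "lymphgen_core_prob", "oncoprint_min_freq",
  "cov_qc_max_iqr"
)

#' Validate a thresholds object
#'
#' Checks the invariants every thresholds object must satisfy: fractions
#' in \[0,1\], `cadd_low < cadd_high`, at least one consecutive amplicon
#' required for a CNV call, and (when a panel is supplied) every
#' confidence-interval override gene present on the panel.
#'
#' @param th an `lbcl_thresholds` object
#' @param panel_genes optional character vector of panel gene symbols
#' @return `th`, invisibly; errors on violation
#' @export
validate_thresholds <- function(th, panel_genes = NULL) {
  for (key in .fraction_keys) {
    v <- th[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("configuration error: '", key, "' must be a single number")
    if (key != "cov_qc_max_iqr" && (v < 0 || v > 1))
      stop("configuration error: '", key, "' must lie in [0, 1], got ", v)
  }
  num_keys <- c("min_read_depth", "titv_exclusion", "min_sample_mean_reads",
                "cadd_high", "cadd_low", "min_pathogenic_notations",
                "min_consecutive_amplicons", "homopolymer_min_run",
                "cov_qc_min_median", "admin_censor_months")
  for (key in num_keys) {
    v <- th[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("configuration error: '", key, "' must be a single non-negative number")
  }
  if (th$cadd_low >= th$cadd_high)
    stop("configuration error: 'cadd_low' must be smaller than 'cadd_high'")
  if (th$min_consecutive_amplicons < 1)
    stop("configuration error: 'min_consecutive_amplicons' must be >= 1")
  ov <- th$ci_level_overrides
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("configuration error: 'ci_level_overrides' must be a named gene -> level map")
    lv <- unlist(ov)
    if (!is.numeric(lv) || any(lv <= 0 | lv >= 1))
      stop("configuration error: 'ci_level_overrides' levels must lie in (0, 1)")
    if (!is.null(panel_genes)) {
      missing <- setdiff(names(ov), panel_genes)
      if (length(missing))
        stop("configuration error: ci_level_overrides gene(s) not on panel: ",
             paste(missing, collapse = ", "))
    }
  }
  invisible(th)
}

#' Load thresholds from a YAML config file
#'
#' Reads a flat key/value YAML file and merges it over the defaults.
#' Absent keys take their default values; unknown keys are rejected so a
#' typo cannot silently leave a threshold at its default. The fully
#' resolved configuration is echoed to the message log.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults
#' @param overrides named list applied on top of the file (convenience
#'   for programmatic use)
#' @param quiet suppress the configuration echo
#' @return a validated `lbcl_thresholds` object
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("min_vaf: 0.05", f)
#' th <- load_thresholds(f, quiet = TRUE)
#' th$min_vaf
load_thresholds <- function(path = NULL, overrides = list(), quiet = FALSE) {
  th <- default_thresholds()
  user <- list()
  if (!is.null(path)) {
    user <- tryCatch(yaml::read_yaml(path),
                     error = function(e) stop("configuration error: cannot parse '",
                                              path, "': ", conditionMessage(e)))
    if (is.null(user)) user <- list()
  }
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(th))
  if (length(unknown))
    stop("configuration error: unknown key(s): ", paste(unknown, collapse = ", "))
  for (key in names(user)) {
    v <- user[[key]]
    if (key == "ci_level_overrides") {
      if (!is.list(v) && is.null(names(v)))
        stop("configuration error: 'ci_level_overrides' must be a gene -> level map")
      th[[key]] <- as.list(v)
    } else {
      if (!is.numeric(v) || length(v) != 1L)
        stop("configuration error: value for '", key, "' must be a single number")
      th[[key]] <- v
    }
  }
  validate_thresholds(th)
  if (!quiet) {
    msg("resolved configuration:")
    for (key in names(th)) {
      v <- th[[key]]
      msg("  ", key, " = ",
          if (is.list(v)) paste(names(v), unlist(v), sep = "=", collapse = ", ")
          else format(v))
    }
  }
  th
}

#' @export
print.lbcl_thresholds <- function(x, ...) {
  cat("Analysis thresholds (lbclpanel)\n")
  for (key in names(x)) {
    v <- x[[key]]
    cat(sprintf("  %-26s %s\n", key,
                if (is.list(v)) paste(names(v), unlist(v), sep = "=", collapse = ", ")
                else format(v)))
  }
  invisible(x)
}
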