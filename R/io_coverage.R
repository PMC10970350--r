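# Amplicon coverage matrix container (one sequencing run): samples x
# amplicons median base coverage plus the panel manifest, with slots
# filled in by coverage QC and normalization.

#' Construct an amplicon coverage matrix
#'
#' @param raw numeric matrix, rows = samples (rownames = sample IDs),
#'   columns = amplicon IDs; values are median base coverage
#' @param manifest panel manifest (see [build_manifest()]); columns of
#'   `raw` must be a subset of its amplicon IDs and are realigned to
#'   manifest (genomic) order
#' @param run_id identifier of the sequencing run
#' @return an object of class `amplicon_coverage`
#' @export
coverage_matrix <- function(raw, manifest, run_id = "run1") {
  validate_manifest(manifest)
  if (is.null(rownames(raw))) stop("coverage matrix must have sample IDs as rownames")
  if (anyDuplicated(rownames(raw)))
    stop("duplicate sample ID in coverage matrix: ",
         rownames(raw)[duplicated(rownames(raw))][1])
  unknown <- setdiff(colnames(raw), manifest$amplicon_id)
  if (length(unknown))
    stop("coverage column(s) not in manifest: ", paste(utils::head(unknown, 5), collapse = ", "))
  if (any(raw < 0, na.rm = TRUE)) stop("coverage values must be non-negative")
  missing_amps <- setdiff(manifest$amplicon_id, colnames(raw))
  # align to manifest order; absent amplicons become NA (flagged) columns
  full <- matrix(NA_real_, nrow(raw), nrow(manifest),
                 dimnames = list(rownames(raw), manifest$amplicon_id))
  full[, colnames(raw)] <- raw
  structure(list(
    run_id = run_id,
    manifest = manifest,
    raw = full,
    normalized = NULL,
    log2_normalized = NULL,
    qc_excluded = character(0),
    masked_amplicons = missing_amps
  ), class = "amplicon_coverage")
}

#' @export
print.amplicon_coverage <- function(x, ...) {
  cat("Amplicon coverage matrix (run ", x$run_id, ")\n", sep = "")
  cat("  ", nrow(x$raw), " samples x ", ncol(x$raw), " amplicons, ",
      length(unique(x$manifest$gene)), " genes\n", sep = "")
  if (length(x$qc_excluded))
    cat("  QC-excluded samples:", paste(x$qc_excluded, collapse = ", "), "\n")
  if (length(x$masked_amplicons))
    cat("  masked amplicons:", length(x$masked_amplicons), "\n")
  cat("  normalized:", if (is.null(x$normalized)) "no" else "yes", "\n")
  invisible(x)
}

#' Read a sample x amplicon coverage matrix from TSV
#'
#' Rows are samples (first column `sample_id`), remaining columns are
#' amplicon IDs. Columns must be a subset of the manifest; they are
#' reordered to genomic order and any manifest amplicon absent from the
#' file is flagged as masked.
#'
#' @param path TSV path
#' @param manifest panel manifest
#' @param run_id run identifier
#' @return an `amplicon_coverage` object
#' @export
read_coverage_matrix <- function(path, manifest, run_id = "run1") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "sample_id")
    stop("coverage TSV must have 'sample_id' as its first column")
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample ID in coverage matrix: ",
         tab$sample_id[duplicated(tab$sample_id)][1])
  raw <- as.matrix(tab[, -1, drop = FALSE])
  mode(raw) <- "numeric"
  rownames(raw) <- tab$sample_id
  coverage_matrix(raw, manifest, run_id = run_id)
}

#' Write a coverage matrix as TSV
#'
#' @param cov an `amplicon_coverage` object (raw values are written)
#' @param path output path
#' @param what `"raw"` or `"normalized"`
#' @return `path`, invisibly
#' @export
write_coverage_matrix <- function(cov, path, what = c("raw", "normalized")) {
  what <- match.arg(what)
  m <- if (what == "raw") cov$raw else cov$normalized
  if (is.null(m)) stop("coverage matrix has no '", what, "' values")
  keep <- colnames(m)[colSums(is.na(m)) < nrow(m)]  # drop fully-masked columns
  tab <- data.frame(sample_id = rownames(m), m[, keep, drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
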