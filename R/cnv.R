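# Gene-level copy-number calling from normalized amplicon coverage.
#
# Pipeline: coverage_sample_qc -> normalize_coverage ->
# amplicon_intervals -> call_cnvs. Intervals and exceedance tests work
# on the log2 of double-median-normalized coverage; a call requires a
# run of at least `min_consecutive_amplicons` consecutive amplicons
# (genomic order, never crossing a gene boundary; masked amplicons
# break runs) all above the upper or all below the lower bound.

#' Coverage-based sample QC for one sequencing run
#'
#' Excludes samples with low quality (median raw coverage below
#' `cov_qc_min_median`) or high variability (IQR of log2
#' sample-median-normalized coverage across amplicons above
#' `cov_qc_max_iqr`). Both parameters are logged.
#'
#' @param cov an `amplicon_coverage` object
#' @param thresholds an `lbcl_thresholds` object
#' @param quiet suppress logging
#' @return `cov` with its `qc_excluded` slot filled
#' @export
coverage_sample_qc <- function(cov, thresholds = default_thresholds(),
                               quiet = FALSE) {
  stopifnot(inherits(cov, "amplicon_coverage"))
  med <- apply(cov$raw, 1, stats::median, na.rm = TRUE)
  disp <- apply(cov$raw, 1, function(x) {
    x <- x[!is.na(x) & x > 0]
    if (!length(x)) return(Inf)
    stats::IQR(log2(x / stats::median(x)))
  })
  excluded <- rownames(cov$raw)[med < thresholds$cov_qc_min_median |
                                  disp > thresholds$cov_qc_max_iqr]
  if (length(excluded) == nrow(cov$raw))
    stop("coverage QC excluded every sample in run ", cov$run_id,
         "; cannot normalize")
  if (!quiet)
    msg("coverage QC (median floor ", thresholds$cov_qc_min_median,
        ", log2-IQR ceiling ", thresholds$cov_qc_max_iqr, "): excluded ",
        length(excluded), " of ", nrow(cov$raw), " sample(s)")
  cov$qc_excluded <- excluded
  cov
}

cov_included <- function(cov) setdiff(rownames(cov$raw), cov$qc_excluded)

#' Normalize an amplicon coverage matrix
#'
#' Two median steps on the log2 scale: each sample row is divided by its
#' median across amplicons (removing per-sample sequencing depth), then
#' each amplicon column by its cross-sample median (removing amplicon
#' efficiency). The result is centered near 1 for diploid cells.
#' Amplicons whose cross-sample median raw coverage is zero are masked
#' and reported; isolated zero cells become missing values (they break
#' CNV runs). Requires at least 3 non-excluded samples, otherwise
#' interval estimation downstream is meaningless.
#'
#' @param cov an `amplicon_coverage` object (after
#'   [coverage_sample_qc()], or raw)
#' @param quiet suppress the masked-amplicon report
#' @return `cov` with `normalized` and `log2_normalized` slots filled
#' @export
normalize_coverage <- function(cov, quiet = FALSE) {
  stopifnot(inherits(cov, "amplicon_coverage"))
  keep <- cov_included(cov)
  if (length(keep) < 3)
    stop("normalization requires >= 3 non-excluded samples, have ",
         length(keep))
  raw <- cov$raw[keep, , drop = FALSE]
  raw[raw == 0] <- NA_real_
  zero_med <- colnames(raw)[apply(raw, 2, function(x) all(is.na(x)) ||
                                    stats::median(x, na.rm = TRUE) == 0)]
  masked <- union(cov$masked_amplicons, zero_med)
  l <- log2(raw)
  l <- l - apply(l, 1, stats::median, na.rm = TRUE)           # sample depth
  l <- sweep(l, 2, apply(l, 2, stats::median, na.rm = TRUE))  # amplicon efficiency
  l[, colnames(l) %in% masked] <- NA_real_
  full <- matrix(NA_real_, nrow(cov$raw), ncol(cov$raw), dimnames = dimnames(cov$raw))
  full[keep, ] <- l
  cov$log2_normalized <- full
  cov$normalized <- 2^full
  cov$masked_amplicons <- masked
  if (!quiet && length(masked))
    msg("masked ", length(masked), " amplicon(s) with zero/absent coverage")
  cov
}

#' Per-amplicon reference intervals
#'
#' For each amplicon, an interval on the log2 normalized scale from the
#' cross-sample distribution: mean +/- z(level) * SD under the default
#' normal-theory method, or symmetric quantiles under the percentile
#' alternative. The level is the gene's configured override when present
#' (e.g. 95% for CDKN2A, whose frequent deletion would otherwise widen
#' its own reference interval), else the default 99%. A zero-SD column
#' with more than one sample yields a degenerate width-0 interval and is
#' logged.
#'
#' @param cov a normalized `amplicon_coverage` object
#' @param thresholds an `lbcl_thresholds` object
#' @param method `"normal"` (default) or `"percentile"`
#' @param quiet suppress degenerate-interval logging
#' @return `data.frame`: amplicon_id, gene, ci_level, lower, upper
#'   (log2 scale)
#' @export
amplicon_intervals <- function(cov, thresholds = default_thresholds(),
                               method = c("normal", "percentile"),
                               quiet = FALSE) {
  method <- match.arg(method)
  if (is.null(cov$log2_normalized)) stop("normalize_coverage() first")
  keep <- cov_included(cov)
  l <- cov$log2_normalized[keep, , drop = FALSE]
  manifest <- cov$manifest
  level <- vapply(manifest$gene, function(g) {
    ov <- thresholds$ci_level_overrides[[g]]
    if (is.null(ov)) thresholds$ci_level_default else as.numeric(ov)
  }, numeric(1))
  if (method == "normal") {
    mu <- colMeans(l, na.rm = TRUE)
    sd <- apply(l, 2, stats::sd, na.rm = TRUE)
    z <- stats::qnorm(1 - (1 - level) / 2)
    lower <- mu - z * sd
    upper <- mu + z * sd
    degenerate <- !is.na(sd) & sd == 0 & colSums(!is.na(l)) > 1
    if (!quiet && any(degenerate))
      msg(sum(degenerate), " amplicon(s) have zero cross-sample SD; ",
          "their reference interval collapses to a point")
  } else {
    qs <- vapply(seq_len(ncol(l)), function(j) {
      a <- (1 - level[j]) / 2
      stats::quantile(l[, j], c(a, 1 - a), na.rm = TRUE, names = FALSE, type = 7)
    }, numeric(2))
    lower <- qs[1, ]; upper <- qs[2, ]
  }
  data.frame(amplicon_id = manifest$amplicon_id, gene = manifest$gene,
             ci_level = unname(level), lower = unname(lower),
             upper = unname(upper), stringsAsFactors = FALSE)
}

# maximal runs of a constant value in an integer/NA status vector,
# restricted to value != 0; returns data.frame(start, end, value)
find_runs <- function(status) {
  n <- length(status)
  if (!n) return(data.frame(start = integer(0), end = integer(0), value = integer(0)))
  key <- ifelse(is.na(status), -99L, status)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values %in% c(-1L, 1L)
  data.frame(start = starts[sel], end = ends[sel], value = r$values[sel])
}

#' Call copy-number gains and losses
#'
#' Per sample, amplicons are scanned in manifest (genomic) order within
#' each gene; maximal runs of consecutive amplicons strictly above the
#' upper bound (gain) or strictly below the lower bound (loss) are
#' emitted when the run length reaches `min_consecutive_amplicons`
#' ("more than two consecutive amplicons" at the default of 3). Runs
#' never cross gene boundaries; missing/masked amplicons break runs;
#' one gene may yield several calls.
#'
#' By default (`intervals = NULL`) each sample is tested against
#' leave-one-out reference intervals: normal-theory bounds recomputed
#' from the other samples via closed-form mean/SD updates. This
#' prevents a true event from widening its own reference interval and
#' masking itself, which measurably costs sensitivity for modest gains
#' at typical run sizes. Passing an explicit [amplicon_intervals()]
#' table instead tests every sample against those cohort-wide bounds.
#'
#' @param cov a normalized `amplicon_coverage` object
#' @param intervals optional output of [amplicon_intervals()]; when
#'   `NULL`, leave-one-out intervals are used
#' @param thresholds an `lbcl_thresholds` object
#' @return `data.frame`: sample_id, gene, direction, run_start, run_end
#'   (global amplicon indices in the manifest), run_length, ci_level,
#'   mean_log2
#' @export
call_cnvs <- function(cov, intervals = NULL,
                      thresholds = default_thresholds()) {
  if (is.null(cov$log2_normalized)) stop("normalize_coverage() first")
  manifest <- cov$manifest
  keep <- cov_included(cov)
  l <- cov$log2_normalized[keep, , drop = FALSE]
  gene_blocks <- split(seq_len(nrow(manifest)), manifest$gene)
  min_run <- thresholds$min_consecutive_amplicons

  level <- vapply(manifest$gene, function(g) {
    ov <- thresholds$ci_level_overrides[[g]]
    if (is.null(ov)) thresholds$ci_level_default else as.numeric(ov)
  }, numeric(1))
  loo <- is.null(intervals)
  if (loo) {
    # closed-form leave-one-out mean/SD per (sample, amplicon)
    nvec <- colSums(!is.na(l))
    mu <- colMeans(l, na.rm = TRUE)
    ss <- colSums(sweep(l, 2, mu)^2, na.rm = TRUE)
    dev <- sweep(l, 2, mu)
    mu_loo <- sweep(-l, 2, nvec * mu, `+`)
    mu_loo <- sweep(mu_loo, 2, nvec - 1, `/`)
    ss_loo <- sweep(-dev^2 * rep(nvec / (nvec - 1), each = nrow(l)), 2, ss, `+`)
    sd_loo <- sqrt(pmax(ss_loo, 0) / rep(pmax(nvec - 2, 1), each = nrow(l)))
    z <- stats::qnorm(1 - (1 - level) / 2)
    lower_m <- mu_loo - sweep(sd_loo, 2, z, `*`)
    upper_m <- mu_loo + sweep(sd_loo, 2, z, `*`)
  } else {
    stopifnot(identical(intervals$amplicon_id, manifest$amplicon_id))
    level <- intervals$ci_level
  }

  calls <- list()
  for (sid in keep) {
    x <- l[sid, ]
    if (loo) {
      lo <- lower_m[sid, ]; up <- upper_m[sid, ]
    } else {
      lo <- intervals$lower; up <- intervals$upper
    }
    status <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & !is.na(lo) & !is.na(up)
    status[ok] <- 0L
    status[ok & x > up] <- 1L
    status[ok & x < lo] <- -1L
    for (g in names(gene_blocks)) {
      idx <- gene_blocks[[g]]
      runs <- find_runs(status[idx])
      runs <- runs[runs$end - runs$start + 1L >= min_run, , drop = FALSE]
      if (!nrow(runs)) next
      for (k in seq_len(nrow(runs))) {
        gi <- idx[runs$start[k]:runs$end[k]]
        calls[[length(calls) + 1L]] <- data.frame(
          sample_id = sid, gene = g,
          direction = if (runs$value[k] == 1L) "gain" else "loss",
          run_start = gi[1], run_end = gi[length(gi)],
          run_length = length(gi),
          ci_level = unname(level[gi[1]]),
          mean_log2 = mean(x[gi]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample_id = character(0), gene = character(0),
               direction = character(0), run_start = integer(0),
               run_end = integer(0), run_length = integer(0),
               ci_level = numeric(0), mean_log2 = numeric(0))
  rownames(out) <- NULL
  out
}

#' Gene-level CNV summary per sample
#'
#' Collapses runs to one row per (sample, gene): direction is the run
#' direction, or `"ambiguous"` (flagged) when a gene shows both gain and
#' loss runs in the same sample.
#'
#' @param calls output of [call_cnvs()]
#' @return `data.frame`: sample_id, gene, direction, n_runs, ambiguous
#' @export
cnv_gene_summary <- function(calls) {
  if (!nrow(calls))
    return(data.frame(sample_id = character(0), gene = character(0),
                      direction = character(0), n_runs = integer(0),
                      ambiguous = logical(0)))
  key <- paste(calls$sample_id, calls$gene, sep = "\r")
  out <- lapply(split(seq_len(nrow(calls)), key), function(i) {
    dirs <- unique(calls$direction[i])
    data.frame(sample_id = calls$sample_id[i[1]], gene = calls$gene[i[1]],
               direction = if (length(dirs) > 1) "ambiguous" else dirs,
               n_runs = length(i), ambiguous = length(dirs) > 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
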