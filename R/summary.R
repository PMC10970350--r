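# Patient x gene alteration matrix and descriptive cohort outputs
# (gene frequencies, per-patient burden, oncoprint export).

#' Build the patient x gene alteration matrix
#'
#' Unions the evidence per (patient, gene): pathogenic variants from
#' [pathogenic_set()], gains/losses from [cnv_gene_summary()] (an
#' ambiguous gene contributes both). Patients with zero alterations are
#' retained as empty columns. Side annotations (disease category,
#' cell-of-origin, LymphGen label, rearrangements, outcome flags) are
#' carried alongside for oncoprint grouping.
#'
#' @param pathogenic_sets `data.frame` (sample_id, gene)
#' @param cnv_calls output of [call_cnvs()] or [cnv_gene_summary()]
#' @param patients phenotype table with `patient_id` (and optional
#'   annotation columns)
#' @param genes panel gene universe; unknown gene symbols in the inputs
#'   are an error
#' @return an `alteration_matrix` object: list with `patients`, `genes`,
#'   `cells` (patients x genes character matrix, `";"`-joined alteration
#'   types among pathogenic_variant / gain / loss), `annotations`
#' @export
build_alteration_matrix <- function(pathogenic_sets, cnv_calls, patients, genes) {
  ids <- patients$patient_id
  cells <- matrix("", nrow = length(ids), ncol = length(genes),
                  dimnames = list(ids, genes))
  add <- function(pid, gene, type) {
    bad <- setdiff(unique(gene), genes)
    if (length(bad))
      stop("unknown gene symbol(s): ", paste(bad, collapse = ", "))
    keep <- pid %in% ids
    pid <- pid[keep]; gene <- gene[keep]; type <- rep_len(type, length(keep))[keep]
    for (i in seq_along(pid)) {
      cur <- cells[pid[i], gene[i]]
      parts <- union(if (nzchar(cur)) strsplit(cur, ";")[[1]] else character(0),
                     type[i])
      cells[pid[i], gene[i]] <<- paste(parts, collapse = ";")
    }
  }
  if (nrow(pathogenic_sets))
    add(pathogenic_sets$sample_id, pathogenic_sets$gene, "pathogenic_variant")
  if (nrow(cnv_calls)) {
    cn <- cnv_calls
    if ("ambiguous" %in% names(cn)) {
      amb <- cn[cn$direction == "ambiguous", , drop = FALSE]
      cn <- cn[cn$direction != "ambiguous", , drop = FALSE]
      if (nrow(amb)) {
        add(amb$sample_id, amb$gene, "gain")
        add(amb$sample_id, amb$gene, "loss")
      }
    }
    if (nrow(cn)) add(cn$sample_id, cn$gene, cn$direction)
  }
  ann_cols <- intersect(c("disease_category", "ann_arbor", "coo",
                          "double_expressor", "lymphgen_label",
                          "myc_rearr", "bcl2_rearr", "bcl6_rearr",
                          "os_event", "pfs_event", "death_cause"),
                        names(patients))
  structure(list(patients = ids, genes = genes, cells = cells,
                 annotations = patients[, c("patient_id", ann_cols), drop = FALSE]),
            class = "alteration_matrix")
}

#' @export
print.alteration_matrix <- function(x, ...) {
  altered <- sum(nzchar(x$cells))
  cat("Alteration matrix: ", length(x$patients), " patients x ",
      length(x$genes), " genes; ", altered, " altered cells\n", sep = "")
  invisible(x)
}

#' Per-gene alteration frequencies
#'
#' Counts patients with any alteration of each gene within the given
#' patient group; percent is count / n rounded half away from zero to
#' the nearest integer (so 4 of 14 prints as 29%).
#'
#' @param am an `alteration_matrix`
#' @param group optional character vector of patient IDs (default: all)
#' @return `data.frame`: gene, count, n, percent, sorted by descending
#'   count
#' @export
gene_frequencies <- function(am, group = NULL) {
  ids <- group %||% am$patients
  ids <- intersect(am$patients, ids)
  if (!length(ids)) stop("gene_frequencies: empty patient group")
  sub <- am$cells[ids, , drop = FALSE]
  hit <- nzchar(sub)
  dim(hit) <- dim(sub)
  count <- colSums(hit)
  out <- data.frame(gene = am$genes, count = as.integer(count),
                    n = length(ids),
                    percent = as.integer(round_half_up(100 * count / length(ids))),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Per-patient alteration burden
#'
#' Counts distinct altered genes per patient, either restricted to
#' pathogenic variants or including CNVs, and summarizes with the median
#' and interquartile range using linear interpolation between order
#' statistics (quantile type 7, which is how fractional quartiles such
#' as 8.25 arise).
#'
#' @param am an `alteration_matrix`
#' @param mode `"variants_and_cnvs"` or `"variants_only"`
#' @return list: `counts` (named per patient), `median`, `q1`, `q3`
#' @export
per_patient_burden <- function(am, mode = c("variants_and_cnvs", "variants_only")) {
  mode <- match.arg(mode)
  if (!length(am$patients)) stop("per_patient_burden: no patients")
  hit <- if (mode == "variants_only") {
    grepl("pathogenic_variant", am$cells, fixed = TRUE)
  } else {
    nzchar(am$cells)
  }
  dim(hit) <- dim(am$cells)
  counts <- rowSums(hit)
  names(counts) <- am$patients
  qs <- stats::quantile(counts, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(counts = counts, median = qs[2], q1 = qs[1], q3 = qs[3])
}

#' Oncoprint export
#'
#' Retains genes whose overall alteration frequency strictly exceeds
#' `oncoprint_min_freq` (default 5%), orders rows by descending
#' frequency and columns by disease category, and encodes multi-type
#' cells with their `";"`-joined type string. The TSV-able table is the
#' contract; [plot_oncoprint()] renders a best-effort figure.
#'
#' @param am an `alteration_matrix`
#' @param thresholds an `lbcl_thresholds` object
#' @return list: `table` (genes x patients `data.frame` with a leading
#'   `gene` column), `genes` (retained, ordered), `patients` (ordered),
#'   `frequencies`
#' @export
oncoprint_export <- function(am, thresholds = default_thresholds()) {
  freq <- gene_frequencies(am)
  keep <- freq[freq$count / freq$n > thresholds$oncoprint_min_freq, , drop = FALSE]
  if (!nrow(keep))
    warning("no gene exceeds the oncoprint frequency threshold; empty output")
  ord_pat <- am$patients
  ann <- am$annotations
  if ("disease_category" %in% names(ann)) {
    cat_order <- c("primary", "disseminated", "unstaged", "relapsed")
    r <- match(ann$disease_category, cat_order)
    ord_pat <- ann$patient_id[order(r, ann$patient_id)]
  }
  tab <- as.data.frame(am$cells[ord_pat, keep$gene, drop = FALSE],
                       stringsAsFactors = FALSE)
  tab <- cbind(gene = keep$gene,
               as.data.frame(t(tab), stringsAsFactors = FALSE))
  rownames(tab) <- NULL
  list(table = tab, genes = keep$gene, patients = ord_pat, frequencies = keep)
}

#' Render an oncoprint figure (best effort)
#'
#' Simple base-graphics glyph rendering of an [oncoprint_export()]
#' result: one row per gene, one column per patient; boxes for
#' pathogenic variants, up/down triangles overlaid for gains/losses.
#'
#' @param onco result of [oncoprint_export()]
#' @param am the source `alteration_matrix`
#' @param main plot title
#' @return invisibly, `NULL`
#' @export
plot_oncoprint <- function(onco, am, main = "Oncoprint") {
  genes <- onco$genes; pats <- onco$patients
  if (!length(genes)) return(invisible(NULL))
  op <- graphics::par(mar = c(6, 6, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = c(0, length(pats)) + 0.5,
                 ylim = c(0, length(genes)) + 0.5,
                 xlab = "", ylab = "", axes = FALSE, main = main)
  for (gi in seq_along(genes)) {
    y <- length(genes) - gi + 1
    for (pi in seq_along(pats)) {
      cell <- am$cells[pats[pi], genes[gi]]
      graphics::rect(pi - 0.45, y - 0.45, pi + 0.45, y + 0.45,
                     col = "grey92", border = NA)
      if (!nzchar(cell)) next
      types <- strsplit(cell, ";")[[1]]
      if ("pathogenic_variant" %in% types)
        graphics::rect(pi - 0.45, y - 0.45, pi + 0.45, y + 0.45,
                       col = "forestgreen", border = NA)
      if ("gain" %in% types)
        graphics::points(pi, y, pch = 24, bg = "firebrick", cex = 0.8)
      if ("loss" %in% types)
        graphics::points(pi, y, pch = 25, bg = "royalblue", cex = 0.8)
    }
  }
  graphics::axis(2, at = rev(seq_along(genes)), labels = genes, las = 2,
                 tick = FALSE, cex.axis = 0.7)
  graphics::axis(1, at = seq_along(pats), labels = pats, las = 2,
                 tick = FALSE, cex.axis = 0.6)
  pct <- onco$frequencies$percent
  graphics::axis(4, at = rev(seq_along(genes)), labels = paste0(pct, "%"),
                 las = 2, tick = FALSE, cex.axis = 0.7)
  invisible(NULL)
}
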