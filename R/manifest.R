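# Amplicon panel manifest: ordered table of amplicons with gene and
# primer-pool assignment. Internal coordinates are 1-based inclusive
# (VCF convention); BED input is converted at the boundary.

# Recurrently altered B-cell lymphoma genes used to name synthetic panels.
.lymphoma_genes <- c(
  "MYD88", "CD79B", "PIM1", "TBL1XR1", "SETD1B", "DUSP2", "KLHL14", "BTG1",
  "BTG2", "HIST1H1E", "TCF3", "ETV6", "IRF4", "CDKN2A", "CREBBP", "SGK1",
  "MYC", "BCL2", "BCL6", "TNFRSF14", "POU2F2", "TP53", "CARD11", "EZH2",
  "KMT2D", "B2M", "CD58", "SOCS1", "STAT3", "TNFAIP3", "PRDM1", "NOTCH1",
  "NOTCH2", "SPEN", "DDX3X", "TET2", "GNA13", "EP300", "ARID1A", "FOXO1",
  "CCND3", "XPO1", "ID3", "MEF2B", "CD70", "NFKBIE", "STAT6", "ZFP36L1",
  "GRHPR", "BCL10"
)

panel_gene_names <- function(n_genes) {
  if (n_genes <= length(.lymphoma_genes)) return(.lymphoma_genes[seq_len(n_genes)])
  c(.lymphoma_genes,
    sprintf("LYMF%03d", seq_len(n_genes - length(.lymphoma_genes))))
}

#' Build a synthetic panel manifest
#'
#' Constructs an amplicon manifest in genomic order: `n_genes` genes laid
#' out across chromosomes, each covered by a contiguous tile of
#' amplicons alternating between two primer pools. Gene symbols are
#' recurrently altered B-cell lymphoma genes (padded with placeholder
#' symbols for large panels) so that per-gene threshold overrides such
#' as the CDKN2A confidence level are exercised.
#'
#' @param n_genes number of genes on the panel
#' @param amplicons_per_gene amplicons tiled over each gene; either a
#'   single count or a vector of length `n_genes`
#' @return a `data.frame` with columns `amplicon_id`, `chrom`, `start`,
#'   `end`, `gene`, `pool` (1-based inclusive coordinates, genomic order)
#' @export
#' @examples
#' m <- build_manifest(4, 6)
#' head(m)
build_manifest <- function(n_genes = 20, amplicons_per_gene = 8) {
  stopifnot(n_genes >= 1)
  apg <- rep_len(amplicons_per_gene, n_genes)
  stopifnot(all(apg >= 1))
  genes <- panel_gene_names(n_genes)
  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    chrom <- paste0("chr", ((g - 1L) %% 22L) + 1L)
    gene_start <- 1e6 * (((g - 1L) %/% 22L) + 1L) + 1
    starts <- gene_start + (seq_len(apg[g]) - 1L) * 120
    rows[[g]] <- data.frame(
      amplicon_id = sprintf("AMP_%s_%03d", genes[g], seq_len(apg[g])),
      chrom = chrom,
      start = starts,
      end = starts + 149,
      gene = genes[g],
      pool = ((seq_len(apg[g]) - 1L) %% 2L) + 1L,
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  manifest <- manifest[order_genomic(manifest$chrom, manifest$start), ]
  rownames(manifest) <- NULL
  validate_manifest(manifest)
}

# genomic sort order: chr1..chr22 then others lexicographic
order_genomic <- function(chrom, start) {
  num <- suppressWarnings(as.integer(sub("^chr", "", chrom)))
  num[is.na(num)] <- 1000L
  order(num, chrom, start)
}

#' Full-scale panel preset
#'
#' A manifest of 128 B-cell-lymphoma-relevant genes covered by 3359
#' amplicons in two primer pools, matching the scale of the diagnostic
#' amplicon panels this pipeline targets. Amplicon counts are spread as
#' evenly as the total allows (26 or 27 per gene).
#'
#' @return a manifest `data.frame` (see [build_manifest()])
#' @export
full_panel_manifest <- function() {
  n_genes <- 128L
  total <- 3359L
  base <- total %/% n_genes
  extra <- total - base * n_genes
  apg <- rep(base, n_genes)
  if (extra > 0) apg[seq_len(extra)] <- base + 1L
  build_manifest(n_genes, apg)
}

#' Validate a panel manifest
#'
#' @param manifest a manifest `data.frame`
#' @return the manifest, invisibly returned visibly for chaining
#' @export
validate_manifest <- function(manifest) {
  req <- c("amplicon_id", "chrom", "start", "end", "gene", "pool")
  missing <- setdiff(req, names(manifest))
  if (length(missing))
    stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(manifest$amplicon_id))
    stop("manifest contains duplicate amplicon IDs")
  if (!all(manifest$pool %in% c(1L, 2L)))
    stop("manifest primer pool must be 1 or 2")
  if (any(manifest$end < manifest$start))
    stop("manifest has amplicons with end < start")
  # each amplicon maps to exactly one gene is structural (one row each);
  # require gene blocks to be contiguous in the ordered manifest
  r <- rle(manifest$gene)
  if (anyDuplicated(r$values))
    stop("manifest gene blocks are not contiguous in genomic order")
  manifest
}

#' Read a BED-like amplicon manifest
#'
#' Columns: chrom, start (0-based half-open BED convention), end,
#' amplicon_id, gene, pool. Coordinates are converted to the package's
#' internal 1-based inclusive convention on read.
#'
#' @param path path to a tab-separated manifest file (no header)
#' @return a validated manifest `data.frame`
#' @export
read_manifest <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end",
                                         "amplicon_id", "gene", "pool"))
  manifest <- data.frame(
    amplicon_id = as.character(bed$amplicon_id),
    chrom = as.character(bed$chrom),
    start = as.numeric(bed$start) + 1,  # BED 0-based -> 1-based
    end = as.numeric(bed$end),          # half-open end == inclusive end
    gene = as.character(bed$gene),
    pool = as.integer(bed$pool),
    stringsAsFactors = FALSE
  )
  manifest <- manifest[order_genomic(manifest$chrom, manifest$start), ]
  rownames(manifest) <- NULL
  validate_manifest(manifest)
}

#' Write a manifest as BED-like text
#'
#' Inverse of [read_manifest()]; coordinates are emitted 0-based
#' half-open.
#'
#' @param manifest a manifest `data.frame`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_manifest <- function(manifest, path) {
  bed <- data.frame(manifest$chrom, manifest$start - 1, manifest$end,
                    manifest$amplicon_id, manifest$gene, manifest$pool)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
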