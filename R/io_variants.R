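# Variant table I/O. The workhorse format is a multi-sample TSV with one
# row per called variant; a single-sample Ion-Torrent-style VCF 4.2
# dialect is supported for interoperability (FORMAT DP/AF, strand counts
# and annotations in INFO).

.variant_required <- c(
  "sample_id", "gene", "chrom", "pos", "ref", "alt", "depth", "vaf",
  "alt_forward", "alt_reverse", "population_freq", "pathogenicity_class",
  "cadd_phred", "sift", "polyphen2_hdiv", "lrt", "mutationtaster"
)
.variant_optional <- c("in_normal_blacklist", "homopolymer_context", "truth",
                       "filter_flags", "filter_pass", "pathogenic", "pathogenic_reason")
.predictor_cols <- c("sift", "polyphen2_hdiv", "lrt", "mutationtaster")

# Coerce types and check row-level invariants; `where` labels error messages.
validate_variants <- function(variants, where = "variant table") {
  missing <- setdiff(.variant_required, names(variants))
  if (length(missing))
    stop(where, ": missing required column(s): ", paste(missing, collapse = ", "))
  num <- c("pos", "depth", "vaf", "alt_forward", "alt_reverse",
           "population_freq", "pathogenicity_class", "cadd_phred")
  for (col in num) variants[[col]] <- suppressWarnings(as.numeric(variants[[col]]))
  for (col in .predictor_cols) variants[[col]] <- as.character(variants[[col]])
  if ("homopolymer_context" %in% names(variants))
    variants$homopolymer_context <- suppressWarnings(as.numeric(variants$homopolymer_context))
  core <- c("pos", "depth", "vaf", "alt_forward", "alt_reverse")
  for (col in core) {
    bad <- which(is.na(variants[[col]]))
    if (length(bad))
      stop(where, ": missing/invalid '", col, "' at row ", bad[1])
  }
  bad <- which(variants$vaf < 0 | variants$vaf > 1)
  if (length(bad))
    stop(where, ": vaf outside [0, 1] at row ", bad[1])
  bad <- which(variants$alt_forward + variants$alt_reverse > variants$depth)
  if (length(bad))
    stop(where, ": alt strand counts exceed depth at row ", bad[1])
  bad <- which(!is.na(variants$pathogenicity_class) &
                 !(variants$pathogenicity_class %in% 1:5))
  if (length(bad))
    stop(where, ": pathogenicity_class outside 1..5 at row ", bad[1])
  variants
}

#' Read a variant call table
#'
#' Reads per-sample variant calls either from the package's TSV dialect
#' (multi-sample, one row per call, documented column names) or from a
#' single-sample VCF 4.2 with per-sample FORMAT fields `DP` and `AF` and
#' strand counts / annotations in INFO (`SAF`, `SAR`, `GENE`, `PF`,
#' `CLASS`, `CADD`, `SIFT`, `PP2HDIV`, `LRT`, `MT`, `HRUN`, `BLK`).
#' Coordinates are 1-based inclusive internally.
#'
#' @param path input file path
#' @param dialect `"tsv"` or `"vcf"`
#' @return a `data.frame` of variant records
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    variants <- utils::read.delim(path, stringsAsFactors = FALSE,
                                  na.strings = c("NA", "."))
    if (nrow(variants) == 0) {
      missing <- setdiff(.variant_required, names(variants))
      if (length(missing))
        stop("variant table: missing required column(s): ",
             paste(missing, collapse = ", "))
      return(variants)
    }
    return(validate_variants(variants, paste0("variant table '", path, "'")))
  }
  read_variant_vcf(path)
}

read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  n <- nrow(fix)
  sample_id <- colnames(vcf@gt)[-1][1]
  if (is.na(sample_id)) stop("VCF has no sample column")
  info_num <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    suppressWarnings(as.numeric(v))
  }
  info_chr <- function(key) vcfR::extract.info(vcf, element = key)
  dp <- suppressWarnings(as.numeric(vcfR::extract.gt(vcf, element = "DP")[, 1]))
  af <- suppressWarnings(as.numeric(vcfR::extract.gt(vcf, element = "AF")[, 1]))
  if (n > 0 && all(is.na(af)))
    stop("VCF '", path, "' lacks the AF (variant allele frequency) FORMAT field")
  decode_pred <- function(x) {
    out <- rep(NA_character_, length(x))
    out[x %in% "P"] <- "pathogenic"
    out[x %in% "B"] <- "benign"
    out
  }
  variants <- data.frame(
    sample_id = rep(sample_id, n),
    gene = info_chr("GENE"),
    chrom = fix$CHROM,
    pos = as.numeric(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    depth = dp,
    vaf = af,
    alt_forward = info_num("SAF"),
    alt_reverse = info_num("SAR"),
    population_freq = info_num("PF"),
    in_normal_blacklist = !is.na(info_chr("BLK")) & info_chr("BLK") == "1",
    homopolymer_context = info_num("HRUN"),
    pathogenicity_class = info_num("CLASS"),
    cadd_phred = info_num("CADD"),
    sift = decode_pred(info_chr("SIFT")),
    polyphen2_hdiv = decode_pred(info_chr("PP2HDIV")),
    lrt = decode_pred(info_chr("LRT")),
    mutationtaster = decode_pred(info_chr("MT")),
    stringsAsFactors = FALSE
  )
  if (n == 0) return(variants)
  validate_variants(variants, paste0("VCF '", path, "'"))
}

#' Write a variant table as TSV
#'
#' @param variants variant `data.frame`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write one sample's variants as a VCF
#'
#' Emits the single-sample VCF dialect read back by
#' [read_variant_table()] with `dialect = "vcf"`.
#'
#' @param variants variant `data.frame` for exactly one sample
#' @param path output path
#' @return `path`, invisibly
#' @export
write_variant_vcf <- function(variants, path) {
  sid <- unique(variants$sample_id)
  if (length(sid) != 1L)
    stop("write_variant_vcf expects exactly one sample, got ", length(sid))
  enc_pred <- function(x) ifelse(is.na(x), ".", ifelse(x == "pathogenic", "P", "B"))
  num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE, scientific = FALSE))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=lbclpanel",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Alt reads forward strand\">",
    "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Alt reads reverse strand\">",
    "##INFO=<ID=PF,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=BLK,Number=1,Type=Integer,Description=\"Present in panel-of-normals blacklist\">",
    "##INFO=<ID=HRUN,Number=1,Type=Integer,Description=\"Flanking homopolymer run length\">",
    "##INFO=<ID=CLASS,Number=1,Type=Integer,Description=\"Pathogenicity class 1-5\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD-PHRED score\">",
    "##INFO=<ID=SIFT,Number=1,Type=Character,Description=\"SIFT call P/B\">",
    "##INFO=<ID=PP2HDIV,Number=1,Type=Character,Description=\"Polyphen2 HDIV call P/B\">",
    "##INFO=<ID=LRT,Number=1,Type=Character,Description=\"LRT call P/B\">",
    "##INFO=<ID=MT,Number=1,Type=Character,Description=\"MutationTaster call P/B\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sid)
  )
  info <- paste0(
    "GENE=", variants$gene,
    ";SAF=", num(variants$alt_forward),
    ";SAR=", num(variants$alt_reverse),
    ";PF=", num(variants$population_freq),
    ";BLK=", as.integer(isTRUE_vec(variants$in_normal_blacklist)),
    ";HRUN=", num(variants$homopolymer_context %||% rep(0, nrow(variants))),
    ";CLASS=", num(variants$pathogenicity_class),
    ";CADD=", num(variants$cadd_phred),
    ";SIFT=", enc_pred(variants$sift),
    ";PP2HDIV=", enc_pred(variants$polyphen2_hdiv),
    ";LRT=", enc_pred(variants$lrt),
    ";MT=", enc_pred(variants$mutationtaster)
  )
  body <- paste(variants$chrom, format(variants$pos, trim = TRUE, scientific = FALSE),
                ".", variants$ref, variants$alt, ".", "PASS", info, "DP:AF",
                paste0(variants$depth, ":", variants$vaf), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & as.logical(x)

#' Read / write a panel-of-normals blacklist
#'
#' The recurrent-technical-call blacklist (built from sequencing of
#' healthy-donor DNA mixtures) is modeled as an explicit site list with
#' columns `chrom`, `pos`, `ref`, `alt`.
#'
#' @param path TSV path
#' @return `data.frame` with the four site columns
#' @export
read_blacklist <- function(path) {
  bl <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  missing <- setdiff(req, names(bl))
  if (length(missing))
    stop("blacklist: missing column(s): ", paste(missing, collapse = ", "))
  bl$pos <- as.numeric(bl$pos)
  bl
}

#' @rdname read_blacklist
#' @param blacklist blacklist `data.frame`
#' @export
write_blacklist <- function(blacklist, path) {
  utils::write.table(blacklist, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
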