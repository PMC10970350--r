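# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Displayed percentages use commercial rounding (0.5 always rounds away
#' from zero), not banker's rounding, so that e.g. 4/14 prints as 29%.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive an independent sub-seed from a master seed for one named stream.
# All randomness in the package flows from one seed through this function,
# so individual components can be regenerated independently.
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  streams <- c(variants = 1, coverage = 2, cohort = 3, panel = 4, misc = 5)
  k <- if (is.character(stream)) unname(streams[stream]) else as.numeric(stream)
  if (is.na(k)) stop("unknown seed stream: ", stream)
  as.integer((abs(seed) * 1009 + k * 99991) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_snv <- function(ref, alt) {
  bases <- c("A", "C", "G", "T")
  nchar(ref) == 1L & nchar(alt) == 1L & ref %in% bases & alt %in% bases & ref != alt
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

msg <- function(...) message("[lbclpanel] ", ...)
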