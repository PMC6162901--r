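DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the convention
#' used when percentages are reported to one decimal), unlike [round()] which
#' rounds half to even.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T/N)
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

substitute_base <- function(base) {
  alts <- setdiff(DNA_BASES, base)
  alts[sample.int(3L, 1L)]
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# intervals are 0-based half-open throughout the package; 1-based only on
# VCF/SAM/BED-adjacent output where the format requires it
overlaps <- function(start1, end1, start2, end2) {
  start1 < end2 & start2 < end1
}

fmt_pct1 <- function(x) sprintf("%.1f%%", round_half_up(100 * x, 1))
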