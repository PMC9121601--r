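#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
NULL

BASES <- c("A", "C", "G", "T")

#' Normalize a chromosome name for comparison
#'
#' Genomic resources mix the `"chr1"` and `"1"` dialects. All interval and
#' variant comparisons in this package strip a leading `"chr"` prefix on both
#' sides, so `"chr1"` and `"1"` refer to the same chromosome.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector without the `"chr"` prefix.
#' @export
#' @examples
#' normalize_chrom(c("chr1", "1", "chrX"))
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

#' Reverse-complement a DNA string
#'
#' `N` is its own complement. Input must be uppercase A/C/G/T/N.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Split a DNA string into a vector of single characters.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# 1-based VCF position -> 0-based genomic coordinate of the SNP base.
# This is the single conversion point between the two coordinate systems
# used by the package (VCF is 1-based, BED is 0-based half-open).
pos_to_zero_based <- function(pos) as.integer(pos) - 1L

assert_prob_vector <- function(p, what = "p") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort(sprintf("%s must be in [0, 1]", what))
  }
  invisible(p)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
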