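# Allele-specific expression: per-SNP exact binomial tests on allelic read
# counts, and the set-level enrichment of ASE among functional SNPs against
# a genome-wide background proportion. Both tests use the exact two-sided
# minimum-likelihood tail: the p-value sums P(X = j) over every outcome j
# whose point probability does not exceed that of the observed count (with
# a 1e-7 relative tolerance on the comparison).

min_likelihood_two_sided <- function(k, n, p0, rel_tol = 1e-7) {
  d <- stats::dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1L] * (1 + rel_tol)])
}

#' Per-SNP allele-specific expression binomial test
#'
#' Tests whether reads are split evenly between the two alleles: exact
#' two-sided binomial test of `count_allele1` out of the total against
#' success probability 0.5 (minimum-likelihood tail, which for p0 = 0.5 is
#' the symmetric two-tail sum). Vectorized over counts.
#'
#' @param count_allele1,count_allele2 Non-negative integer read counts;
#'   each pair must total at least 1.
#' @return Numeric vector of two-sided p-values.
#' @export
#' @examples
#' ase_binomial_test(5, 5)    # 1
#' ase_binomial_test(0, 10)   # 2 * 0.5^10
ase_binomial_test <- function(count_allele1, count_allele2) {
  if (length(count_allele1) != length(count_allele2)) abort("count vectors differ in length")
  if (any(count_allele1 < 0) || any(count_allele2 < 0)) abort("counts must be non-negative")
  tot <- count_allele1 + count_allele2
  if (any(tot < 1)) abort("untestable: both allele counts are zero")
  vapply(seq_along(tot), function(i) {
    min_likelihood_two_sided(as.integer(count_allele1[[i]]), as.integer(tot[[i]]), 0.5)
  }, numeric(1))
}

#' Set-level ASE enrichment test
#'
#' Tests whether the number of functional SNPs showing ASE (`k` of `n`)
#' exceeds what is expected if they behaved like random variants, of which
#' `K` out of `N` genome-wide show ASE: an exact two-sided binomial test of
#' `k` successes in `n` trials against null probability `K / N`
#' (minimum-likelihood tail).
#'
#' @param k Functional SNPs with ASE (0 <= k <= n).
#' @param n Functional SNPs tested.
#' @param K Genome-wide variants showing ASE.
#' @param N Genome-wide variants (`0 < K <= N`).
#' @return An object of class `ase_enrichment` with fields k, n, K, N,
#'   null_prob, estimate (k/n) and p_value.
#' @export
#' @examples
#' ase_enrichment_test(4, 16, 571220, 46526292)
ase_enrichment_test <- function(k, n, K, N) {
  if (K > N) abort("K must not exceed N")
  if (K <= 0 || N <= 0) abort("K and N must be positive")
  if (k < 0 || k > n) abort("k must be in [0, n]")
  p0 <- K / N
  p <- min_likelihood_two_sided(as.integer(k), as.integer(n), p0)
  structure(
    list(k = as.integer(k), n = as.integer(n), K = K, N = N,
         null_prob = p0, estimate = k / n, p_value = p),
    class = "ase_enrichment"
  )
}

#' @export
print.ase_enrichment <- function(x, ...) {
  cat(sprintf(
    "ASE enrichment: %d / %d functional SNPs with ASE vs background %.0f / %.0f (p0 = %.3e)\n  two-sided exact binomial p = %.3g\n",
    x$k, x$n, x$K, x$N, x$null_prob, x$p_value))
  invisible(x)
}

#' @rdname ase_enrichment_test
#' @param x An `ase_enrichment` object.
#' @param ... Unused.
#' @export
tidy.ase_enrichment <- function(x, ...) {
  tibble(k = x$k, n = x$n, K = x$K, N = x$N, null_prob = x$null_prob,
         estimate = x$estimate, p_value = x$p_value)
}

#' @rdname ase_enrichment_test
#' @export
glance.ase_enrichment <- function(x, ...) tidy(x)

#' Test a table of allelic read counts for ASE
#'
#' Applies [ase_binomial_test()] per row and flags significance at `alpha`,
#' optionally after BH-FDR adjustment across all rows.
#'
#' @param counts Tibble with columns snp_id, count_allele1, count_allele2
#'   (and optionally tissue).
#' @param alpha Significance level (default 0.05).
#' @param fdr Adjust across rows with BH before thresholding (default
#'   FALSE: raw p, matching consumption of precomputed ASE calls).
#' @return The input with p_value (and fdr when requested) and significant
#'   columns appended.
#' @export
ase_test_table <- function(counts, alpha = 0.05, fdr = FALSE) {
  need <- c("snp_id", "count_allele1", "count_allele2")
  if (!all(need %in% names(counts))) {
    abort(sprintf("counts table must have columns: %s", paste(need, collapse = ", ")))
  }
  out <- counts |>
    mutate(p_value = ase_binomial_test(.data$count_allele1, .data$count_allele2))
  if (fdr) {
    out |> mutate(fdr = bh_fdr(.data$p_value), significant = .data$fdr < alpha)
  } else {
    out |> mutate(significant = .data$p_value < alpha)
  }
}
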