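# Linkage disequilibrium from phased haplotypes by direct counting.
# r2 is computed from the 2x2 haplotype table; no EM estimation is offered,
# so unphased input is rejected upstream at VCF parsing.

#' Construct a haplotype panel
#'
#' A haplotype panel holds the phased alleles of a reference cohort: one row
#' per haplotype (two per sample, in sample order) and one column per
#' variant, entries coded 0 (reference allele) / 1 (alternate allele).
#'
#' @param haplotypes Integer matrix of 0/1 alleles, `(2 * n_samples) x n_variants`.
#' @param variant_ids Character vector naming the columns.
#' @param sample_ids Character vector naming the samples.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, variant_ids, sample_ids) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) %% 2L != 0L) abort("haplotype row count must be even (two per sample)")
  if (ncol(haplotypes) != length(variant_ids)) abort("variant_ids length must match column count")
  if (nrow(haplotypes) != 2L * length(sample_ids)) abort("sample_ids length must be nrow/2")
  if (any(!haplotypes %in% c(0L, 1L))) abort("haplotype entries must be 0 or 1")
  structure(
    list(haplotypes = haplotypes, variant_ids = as.character(variant_ids),
         sample_ids = as.character(sample_ids)),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel: %d haplotypes (%d samples) x %d variants>\n",
              nrow(x$haplotypes), length(x$sample_ids), length(x$variant_ids)))
  invisible(x)
}

#' Pairwise linkage disequilibrium r-squared from two haplotype vectors
#'
#' Computes allele and joint haplotype frequencies by direct counting and
#' returns the squared correlation `r2 = D^2 / (pA (1-pA) pB (1-pB))` with
#' `D = pAB - pA * pB`. Both sites must be polymorphic in the panel;
#' monomorphic sites leave r2 undefined and raise an error.
#'
#' @param hap_a,hap_b Integer 0/1 vectors of equal length (>= 2), one entry
#'   per haplotype.
#' @return A one-row tibble: p_a, p_b, p_ab, d, r2.
#' @export
#' @examples
#' r_squared(c(0L, 1L, 1L, 0L), c(0L, 1L, 1L, 0L))$r2  # 1
r_squared <- function(hap_a, hap_b) {
  if (length(hap_a) != length(hap_b)) abort("haplotype vectors must have equal length")
  n <- length(hap_a)
  if (n < 2L) abort("need at least two haplotypes")
  if (any(!hap_a %in% c(0L, 1L)) || any(!hap_b %in% c(0L, 1L))) {
    abort("haplotype entries must be 0 or 1")
  }
  p_a <- mean(hap_a)
  p_b <- mean(hap_b)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    abort("undefined r2: monomorphic site in panel")
  }
  p_ab <- mean(hap_a == 1L & hap_b == 1L)
  d <- p_ab - p_a * p_b
  r2 <- d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  tibble(p_a = p_a, p_b = p_b, p_ab = p_ab, d = d, r2 = r2)
}

#' Extract SNPs in LD with index SNPs
#'
#' For each index SNP, returns every panel variant whose r-squared with the
#' index strictly exceeds `r2_min`, plus the index SNP itself (r2 = 1). A
#' variant in LD with several index SNPs is assigned to the index with the
#' highest r2 (ties broken by index input order). Monomorphic panel variants
#' are skipped with a warning; absent index ids are logged and skipped.
#'
#' @param panel A [haplotype_panel()].
#' @param index_ids Character vector of index SNP ids (non-empty).
#' @param r2_min Strict lower r-squared bound, in (0, 1]. Default 0.6.
#' @return Tibble with columns index_id, snp_id, r2, sorted by
#'   (index_id in input order, descending r2, snp_id).
#' @export
ld_partners <- function(panel, index_ids, r2_min = 0.6) {
  if (length(index_ids) == 0L) abort("index SNP list is empty")
  if (!(r2_min > 0 && r2_min <= 1)) abort("r2_min must be in (0, 1]")
  present <- index_ids %in% panel$variant_ids
  if (any(!present)) {
    warn(sprintf("index SNP(s) not in panel, skipped: %s",
                 paste(index_ids[!present], collapse = ", ")))
  }
  index_ids <- index_ids[present]
  if (length(index_ids) == 0L) abort("no index SNPs present in panel")

  freqs <- colMeans(panel$haplotypes)
  poly <- freqs > 0 & freqs < 1
  if (any(!poly)) {
    warn(sprintf("%d monomorphic panel variant(s) skipped", sum(!poly)))
  }

  rows <- purrr::map_dfr(seq_along(index_ids), function(k) {
    idx <- index_ids[[k]]
    j <- match(idx, panel$variant_ids)
    if (!poly[[j]]) {
      warn(sprintf("index SNP %s is monomorphic; r2 undefined, skipped", idx))
      return(tibble())
    }
    hap_i <- panel$haplotypes[, j]
    keep <- which(poly)
    r2 <- vapply(keep, function(m) {
      if (m == j) return(1.0)
      r_squared(hap_i, panel$haplotypes[, m])$r2
    }, numeric(1))
    # strict threshold; perfect LD (r2 == 1) always qualifies, so the
    # boundary r2_min = 1 still retains exact duplicates of the index
    sel <- r2 > r2_min | r2 == 1 | keep == j
    tibble(index_rank = k, index_id = idx,
           snp_id = panel$variant_ids[keep[sel]], r2 = r2[sel])
  })
  if (nrow(rows) == 0L) abort("no index SNPs usable")

  # a variant claimed by several indices goes to the highest-r2 index
  rows |>
    arrange(.data$snp_id, desc(.data$r2), .data$index_rank) |>
    distinct(.data$snp_id, .keep_all = TRUE) |>
    arrange(.data$index_rank, desc(.data$r2), .data$snp_id) |>
    select("index_id", "snp_id", "r2")
}
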