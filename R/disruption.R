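# Classification of TF-binding-disrupting SNPs: a SNP is called disrupting
# for a TF when (1) exactly one allele carries a significant motif
# occurrence covering the SNP and (2) the SNP base lies inside a ChIP-Seq
# peak of that same TF. Both criteria are required; peak matching is per-TF.

#' Does a SNP base fall inside a peak of a given TF?
#'
#' The SNP at 1-based position `pos` occupies 0-based coordinate `pos - 1`;
#' containment in the half-open peak interval `[start, end)` is tested after
#' normalizing chromosome names on both sides.
#'
#' @param variant One-row tibble with chrom and pos.
#' @param peaks Tibble of peaks (chrom, start, end, tf_name).
#' @param tf_name TF whose peaks to consider.
#' @return Logical scalar.
#' @export
snp_in_peak <- function(variant, peaks, tf_name) {
  if (nrow(peaks) == 0L) return(FALSE)
  coord <- pos_to_zero_based(variant$pos)
  any(peaks$tf_name == tf_name &
        normalize_chrom(peaks$chrom) == normalize_chrom(variant$chrom) &
        peaks$start <= coord & coord < peaks$end)
}

#' Classify allele-specific scan results into disruption calls
#'
#' One call is produced per motif scanned. Verdicts: `disrupting` (in peak,
#' exactly one allele hits), `motif_retained` (in peak, both alleles hit),
#' `no_motif` (in peak, neither hits), `no_peak` (SNP outside every peak of
#' the motif's TF — never disrupting regardless of the scan). In permissive
#' mode a call with both alleles hitting but an absolute score difference of
#' at least `delta_bits` is also labelled `disrupting`.
#'
#' @param scan Result of [scan_alleles()] for one variant (both alleles).
#' @param variant The one-row variant tibble that was scanned.
#' @param peaks Tibble of peaks tagged with tf_name.
#' @param permissive Also call large score shifts with both alleles
#'   significant (default FALSE).
#' @param delta_bits Score-shift threshold for permissive mode (default 2).
#' @return Tibble: variant_id, tf_name, motif_id, in_peak, ref_hit, alt_hit,
#'   ref_score, ref_p, alt_score, alt_p, delta_score_bits, verdict.
#' @export
classify_disruption <- function(scan, variant, peaks, permissive = FALSE,
                                delta_bits = 2) {
  stopifnot(length(unique(scan$variant_id)) == 1L)
  wide <- scan |>
    select("variant_id", "allele", "motif_id", "tf_name", "hit",
           "score_bits", "pvalue") |>
    tidyr::pivot_wider(names_from = "allele",
                       values_from = c("hit", "score_bits", "pvalue"))
  if (any(is.na(wide$tf_name))) abort("motif without a TF mapping")
  wide |>
    rowwise() |>
    mutate(in_peak = snp_in_peak(variant, peaks, .data$tf_name)) |>
    ungroup() |>
    mutate(
      delta_score_bits = ifelse(.data$hit_ref & .data$hit_alt,
                                .data$score_bits_ref - .data$score_bits_alt,
                                NA_real_),
      verdict = case_when(
        !.data$in_peak ~ "no_peak",
        xor(.data$hit_ref, .data$hit_alt) ~ "disrupting",
        .data$hit_ref & .data$hit_alt &
          permissive & abs(.data$delta_score_bits) >= delta_bits ~ "disrupting",
        .data$hit_ref & .data$hit_alt ~ "motif_retained",
        TRUE ~ "no_motif"
      )
    ) |>
    transmute(
      variant_id = .data$variant_id, tf_name = .data$tf_name,
      motif_id = .data$motif_id, in_peak = .data$in_peak,
      ref_hit = .data$hit_ref, alt_hit = .data$hit_alt,
      ref_score = .data$score_bits_ref, ref_p = .data$pvalue_ref,
      alt_score = .data$score_bits_alt, alt_p = .data$pvalue_alt,
      delta_score_bits = .data$delta_score_bits, verdict = .data$verdict
    )
}

#' Summarize disruption calls
#'
#' Counts, per TF, the SNPs with at least one disrupting call (a SNP
#' disrupting two motifs of the same TF counts once), lists the TFs
#' disrupted by each SNP, and counts SNPs disrupting two or more TFs.
#'
#' @param calls Tibble of disruption calls from [classify_disruption()]
#'   (rows from many variants may be concatenated).
#' @return An object of class `disruption_summary` with elements `per_tf`
#'   (tibble: tf_name, n_snps), `per_snp` (tibble: variant_id, tfs, n_tfs),
#'   and `n_multi_tf_snps`.
#' @export
summarize_disruptions <- function(calls) {
  disrupting <- calls |>
    filter(.data$verdict == "disrupting") |>
    distinct(.data$variant_id, .data$tf_name)
  per_tf <- disrupting |>
    count(.data$tf_name, name = "n_snps") |>
    arrange(desc(.data$n_snps), .data$tf_name)
  per_snp <- disrupting |>
    group_by(.data$variant_id) |>
    summarize(tfs = paste(sort(.data$tf_name), collapse = ","),
              n_tfs = n(), .groups = "drop") |>
    arrange(.data$variant_id)
  structure(
    list(per_tf = per_tf, per_snp = per_snp,
         n_functional_snps = nrow(per_snp),
         n_multi_tf_snps = sum(per_snp$n_tfs >= 2L)),
    class = "disruption_summary"
  )
}

#' @export
print.disruption_summary <- function(x, ...) {
  cat(sprintf("Disruption summary: %d functional SNP(s), %d disrupting >= 2 TFs\n",
              x$n_functional_snps, x$n_multi_tf_snps))
  if (nrow(x$per_tf) > 0L) {
    for (i in seq_len(nrow(x$per_tf))) {
      cat(sprintf("  %s: %d SNP(s)\n", x$per_tf$tf_name[i], x$per_tf$n_snps[i]))
    }
  }
  invisible(x)
}

#' @rdname summarize_disruptions
#' @param x A `disruption_summary`.
#' @param ... Unused.
#' @export
tidy.disruption_summary <- function(x, ...) x$per_tf

#' @rdname summarize_disruptions
#' @export
glance.disruption_summary <- function(x, ...) {
  tibble(n_functional_snps = x$n_functional_snps,
         n_tfs_disrupted = nrow(x$per_tf),
         n_multi_tf_snps = x$n_multi_tf_snps)
}
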