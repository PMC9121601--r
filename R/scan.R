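# Allele-specific window extraction and motif scanning. For each candidate
# SNP two windows are built that differ at exactly one base (reference vs
# alternate allele); each window is scanned on both strands against every
# motif, and the best significant hit covering the SNP is kept per motif.

base_codes <- function(window) {
  codes <- match(seq_chars(window), BASES)  # N and anything else -> NA
  codes
}

#' Extract the two allele windows around a SNP
#'
#' Cuts `flank` bases of reference sequence on each side of the SNP
#' (clamped at sequence ends) and substitutes the alternate allele at the
#' SNP base to form the second window. The reference base at the SNP
#' position must equal the variant's REF allele.
#'
#' @param variant One-row tibble (or list) with chrom, pos (1-based), id,
#'   ref, alt.
#' @param reference Tibble of sequence records from [read_fasta()].
#' @param cfg A [scan_config()].
#' @return A list: `ref_window`, `alt_window`, `snp_index` (0-based offset of
#'   the SNP within the window), `window_start` (1-based genomic position of
#'   the window's first base).
#' @export
allele_windows <- function(variant, reference, cfg = scan_config()) {
  chrom <- normalize_chrom(variant$chrom)
  hit <- which(normalize_chrom(reference$name) == chrom)
  if (length(hit) == 0L) {
    abort(sprintf("chromosome '%s' not found in reference", variant$chrom))
  }
  seq <- reference$sequence[[hit[1]]]
  len <- nchar(seq)
  pos <- as.integer(variant$pos)
  if (pos < 1L || pos > len) {
    abort(sprintf("position %d out of range for sequence '%s' (length %d)",
                  pos, variant$chrom, len))
  }
  lo <- max(1L, pos - cfg$flank)
  hi <- min(len, pos + cfg$flank)
  window <- substr(seq, lo, hi)
  snp_index <- pos - lo  # 0-based within window
  obs <- substr(window, snp_index + 1L, snp_index + 1L)
  if (obs != variant$ref) {
    abort(sprintf("REF mismatch at %s:%d for %s: expected %s, reference has %s",
                  variant$chrom, pos, variant$id, variant$ref, obs))
  }
  alt_window <- window
  substr(alt_window, snp_index + 1L, snp_index + 1L) <- variant$alt
  list(ref_window = window, alt_window = alt_window,
       snp_index = snp_index, window_start = lo)
}

#' Scan one window with one motif
#'
#' Evaluates every offset on the forward strand and, when configured, every
#' offset of the reverse complement. Candidate hits must have an exact match
#' p-value strictly below the threshold and, when `require_snp_overlap`,
#' must cover the SNP base (reverse-strand hits are mapped back to forward
#' coordinates first). The best candidate is chosen by highest integer
#' score, then smallest forward start, then `+` strand. Positions containing
#' `N` contribute score 0 (background-equivalent). A window shorter than the
#' motif yields no hit, with a warning.
#'
#' @param window DNA string (uppercase A/C/G/T/N).
#' @param lom A [log_odds_matrix()].
#' @param table The matching [score_pvalue_table()].
#' @param cfg A [scan_config()].
#' @param snp_index 0-based offset of the SNP within the window, or `NA` to
#'   disable the overlap requirement for this call.
#' @return A one-row tibble (motif_id, tf_name, strand, start, width,
#'   score_bits, pvalue, covers_snp) or `NULL` when no candidate passes.
#' @export
scan_window <- function(window, lom, table, cfg = scan_config(), snp_index = NA) {
  w <- lom$width
  L <- nchar(window)
  if (L < w) {
    warn(sprintf("window (%d bp) shorter than motif %s (%d bp); no scan", L, lom$motif_id, w))
    return(NULL)
  }
  offsets <- 0:(L - w)
  score_strand <- function(codes) {
    t(vapply(offsets, function(s) {
      idx <- codes[(s + 1L):(s + w)]
      c(sum(lom$int_scores[cbind(seq_len(w), idx)], na.rm = TRUE),
        sum(!is.na(idx)))
    }, numeric(2)))
  }
  fwd_codes <- base_codes(window)
  fwd <- score_strand(fwd_codes)
  cand <- tibble(strand = "+", start = offsets, int_score = fwd[, 1],
                 informative = fwd[, 2])
  if (cfg$both_strands) {
    rc_codes <- base_codes(revcomp(window))
    rcs <- score_strand(rc_codes)
    rc <- tibble(strand = "-", start_rc = offsets, int_score = rcs[, 1],
                 informative = rcs[, 2])
    rc$start <- L - rc$start_rc - w  # map back to forward coordinates
    cand <- bind_rows(cand, rc[, c("strand", "start", "int_score", "informative")])
  }
  cand$pvalue <- score_pvalue(table, cand$int_score)
  cand$covers_snp <- if (is.na(snp_index)) {
    rep(NA, nrow(cand))
  } else {
    cand$start <= snp_index & snp_index < cand$start + w
  }
  # an offset made entirely of N carries no sequence evidence and is never a hit
  keep <- cand$pvalue < cfg$p_threshold & cand$informative > 0
  if (cfg$require_snp_overlap && !is.na(snp_index)) keep <- keep & cand$covers_snp
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  best <- cand |>
    arrange(desc(.data$int_score), .data$start, .data$strand) |>
    slice(1L)
  tibble(motif_id = lom$motif_id, tf_name = lom$tf_name,
         strand = best$strand, start = best$start, width = w,
         score_bits = best$int_score * lom$epsilon, pvalue = best$pvalue,
         covers_snp = if (is.na(snp_index)) TRUE else best$covers_snp)
}

#' Precompile motifs for scanning
#'
#' Builds the log-odds matrix and exact p-value table for each PWM once, so
#' they can be reused across many SNPs.
#'
#' @param pwms List of [pwm()] objects.
#' @param cfg A [scan_config()].
#' @return A list of class `compiled_motifs`.
#' @export
compile_motifs <- function(pwms, cfg = scan_config()) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  out <- lapply(pwms, function(p) {
    lom <- log_odds(p, cfg)
    list(pwm = p, lom = lom, table = score_pvalue_table(lom, cfg))
  })
  names(out) <- vapply(out, function(m) m$pwm$motif_id, character(1))
  structure(out, class = "compiled_motifs")
}

#' Scan both alleles of a SNP against a motif set
#'
#' @param variant One-row tibble with chrom, pos, id, ref, alt.
#' @param reference Tibble of sequence records.
#' @param motifs List of [pwm()] objects or a [compile_motifs()] result.
#' @param cfg A [scan_config()].
#' @return Tibble with one row per (allele, motif): variant_id, allele
#'   ("ref"/"alt"), motif_id, tf_name, hit (logical), strand, start
#'   (0-based within window), width, score_bits, pvalue, covers_snp,
#'   window_start (1-based genomic), snp_index.
#' @export
scan_alleles <- function(variant, reference, motifs, cfg = scan_config()) {
  if (!inherits(motifs, "compiled_motifs")) motifs <- compile_motifs(motifs, cfg)
  win <- allele_windows(variant, reference, cfg)
  one_allele <- function(allele, window) {
    purrr::map_dfr(motifs, function(m) {
      best <- scan_window(window, m$lom, m$table, cfg, win$snp_index)
      if (is.null(best)) {
        tibble(motif_id = m$pwm$motif_id, tf_name = m$pwm$tf_name,
               hit = FALSE, strand = NA_character_, start = NA_integer_,
               width = m$pwm$width, score_bits = NA_real_, pvalue = NA_real_,
               covers_snp = NA)
      } else {
        tibble(motif_id = best$motif_id, tf_name = best$tf_name, hit = TRUE,
               strand = best$strand, start = as.integer(best$start),
               width = as.integer(best$width), score_bits = best$score_bits,
               pvalue = best$pvalue, covers_snp = best$covers_snp)
      }
    }) |>
      mutate(variant_id = variant$id, allele = allele,
             window_start = win$window_start, snp_index = win$snp_index,
             .before = 1L)
  }
  bind_rows(one_allele("ref", win$ref_window), one_allele("alt", win$alt_window))
}
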