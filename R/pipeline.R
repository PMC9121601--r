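# End-to-end orchestration: LD extraction -> allele-specific motif scan ->
# disruption classification -> optional eQTL consensus -> optional ASE ->
# plain-text report. Each stage writes its TSV so any stage can be rerun
# alone; reruns with identical inputs are byte-identical.

#' Pipeline configuration
#'
#' @param fasta Reference FASTA path.
#' @param vcf Phased panel VCF path.
#' @param index_snps Path to the index-SNP list (one id per line).
#' @param meme MEME minimal motif file path.
#' @param beds Named character vector of BED paths; names are TF names
#'   (unnamed entries use BED column 4).
#' @param out_dir Output directory for stage TSVs and the report.
#' @param r2_min LD extraction threshold, strict (default 0.6).
#' @param scan A [scan_config()].
#' @param eqtl_table Optional precomputed eQTL association TSV (see
#'   [read_eqtl_table()]).
#' @param eqtl_rule,eqtl_alpha,eqtl_tau Consensus significance rule and
#'   cutoffs (see [consensus_tally()]).
#' @param ase_counts Optional ASE read-count TSV (snp_id, count_allele1,
#'   count_allele2).
#' @param ase_alpha Per-SNP ASE significance level (default 0.05).
#' @param ase_background Optional `c(K, N)` genome-wide ASE background for
#'   the enrichment test.
#' @param permissive_disruption,delta_bits See [classify_disruption()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, vcf, index_snps, meme, beds, out_dir,
                            r2_min = 0.6, scan = scan_config(),
                            eqtl_table = NULL, eqtl_rule = "raw_p",
                            eqtl_alpha = 0.05, eqtl_tau = 0.01,
                            ase_counts = NULL, ase_alpha = 0.05,
                            ase_background = NULL,
                            permissive_disruption = FALSE, delta_bits = 2) {
  req <- c(fasta = fasta, vcf = vcf, index_snps = index_snps, meme = meme, beds)
  missing_files <- req[!file.exists(req)]
  if (length(missing_files) > 0L) {
    abort(sprintf("input file(s) not found: %s", paste(missing_files, collapse = ", ")))
  }
  structure(
    list(fasta = fasta, vcf = vcf, index_snps = index_snps, meme = meme,
         beds = beds, out_dir = out_dir, r2_min = r2_min, scan = scan,
         eqtl_table = eqtl_table, eqtl_rule = eqtl_rule,
         eqtl_alpha = eqtl_alpha, eqtl_tau = eqtl_tau,
         ase_counts = ase_counts, ase_alpha = ase_alpha,
         ase_background = ase_background,
         permissive_disruption = permissive_disruption,
         delta_bits = delta_bits),
    class = "pipeline_config"
  )
}

read_all_peaks <- function(beds) {
  nm <- names(beds) %||% rep("", length(beds))
  bind_rows(lapply(seq_along(beds), function(i) {
    read_peaks_bed(beds[[i]], tf_name = if (is.null(nm[i]) || is.na(nm[i])) "" else nm[i])
  }))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full pipeline
#'
#' Stages in order: LD partner extraction, allele-specific motif scan of
#' every candidate SNP (index SNPs and LD partners), disruption
#' classification against the peak sets, then eQTL consensus and ASE when
#' their inputs are configured. Each stage's table is written to
#' `out_dir`, a report is rendered, and everything is returned invisibly.
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `pipeline_result`: ld (tibble), scans
#'   (tibble), calls (tibble), summary ([summarize_disruptions()] result),
#'   consensus (or NULL), ase (or NULL), ase_enrichment (or NULL),
#'   report_path, and the per-stage file paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  # --- ld stage ---------------------------------------------------------
  ld_out <- run_stage("ld", {
    vcf <- read_vcf_snps(cfg$vcf)
    index_ids <- readLines(cfg$index_snps)
    index_ids <- index_ids[nzchar(index_ids)]
    partners <- ld_partners(vcf$panel, index_ids, r2_min = cfg$r2_min)
    list(vcf = vcf, partners = partners)
  })
  ld_tab <- ld_out$partners |>
    left_join(ld_out$vcf$variants, by = c(snp_id = "id")) |>
    select("index_id", "snp_id", "chrom", "pos", "ref", "alt", "r2")
  paths$ld <- file.path(cfg$out_dir, "ld_partners.tsv")
  readr::write_tsv(ld_tab, paths$ld)

  # --- scan stage: all candidate SNPs in the panel ----------------------
  scans <- run_stage("scan", {
    reference <- read_fasta(cfg$fasta)
    motifs <- compile_motifs(read_meme_motifs(cfg$meme), cfg$scan)
    candidates <- ld_out$vcf$variants
    purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
      scan_alleles(candidates[i, ], reference, motifs, cfg$scan)
    })
  })
  paths$scans <- file.path(cfg$out_dir, "motif_hits.tsv")
  readr::write_tsv(scans, paths$scans)

  # --- disruption stage -------------------------------------------------
  calls <- run_stage("classify", {
    peaks <- read_all_peaks(cfg$beds)
    candidates <- ld_out$vcf$variants
    purrr::map_dfr(unique(scans$variant_id), function(vid) {
      classify_disruption(scans |> filter(.data$variant_id == vid),
                          candidates |> filter(.data$id == vid),
                          peaks,
                          permissive = cfg$permissive_disruption,
                          delta_bits = cfg$delta_bits)
    })
  })
  disruption_summary <- summarize_disruptions(calls)
  paths$calls <- file.path(cfg$out_dir, "disruption_calls.tsv")
  readr::write_tsv(calls, paths$calls)
  paths$summary <- file.path(cfg$out_dir, "disruption_summary.tsv")
  readr::write_tsv(disruption_summary$per_tf, paths$summary)

  # --- eQTL stage (optional) --------------------------------------------
  consensus <- NULL
  if (!is.null(cfg$eqtl_table)) {
    consensus <- run_stage("eqtl", {
      assoc <- read_eqtl_table(cfg$eqtl_table)
      snps <- disruption_summary$per_snp$variant_id
      if (length(snps) == 0L) snps <- unique(assoc$snp_id)
      consensus_tally(assoc, snps, rule = cfg$eqtl_rule,
                      alpha = cfg$eqtl_alpha, tau = cfg$eqtl_tau)
    })
    paths$consensus <- file.path(cfg$out_dir, "eqtl_consensus.tsv")
    readr::write_tsv(consensus$per_snp, paths$consensus)
  }

  # --- ASE stage (optional) ---------------------------------------------
  ase <- NULL; enrichment <- NULL
  if (!is.null(cfg$ase_counts)) {
    ase <- run_stage("ase", {
      counts <- readr::read_tsv(cfg$ase_counts, show_col_types = FALSE)
      ase_test_table(counts, alpha = cfg$ase_alpha)
    })
    paths$ase <- file.path(cfg$out_dir, "ase_tests.tsv")
    readr::write_tsv(ase, paths$ase)
    if (!is.null(cfg$ase_background)) {
      enrichment <- ase_enrichment_test(
        k = sum(ase$significant), n = nrow(ase),
        K = cfg$ase_background[[1]], N = cfg$ase_background[[2]])
      paths$ase_enrichment <- file.path(cfg$out_dir, "ase_enrichment.tsv")
      readr::write_tsv(tidy(enrichment), paths$ase_enrichment)
    }
  }

  result <- structure(
    list(ld = ld_tab, scans = scans, calls = calls,
         summary = disruption_summary, consensus = consensus, ase = ase,
         ase_enrichment = enrichment, paths = paths, out_dir = cfg$out_dir),
    class = "pipeline_result"
  )
  result$report_path <- file.path(cfg$out_dir, "report.md")
  writeLines(render_report(result), result$report_path)
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(paste(render_report(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Render the pipeline report
#'
#' Plain-markdown summary mirroring the study's summary surfaces: per-TF
#' disruption counts, multi-TF SNPs, cross-dataset consensus tallies, and
#' the ASE enrichment line (k, n, K, N, p). Sections whose inputs were not
#' supplied are marked skipped.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
render_report <- function(result) {
  s <- result$summary
  lines <- c(
    "# Regulatory SNP pipeline report", "",
    sprintf("Candidate SNPs scanned: %d", length(unique(result$scans$variant_id))),
    sprintf("LD partners retained (incl. index SNPs): %d", nrow(result$ld)), "",
    "## TF binding-disrupting SNPs", "")
  if (s$n_functional_snps == 0L) {
    lines <- c(lines, "No functional (TF binding-disrupting) SNPs found.")
  } else {
    lines <- c(lines,
      sprintf("Functional SNPs: %d; disrupting >= 2 TFs: %d",
              s$n_functional_snps, s$n_multi_tf_snps),
      sprintf("- %s: %d SNP(s)", s$per_tf$tf_name, s$per_tf$n_snps), "",
      sprintf("- %s disrupts: %s", s$per_snp$variant_id, s$per_snp$tfs))
  }
  lines <- c(lines, "", "## eQTL consensus", "")
  if (is.null(result$consensus)) {
    lines <- c(lines, "skipped (no eQTL input)")
  } else {
    tl <- result$consensus$tally
    lines <- c(lines, sprintf("- significant in >= %d dataset(s): %d SNP(s)",
                              tl$k, tl$n_snps_at_least_k))
  }
  lines <- c(lines, "", "## Allele-specific expression", "")
  if (is.null(result$ase)) {
    lines <- c(lines, "skipped (no ASE input)")
  } else {
    lines <- c(lines, sprintf("SNPs tested: %d; significant ASE: %d",
                              nrow(result$ase), sum(result$ase$significant)))
    if (!is.null(result$ase_enrichment)) {
      e <- result$ase_enrichment
      lines <- c(lines, sprintf(
        "Enrichment: k=%d n=%d K=%.0f N=%.0f p=%.3g", e$k, e$n, e$K, e$N, e$p_value))
    }
  }
  lines
}
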