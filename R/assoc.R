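# eQTL association scanning, multiple-testing correction, cross-dataset
# consensus tallies, and case/control differential-expression screening.
# The association model is an ordinary least-squares regression of (log2)
# expression on alternate-allele dosage; the published consortium pipelines
# behind the real datasets are not reimplemented.

#' Construct an expression dataset
#'
#' @param dataset_id Dataset label.
#' @param expression Genes-by-samples numeric matrix (log2 scale), with gene
#'   ids as rownames and sample ids as colnames.
#' @param dosages Variants-by-samples matrix of alternate-allele counts
#'   \{0, 1, 2\}, variant ids as rownames, same sample order.
#' @param group_labels Optional per-sample factor with levels
#'   `case`/`control`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, expression, dosages = NULL,
                               group_labels = NULL) {
  expression <- as.matrix(expression)
  if (!is.null(dosages)) {
    dosages <- as.matrix(dosages)
    if (ncol(dosages) != ncol(expression)) abort("dosage/expression sample counts differ")
    if (any(!dosages %in% c(0, 1, 2))) abort("dosages must be 0, 1 or 2")
  }
  if (!is.null(group_labels)) {
    if (length(group_labels) != ncol(expression)) abort("one group label per sample required")
    if (any(!group_labels %in% c("case", "control"))) abort("group labels must be 'case'/'control'")
  }
  if (any(!is.finite(expression))) abort("expression matrix contains missing values")
  structure(
    list(dataset_id = as.character(dataset_id), expression = expression,
         dosages = dosages, group_labels = group_labels),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset %s: %d genes x %d samples, %d variant(s)%s>\n",
              x$dataset_id, nrow(x$expression), ncol(x$expression),
              if (is.null(x$dosages)) 0L else nrow(x$dosages),
              if (is.null(x$group_labels)) "" else ", case/control labels"))
  invisible(x)
}

#' eQTL scan: regress expression on allele dosage
#'
#' Ordinary least squares of expression on dosage per (SNP, gene) pair:
#' `beta = cov(g, y) / var(g)`, two-sided p-value from the t statistic with
#' `n - 2` degrees of freedom. Pairs with zero dosage variance are skipped
#' with a warning. A perfect fit (zero residual variance, nonzero slope)
#' gets the smallest representable positive p-value and is flagged; a
#' constant response gets beta 0, p 1.
#'
#' @param ds An [expression_dataset()] with dosages.
#' @param pairs Tibble with columns snp_id, gene_id; defaults to all
#'   (variant, gene) combinations.
#' @return Tibble: dataset_id, snp_id, gene_id, beta, se, t_stat, p_value,
#'   fdr (BH across the scan), degenerate (flag for perfect fits).
#' @export
eqtl_scan <- function(ds, pairs = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$dosages)) abort("dataset carries no dosages")
  n <- ncol(ds$expression)
  if (n < 3L) abort("need at least 3 samples")
  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(snp_id = rownames(ds$dosages),
                                gene_id = rownames(ds$expression))
  }
  res <- purrr::pmap_dfr(pairs, function(snp_id, gene_id) {
    g <- ds$dosages[snp_id, ]
    y <- ds$expression[gene_id, ]
    vg <- stats::var(g)
    if (vg == 0) {
      warn(sprintf("zero dosage variance for %s; association skipped", snp_id))
      return(tibble())
    }
    beta <- stats::cov(g, y) / vg
    resid <- y - mean(y) - beta * (g - mean(g))
    rss <- sum(resid^2)
    degenerate <- FALSE
    if (rss == 0) {
      if (beta == 0) {  # constant response: no evidence either way
        se <- 0; t_stat <- 0; p <- 1
      } else {
        se <- 0; t_stat <- Inf; p <- .Machine$double.xmin; degenerate <- TRUE
      }
    } else {
      sigma2 <- rss / (n - 2)
      se <- sqrt(sigma2 / (vg * (n - 1)))
      t_stat <- beta / se
      p <- 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
    }
    tibble(snp_id = snp_id, gene_id = gene_id, beta = beta, se = se,
           t_stat = t_stat, p_value = p, degenerate = degenerate)
  })
  if (nrow(res) == 0L) return(res)
  res |>
    mutate(dataset_id = ds$dataset_id, .before = 1L) |>
    mutate(fdr = bh_fdr(.data$p_value))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin, validated wrapper over `stats::p.adjust(method = "BH")`, returning
#' adjusted values in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, capped at 1.
#' @export
bh_fdr <- function(p_values) {
  assert_prob_vector(p_values, "p-values")
  stats::p.adjust(p_values, method = "BH")
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` elementwise, `m` the number of tests.
#'
#' @inheritParams bh_fdr
#' @return Adjusted values.
#' @export
bonferroni <- function(p_values) {
  assert_prob_vector(p_values, "p-values")
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Cross-dataset consensus tally of eQTL support
#'
#' Counts, per SNP, the number of datasets in which it has at least one
#' significant gene association, and tallies how many SNPs reach at least
#' `k` supporting datasets for `k = 1..n_datasets`. Significance rule:
#' either `fdr < alpha` (default) or raw `p < tau`, the two rules the study
#' design supports.
#'
#' @param associations Tibble with dataset_id, snp_id, gene_id, p_value and
#'   (for the FDR rule) fdr.
#' @param snp_ids SNPs of interest; associations for other SNPs are ignored
#'   with a warning.
#' @param rule `"fdr"` or `"raw_p"`.
#' @param alpha FDR cutoff (default 0.05).
#' @param tau Raw-p cutoff (default 0.01).
#' @param n_datasets Total datasets for the tally range; defaults to the
#'   number of distinct dataset_ids present.
#' @return An object of class `consensus_summary`: `per_snp` (snp_id,
#'   n_datasets_supporting), `tally` (k, n_snps_at_least_k, non-increasing
#'   in k), `support` (per SNP-gene dataset support).
#' @export
consensus_tally <- function(associations, snp_ids, rule = c("fdr", "raw_p"),
                            alpha = 0.05, tau = 0.01, n_datasets = NULL) {
  rule <- match.arg(rule)
  unknown <- setdiff(unique(associations$snp_id), snp_ids)
  if (length(unknown) > 0L) {
    warn(sprintf("associations for %d SNP(s) outside the query set ignored", length(unknown)))
    associations <- associations |> filter(.data$snp_id %in% snp_ids)
  }
  if (is.null(n_datasets)) n_datasets <- length(unique(associations$dataset_id))
  n_datasets <- max(1L, n_datasets)
  sig <- associations |>
    mutate(significant = if (rule == "fdr") .data$fdr < alpha else .data$p_value < tau)
  support <- sig |>
    filter(.data$significant) |>
    distinct(.data$snp_id, .data$gene_id, .data$dataset_id) |>
    group_by(.data$snp_id, .data$gene_id) |>
    summarize(n_datasets = n(),
              datasets = paste(sort(.data$dataset_id), collapse = ","),
              .groups = "drop")
  per_snp <- sig |>
    filter(.data$significant) |>
    distinct(.data$snp_id, .data$dataset_id) |>
    count(.data$snp_id, name = "n_datasets_supporting") |>
    right_join(tibble(snp_id = snp_ids), by = "snp_id") |>
    mutate(n_datasets_supporting = tidyr::replace_na(.data$n_datasets_supporting, 0L)) |>
    arrange(match(.data$snp_id, snp_ids))
  tally <- tibble(k = seq_len(n_datasets)) |>
    rowwise() |>
    mutate(n_snps_at_least_k = sum(per_snp$n_datasets_supporting >= .data$k)) |>
    ungroup()
  structure(
    list(per_snp = per_snp, tally = tally, support = support,
         rule = rule, alpha = alpha, tau = tau, n_datasets = n_datasets),
    class = "consensus_summary"
  )
}

#' @export
print.consensus_summary <- function(x, ...) {
  rule <- if (x$rule == "fdr") sprintf("FDR < %g", x$alpha) else sprintf("p < %g", x$tau)
  cat(sprintf("Consensus across %d dataset(s), rule %s:\n", x$n_datasets, rule))
  for (i in seq_len(nrow(x$tally))) {
    cat(sprintf("  >= %d dataset(s): %d SNP(s)\n",
                x$tally$k[i], x$tally$n_snps_at_least_k[i]))
  }
  invisible(x)
}

#' @rdname consensus_tally
#' @param x A `consensus_summary`.
#' @param ... Unused.
#' @export
tidy.consensus_summary <- function(x, ...) x$tally

#' @rdname consensus_tally
#' @export
glance.consensus_summary <- function(x, ...) {
  tibble(n_datasets = x$n_datasets, rule = x$rule,
         n_snps_supported = sum(x$per_snp$n_datasets_supporting >= 1L),
         n_snps_all_datasets = sum(x$per_snp$n_datasets_supporting >= x$n_datasets))
}

#' Case/control differential expression screen
#'
#' Per gene: log2 fold change = mean(case) - mean(control) on the log2
#' scale, two-sided Welch (unequal-variance) t-test p-value, and BH-FDR
#' across all tested genes. Both groups need at least two samples.
#'
#' @param ds An [expression_dataset()] with case/control group labels.
#' @return Tibble: gene_id, log2_fc, p_value, fdr.
#' @export
differential_expression <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$group_labels)) abort("dataset carries no case/control labels")
  case <- ds$group_labels == "case"
  if (sum(case) < 2L || sum(!case) < 2L) abort("each group needs at least 2 samples")
  res <- purrr::map_dfr(rownames(ds$expression), function(g) {
    y <- ds$expression[g, ]
    tt <- stats::t.test(y[case], y[!case], var.equal = FALSE)
    tibble(gene_id = g, log2_fc = mean(y[case]) - mean(y[!case]),
           p_value = tt$p.value)
  })
  res |> mutate(fdr = bh_fdr(.data$p_value))
}

#' Read a precomputed eQTL association table
#'
#' TSV with columns dataset_id, snp_id, gene_id, p_value and optionally beta
#' and fdr. When a dataset lacks FDR values, Bonferroni adjustment within
#' that dataset fills the fdr column (mirroring the practice of falling back
#' to Bonferroni when the source provides no FDR).
#'
#' @param path Path to the TSV file.
#' @return Tibble with fdr filled for every row.
#' @export
read_eqtl_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("dataset_id", "snp_id", "gene_id", "p_value")
  if (!all(need %in% names(tab))) {
    abort(sprintf("eQTL table must have columns: %s", paste(need, collapse = ", ")))
  }
  if (!"fdr" %in% names(tab)) tab$fdr <- NA_real_
  tab |>
    group_by(.data$dataset_id) |>
    mutate(fdr = if (all(is.na(.data$fdr))) bonferroni(.data$p_value) else .data$fdr) |>
    ungroup()
}
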