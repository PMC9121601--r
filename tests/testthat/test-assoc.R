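make_ds <- function(y, g, id = "DS1") {
  expression_dataset(id,
                     matrix(y, nrow = 1, dimnames = list("g1", paste0("s", seq_along(y)))),
                     matrix(g, nrow = 1, dimnames = list("snp1", paste0("s", seq_along(g)))))
}

test_that("eqtl_scan matches closed-form OLS and lm on a fixed example", {
  g <- c(0, 1, 2, 0, 1, 2)
  y <- c(1.0, 2.1, 2.9, 1.2, 1.8, 3.1)
  res <- eqtl_scan(make_ds(y, g))
  fit <- summary(lm(y ~ g))$coefficients  # independent route
  expect_equal(res$beta, fit["g", "Estimate"])
  expect_equal(res$se, fit["g", "Std. Error"])
  expect_equal(res$p_value, fit["g", "Pr(>|t|)"])
})

test_that("eqtl_scan degenerate policies: perfect fit, constant response, zero variance", {
  res <- eqtl_scan(make_ds(2 * (0:9 %% 3), rep(0:2, length.out = 10)))
  expect_equal(res$beta, 2.0)
  expect_true(res$degenerate)
  expect_equal(res$p_value, .Machine$double.xmin)

  res2 <- eqtl_scan(make_ds(rep(5, 10), rep(0:2, length.out = 10)))
  expect_equal(res2$beta, 0)
  expect_equal(res2$p_value, 1)

  expect_warning(res3 <- eqtl_scan(make_ds(rnorm(10), rep(1, 10))), "zero dosage variance")
  expect_equal(nrow(res3), 0L)
})

test_that("BH and Bonferroni match hand step-up oracles and p.adjust semantics", {
  expect_equal(bh_fdr(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bonferroni(c(0.01)), 0.01)
  expect_equal(bonferroni(c(0.01, 0.4, 0.9)), c(0.03, 1.0, 1.0))
  expect_equal(bonferroni(rep(0.2, 10)), rep(1.0, 10))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  set.seed(19)
  for (i in 1:50) {
    p <- runif(sample(2:40, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))  # never below the raw p-value
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), adj[perm], tolerance = 1e-12)
  }
})

test_that("consensus_tally counts dataset support with non-increasing tallies", {
  assoc <- tibble::tibble(
    dataset_id = c(paste0("DS", 1:5), "DS1", "DS9"),
    snp_id = c(rep("s1", 5), "s2", "zzz"),
    gene_id = "g", p_value = c(rep(1e-5, 6), 1e-6),
    fdr = c(rep(1e-4, 6), 1e-5))
  expect_warning(cs <- consensus_tally(assoc, c("s1", "s2", "s3"),
                                       rule = "fdr", n_datasets = 5),
                 "outside the query set")
  expect_equal(cs$per_snp$n_datasets_supporting,
               c(5L, 1L, 0L))
  expect_equal(cs$tally$n_snps_at_least_k, c(2L, 1L, 1L, 1L, 1L))
  expect_true(all(diff(cs$tally$n_snps_at_least_k) <= 0))
  expect_equal(glance(cs)$n_snps_all_datasets, 1L)

  none <- suppressWarnings(
    consensus_tally(assoc |> dplyr::mutate(fdr = 0.9), c("s1", "s2"),
                    rule = "fdr", n_datasets = 5))
  expect_equal(sum(none$tally$n_snps_at_least_k), 0L)
})

test_that("planted multi-dataset consensus structure is recovered", {
  cfg <- scenario_config(seed = 303)
  snps <- paste0("snp", 1:7)  # 3 consensus, 2 dataset-specific, 2 null
  gen <- generate_eqtl_expression(cfg, snps)
  assoc <- purrr::map_dfr(gen$datasets, function(ds) {
    eqtl_scan(ds, pairs = tibble::tibble(snp_id = snps,
                                         gene_id = paste0("GENE_", snps)))
  })
  cs <- consensus_tally(assoc, snps, rule = "raw_p", tau = 0.01, n_datasets = 5)
  # with n = 200 and beta = 1 the planted effects are essentially always seen
  expect_equal(cs$per_snp$n_datasets_supporting[1:3], rep(5L, 3))
  expect_true(all(cs$per_snp$n_datasets_supporting[4:5] >= 1L))
  expect_true(all(cs$per_snp$n_datasets_supporting[6:7] <= 1L))
  expect_equal(cs$tally$n_snps_at_least_k[5], 3L)
})

test_that("differential expression finds a planted shift and validates groups", {
  cfg <- scenario_config(seed = 404)
  genes <- paste0("g", 1:20)
  gen <- generate_case_control_expression(cfg, genes, shifted_genes = c("g1", "g2"))
  de <- differential_expression(gen$dataset)
  expect_true(all(de$fdr[de$gene_id %in% c("g1", "g2")] < 0.05))
  expect_equal(de$log2_fc[de$gene_id == "g1"], 0.5, tolerance = 0.2)
  # null genes are not swept in wholesale
  expect_lt(mean(de$p_value[!de$gene_id %in% c("g1", "g2")] < 0.05), 0.3)
  expect_true(all(de$fdr >= de$p_value))

  # Welch p-value agrees with stats::t.test as the independent route
  y <- gen$dataset$expression["g1", ]
  case <- gen$dataset$group_labels == "case"
  expect_equal(de$p_value[de$gene_id == "g1"],
               t.test(y[case], y[!case])$p.value)

  bad <- expression_dataset("x", matrix(rnorm(9), nrow = 3,
                                        dimnames = list(letters[1:3], NULL)),
                            group_labels = c("case", "control", "control"))
  expect_error(differential_expression(bad), "at least 2")
})

test_that("read_eqtl_table fills missing FDR with Bonferroni per dataset", {
  f <- withr::local_tempfile()
  readr::write_tsv(tibble::tibble(
    dataset_id = c("A", "A", "B"), snp_id = "s", gene_id = c("g1", "g2", "g1"),
    p_value = c(0.01, 0.4, 0.02), fdr = c(0.03, 0.5, NA)), f)
  tab <- read_eqtl_table(f)
  expect_equal(tab$fdr[1:2], c(0.03, 0.5))   # provided values kept
  expect_equal(tab$fdr[3], 0.02)             # Bonferroni with m = 1
})
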