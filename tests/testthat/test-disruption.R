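peak_tbl <- function(...) tibble::tibble(...)

test_that("snp_in_peak uses half-open 0-based containment and per-TF matching", {
  v <- tibble::tibble(chrom = "chr1", pos = 100L, id = "s")
  peaks <- peak_tbl(chrom = "chr1", start = 99L, end = 100L, tf_name = "CTCF")
  expect_true(snp_in_peak(v, peaks, "CTCF"))
  peaks2 <- peak_tbl(chrom = "chr1", start = 100L, end = 200L, tf_name = "CTCF")
  expect_false(snp_in_peak(v, peaks2, "CTCF"))  # 0-based coord 99 outside
  peaks3 <- peak_tbl(chrom = "chr1", start = 90L, end = 110L, tf_name = "REST")
  expect_false(snp_in_peak(v, peaks3, "CTCF"))  # other TF's peak
  peaks4 <- peak_tbl(chrom = "1", start = 90L, end = 110L, tf_name = "CTCF")
  expect_true(snp_in_peak(v, peaks4, "CTCF"))   # chr-dialect reconciliation
})

fake_scan <- function(id, motif, tf, ref_hit, alt_hit,
                      ref_score = 10, alt_score = 10) {
  mk <- function(allele, hit, score) {
    tibble::tibble(variant_id = id, allele = allele, motif_id = motif,
                   tf_name = tf, hit = hit,
                   strand = ifelse(hit, "+", NA_character_),
                   start = ifelse(hit, 5L, NA_integer_), width = 6L,
                   score_bits = ifelse(hit, score, NA_real_),
                   pvalue = ifelse(hit, 1e-4, NA_real_),
                   covers_snp = ifelse(hit, TRUE, NA))
  }
  dplyr::bind_rows(mk("ref", ref_hit, ref_score), mk("alt", alt_hit, alt_score))
}

test_that("verdicts follow the two-criterion rule", {
  v <- tibble::tibble(chrom = "chr1", pos = 100L, id = "s")
  inside <- peak_tbl(chrom = "chr1", start = 50L, end = 150L, tf_name = "CTCF")
  outside <- peak_tbl(chrom = "chr1", start = 500L, end = 600L, tf_name = "CTCF")

  # ref hit only, inside the TF's peak -> disrupting
  call <- classify_disruption(fake_scan("s", "m", "CTCF", TRUE, FALSE), v, inside)
  expect_equal(call$verdict, "disrupting")
  expect_true(is.na(call$delta_score_bits))

  # same scan but SNP outside all peaks of that TF -> no_peak
  call2 <- classify_disruption(fake_scan("s", "m", "CTCF", TRUE, FALSE), v, outside)
  expect_equal(call2$verdict, "no_peak")
  expect_false(call2$in_peak)

  # both alleles hit with equal scores -> motif_retained, delta 0
  call3 <- classify_disruption(fake_scan("s", "m", "CTCF", TRUE, TRUE), v, inside)
  expect_equal(call3$verdict, "motif_retained")
  expect_equal(call3$delta_score_bits, 0)

  # neither allele hits inside the peak -> no_motif
  call4 <- classify_disruption(fake_scan("s", "m", "CTCF", FALSE, FALSE), v, inside)
  expect_equal(call4$verdict, "no_motif")
})

test_that("permissive mode promotes large score shifts only when enabled", {
  v <- tibble::tibble(chrom = "chr1", pos = 100L, id = "s")
  inside <- peak_tbl(chrom = "chr1", start = 50L, end = 150L, tf_name = "CTCF")
  scan <- fake_scan("s", "m", "CTCF", TRUE, TRUE, ref_score = 12, alt_score = 9)
  expect_equal(classify_disruption(scan, v, inside)$verdict, "motif_retained")
  expect_equal(classify_disruption(scan, v, inside, permissive = TRUE,
                                   delta_bits = 2)$verdict, "disrupting")
  expect_equal(classify_disruption(scan, v, inside, permissive = TRUE,
                                   delta_bits = 4)$verdict, "motif_retained")
})

test_that("summaries count each SNP once per TF and track multi-TF SNPs", {
  empty <- summarize_disruptions(
    classify_disruption(fake_scan("s", "m", "CTCF", FALSE, FALSE),
                        tibble::tibble(chrom = "chr1", pos = 100L, id = "s"),
                        peak_tbl(chrom = "chr1", start = 50L, end = 150L,
                                 tf_name = "CTCF")))
  expect_equal(empty$n_functional_snps, 0L)
  expect_equal(nrow(tidy(empty)), 0L)

  calls <- tibble::tibble(
    variant_id = c("s1", "s1", "s1", "s2"),
    tf_name = c("CTCF", "CTCF", "TAF1", "CTCF"),
    motif_id = c("m1", "m1b", "m2", "m1"),
    verdict = c("disrupting", "disrupting", "disrupting", "no_motif"))
  s <- summarize_disruptions(calls)
  # two motifs of the same TF count once for that TF
  expect_equal(s$per_tf$n_snps[s$per_tf$tf_name == "CTCF"], 1L)
  expect_equal(s$per_tf$n_snps[s$per_tf$tf_name == "TAF1"], 1L)
  expect_equal(s$n_multi_tf_snps, 1L)
  expect_equal(glance(s)$n_functional_snps, 1L)
})

test_that("planted scenario truth is recovered and no out-of-peak SNP is called", {
  cfg_scan <- scan_config()
  sc <- local_scenario(seed = 202)
  motifs <- compile_motifs(sc$motifs, cfg_scan)
  calls <- purrr::map_dfr(seq_len(nrow(sc$variants)), function(i) {
    v <- sc$variants[i, ]
    classify_disruption(scan_alleles(v, sc$reference, motifs, cfg_scan),
                        v, sc$peaks)
  })
  s <- summarize_disruptions(calls)
  truth_dis <- sc$truth |> dplyr::filter(class == "disrupting")
  expect_setequal(s$per_snp$variant_id, truth_dis$snp_id)
  expect_equal(s$n_functional_snps, nrow(truth_dis))
  # per-TF counts equal the generator's truth table
  truth_tf <- truth_dis |> dplyr::count(tf_name, name = "n_snps")
  expect_equal(s$per_tf |> dplyr::arrange(tf_name),
               truth_tf |> dplyr::arrange(tf_name) |> tibble::as_tibble())

  # universal guard: no disrupting call for a SNP outside every same-TF peak
  disrupting <- calls |> dplyr::filter(verdict == "disrupting")
  for (i in seq_len(nrow(disrupting))) {
    v <- sc$variants |> dplyr::filter(id == disrupting$variant_id[i])
    expect_true(snp_in_peak(v, sc$peaks, disrupting$tf_name[i]))
  }
})

test_that("identical inputs give identical call tables", {
  cfg_scan <- scan_config()
  sc <- local_scenario(seed = 77)
  motifs <- compile_motifs(sc$motifs, cfg_scan)
  v <- sc$variants[1, ]
  c1 <- classify_disruption(scan_alleles(v, sc$reference, motifs, cfg_scan),
                            v, sc$peaks)
  c2 <- classify_disruption(scan_alleles(v, sc$reference, motifs, cfg_scan),
                            v, sc$peaks)
  expect_identical(c1, c2)
})
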