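ref_record <- function(seq, name = "chr1") tibble::tibble(name = name, sequence = seq)

test_that("allele windows are centred, clamped, and differ at exactly one base", {
  set.seed(8)
  long <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  ref <- ref_record(long)
  v <- tibble::tibble(chrom = "chr1", pos = 1000L, id = "s",
                      ref = substr(long, 1000, 1000), alt = "N")
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  w <- allele_windows(v, ref, scan_config(flank = 20))
  expect_equal(nchar(w$ref_window), 41L)
  expect_equal(w$snp_index, 20L)
  diff_at <- which(strsplit(w$ref_window, "")[[1]] != strsplit(w$alt_window, "")[[1]])
  expect_equal(diff_at, 21L)  # 1-based position of the 0-based snp_index 20

  # clamping at the start of a short sequence
  short <- substr(long, 1, 30)
  v2 <- tibble::tibble(chrom = "chr1", pos = 10L, id = "s2",
                       ref = substr(short, 10, 10), alt = "A")
  v2$alt <- setdiff(c("A", "C", "G", "T"), v2$ref)[1]
  w2 <- allele_windows(v2, ref_record(short), scan_config(flank = 20))
  expect_equal(nchar(w2$ref_window), 30L)
  expect_equal(w2$snp_index, 9L)
})

test_that("REF mismatches and bad positions are errors; chr dialects are reconciled", {
  ref <- ref_record(strrep("G", 100))
  v <- tibble::tibble(chrom = "1", pos = 50L, id = "s", ref = "A", alt = "C")
  expect_error(allele_windows(v, ref), "REF mismatch")
  v$ref <- "G"
  expect_silent(allele_windows(v, ref))  # "1" matches record "chr1"
  v$pos <- 500L
  expect_error(allele_windows(v, ref), "out of range")
})

test_that("a planted consensus is found at its offset with the consensus score", {
  set.seed(21)
  cfg <- scan_config()
  p <- build_pwm_from_sites(rep("ACGTAC", 30), pseudocount = 0.5, motif_id = "m")
  lom <- log_odds(p, cfg)
  tab <- score_pvalue_table(lom, cfg)
  window <- paste0(strrep("N", 10), "ACGTAC", strrep("N", 10))
  hit <- scan_window(window, lom, tab, cfg, snp_index = 12L)
  expect_equal(hit$start, 10)
  expect_equal(hit$strand, "+")
  # direct scoring of that offset through the integer matrix
  expected <- sum(lom$int_scores[cbind(1:6, match(c("A","C","G","T","A","C"),
                                                  c("A","C","G","T")))])
  expect_equal(hit$score_bits, expected * cfg$epsilon)
  expect_true(hit$pvalue < cfg$p_threshold)
  expect_true(hit$covers_snp)
})

test_that("all-N windows and too-short windows yield no hit", {
  cfg <- scan_config()
  p <- build_pwm_from_sites(rep("ACGTAC", 30), pseudocount = 0.5)
  lom <- log_odds(p, cfg)
  tab <- score_pvalue_table(lom, cfg)
  expect_null(scan_window(strrep("N", 30), lom, tab, cfg, snp_index = 15L))
  expect_warning(res <- scan_window("ACG", lom, tab, cfg, snp_index = 1L),
                 "shorter than motif")
  expect_null(res)
})

test_that("strand closure: best score is invariant under reverse complement", {
  set.seed(33)
  cfg <- scan_config(p_threshold = 0.999, require_snp_overlap = FALSE)
  for (i in 1:20) {
    p <- random_pwm(5, sharp = i %% 2 == 0)
    lom <- log_odds(p, cfg)
    tab <- score_pvalue_table(lom, cfg)
    window <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")
    h1 <- scan_window(window, lom, tab, cfg, snp_index = NA)
    h2 <- scan_window(revcomp(window), lom, tab, cfg, snp_index = NA)
    expect_equal(h1$score_bits, h2$score_bits)
  }
})

test_that("tightening the p threshold never adds hits", {
  set.seed(44)
  p <- random_pwm(5, sharp = TRUE)
  windows <- replicate(40, paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                                 collapse = ""))
  n_hits <- vapply(c(0.05, 0.01, 0.001), function(thr) {
    cfg <- scan_config(p_threshold = thr, require_snp_overlap = FALSE)
    lom <- log_odds(p, cfg); tab <- score_pvalue_table(lom, cfg)
    sum(vapply(windows, function(w) !is.null(scan_window(w, lom, tab, cfg, NA)),
               logical(1)))
  }, numeric(1))
  expect_true(all(diff(n_hits) <= 0))
})

test_that("scan_alleles separates a broken consensus from a symmetric change", {
  cfg <- scan_config()
  sc <- local_scenario(seed = 5)
  motifs <- compile_motifs(sc$motifs, cfg)
  dis <- sc$truth |> dplyr::filter(class == "disrupting")
  for (i in seq_len(nrow(dis))) {
    v <- sc$variants |> dplyr::filter(id == dis$snp_id[i])
    res <- scan_alleles(v, sc$reference, motifs, cfg)
    own <- res |> dplyr::filter(tf_name == dis$tf_name[i])
    expect_true(own$hit[own$allele == "ref"])
    expect_false(own$hit[own$allele == "alt"])
  }
  # a background SNP far from any motif: no hit on either allele
  bg <- sc$variants |> dplyr::filter(id == "rsBG1")
  res_bg <- scan_alleles(bg, sc$reference, motifs, cfg)
  expect_false(any(res_bg$hit))
})

test_that("allele locality: when no candidate covers the SNP, both alleles agree", {
  # motif planted outside the covering range of the SNP: identical results
  cfg <- scan_config(flank = 20)
  p <- build_pwm_from_sites(rep("ACGTAC", 30), pseudocount = 0.5)
  seq <- paste0("ACGTAC", strrep("T", 60))
  ref <- ref_record(seq)
  v <- tibble::tibble(chrom = "chr1", pos = 40L, id = "s", ref = "T", alt = "C")
  res <- scan_alleles(v, ref, list(p), cfg)
  ref_rows <- res |> dplyr::filter(allele == "ref") |> dplyr::select(-allele)
  alt_rows <- res |> dplyr::filter(allele == "alt") |> dplyr::select(-allele)
  expect_equal(ref_rows, alt_rows)
  expect_false(any(res$hit))  # the distant motif does not cover the SNP
})
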