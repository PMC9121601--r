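test_that("generate_reference: determinism, GC control, validation", {
  r1 <- generate_reference(1000, 0.5, seed = 9)
  r2 <- generate_reference(1000, 0.5, seed = 9)
  expect_identical(r1, r2)
  expect_false(identical(r1, generate_reference(1000, 0.5, seed = 10)))

  big <- generate_reference(100000, 0.5, seed = 9)
  gc <- mean(strsplit(big$sequence, "")[[1]] %in% c("G", "C"))
  expect_equal(gc, 0.5, tolerance = 0.01)

  skew <- generate_reference(100000, 0.3, seed = 9)
  gc2 <- mean(strsplit(skew$sequence, "")[[1]] %in% c("G", "C"))
  expect_equal(gc2, 0.3, tolerance = 0.01)

  expect_error(generate_reference(10, 0.5, seed = 1), ">= 100")
  expect_error(generate_reference(1000, 1.5, seed = 1), "gc")
})

test_that("generated motifs hit the requested information content", {
  cfg <- scenario_config(seed = 1, motif_info_bits_per_column = 1.86)
  ms <- generate_motifs(cfg)
  for (m in ms) {
    expect_equal(pwm_information(m), rep(1.86, m$width), tolerance = 1e-6)
  }
})

test_that("LD panel realizes target r2 and threshold behavior around 0.6", {
  hits <- 0L; realized_09 <- numeric()
  for (seed in 1:40) {
    cfg <- scenario_config(seed = seed, n_index_snps = 1L,
                           partner_r2_targets = c(0.9, 0.3))
    ld <- generate_ld_panel(cfg)
    out <- ld_partners(ld$panel, "rsIDX1", r2_min = 0.6)
    ok <- setequal(out$snp_id, c("rsIDX1", "rsP1_1"))
    hits <- hits + ok
    realized_09 <- c(realized_09, ld$truth$realized_r2[ld$truth$snp_id == "rsP1_1"])
  }
  # correct partner set in >= 95% of seeds; realized r2 concentrated near 0.9
  expect_gte(hits / 40, 0.95)
  expect_gte(mean(abs(realized_09 - 0.9) < 0.15), 0.95)
})

test_that("target r2 = 1 duplicates the index exactly", {
  cfg <- scenario_config(seed = 2, n_index_snps = 1L, partner_r2_targets = 1.0)
  ld <- generate_ld_panel(cfg)
  expect_equal(ld$panel$haplotypes[, 1], ld$panel$haplotypes[, 2])
  expect_equal(ld$truth$realized_r2, c(1, 1))
  expect_error(generate_ld_panel(scenario_config(seed = 2, partner_r2_targets = 1.5)),
               "\\(0, 1\\]")
})

test_that("scenario files parse back cleanly and truth covers every SNP once", {
  sc <- local_scenario(seed = 31)
  ref <- read_fasta(sc$files$fasta)
  expect_equal(ref$sequence, sc$reference$sequence)
  vcf <- read_vcf_snps(sc$files$vcf)  # no warning: all rows biallelic SNPs
  expect_equal(vcf$skipped, 0L)
  expect_equal(vcf$variants$id, sc$variants$id)
  expect_equal(vcf$panel$haplotypes, sc$panel$haplotypes)
  motifs <- read_meme_motifs(sc$files$meme)
  expect_length(motifs, length(sc$motifs))
  beds <- scenario_beds(sc)
  peaks <- purrr::map_dfr(names(beds), ~read_peaks_bed(beds[[.x]], .x))
  expect_equal(nrow(peaks), nrow(sc$peaks))

  # every VCF SNP appears in the truth table exactly once
  expect_setequal(sc$truth$snp_id, vcf$variants$id)
  expect_equal(anyDuplicated(sc$truth$snp_id), 0L)
  # every planted disrupting SNP lies inside a same-TF peak
  dis <- sc$truth |> dplyr::filter(class == "disrupting")
  for (i in seq_len(nrow(dis))) {
    expect_true(snp_in_peak(tibble::tibble(chrom = dis$chrom[i], pos = dis$pos[i]),
                            sc$peaks, dis$tf_name[i]))
  }
  # REF alleles match the reference sequence at each position
  for (i in seq_len(nrow(sc$truth))) {
    expect_equal(substr(ref$sequence, sc$truth$pos[i], sc$truth$pos[i]),
                 sc$truth$ref[i])
  }
})

test_that("scenario generation is byte-identical for a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_regulatory_scenario(scenario_config(seed = 12), dir = d1)
  generate_regulatory_scenario(scenario_config(seed = 12), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("a scenario without disrupting SNPs yields zero disrupting calls", {
  sc <- local_scenario(seed = 41, n_disrupting_snps = 0L)
  cfgs <- scan_config()
  motifs <- compile_motifs(sc$motifs, cfgs)
  calls <- purrr::map_dfr(seq_len(nrow(sc$variants)), function(i) {
    v <- sc$variants[i, ]
    classify_disruption(scan_alleles(v, sc$reference, motifs, cfgs), v, sc$peaks)
  })
  expect_equal(sum(calls$verdict == "disrupting"), 0L)
})

test_that("noiseless eQTL generation recovers beta exactly; nulls are uniform", {
  cfg0 <- scenario_config(seed = 51, noise_sd = 1e-9, n_eqtl_datasets = 1L,
                          n_consensus_snps = 1L, n_specific_snps = 0L)
  gen <- generate_eqtl_expression(cfg0, "snpA")
  res <- eqtl_scan(gen$datasets[[1]],
                   pairs = tibble::tibble(snp_id = "snpA", gene_id = "GENE_snpA"))
  expect_equal(res$beta, 1, tolerance = 1e-3)

  cfg1 <- scenario_config(seed = 52, n_eqtl_datasets = 1L,
                          n_consensus_snps = 0L, n_specific_snps = 0L,
                          n_samples_per_dataset = 100L)
  nulls <- paste0("null", 1:400)
  gen1 <- generate_eqtl_expression(cfg1, nulls)
  res1 <- eqtl_scan(gen1$datasets[[1]],
                    pairs = tibble::tibble(snp_id = nulls,
                                           gene_id = paste0("GENE_", nulls)))
  ks <- suppressWarnings(ks.test(res1$p_value, "punif"))$statistic
  expect_lt(unname(ks), 0.07)
})

test_that("ASE count generation validates depth and imbalance", {
  expect_error(generate_ase_counts(scenario_config(seed = 1, ase_depth = 5L),
                                   "s", TRUE), ">= 10")
  expect_error(generate_ase_counts(
    scenario_config(seed = 1, ase_imbalance_delta = 0.6), "s", TRUE),
    "inside \\(0, 1\\)")
  cfg <- scenario_config(seed = 61)
  counts <- generate_ase_counts(cfg, c("a", "b"), c(TRUE, FALSE))
  expect_equal(counts$count_allele1 + counts$count_allele2, rep(100L, 2))
})
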