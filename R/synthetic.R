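# Seeded generator of a complete synthetic study with known ground truth:
# reference sequence, sharp TF motifs, ChIP-Seq-like peaks, a SNP panel with
# LD structure around index SNPs, planted TF-binding-disrupting SNPs and
# decoy classes, multi-dataset expression with planted eQTL effects,
# case/control shifts, and binomial allelic read counts. Every generator is
# a pure function of its configuration and seed.

#' Synthetic scenario configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 6-bp motifs at ~1.86 bits/column (consensus probability 0.985), so
#' a planted consensus match is significant at the exact-null p < 0.001
#' threshold while the single-base-broken alternate allele is not; LD
#' partners at target r-squared values spanning the 0.6 extraction cutoff;
#' five eQTL cohorts of 200 samples with unit effect and unit noise; allelic
#' read depth 100 with an imbalance of 0.2 for ASE-positive SNPs.
#'
#' @param seed Integer seed (mandatory); all randomness derives from it.
#' @param reference_length Reference chromosome length (default 20000).
#' @param gc_content GC fraction of the reference (default 0.5, matching the
#'   uniform scan background).
#' @param n_tfs Number of TFs with motifs and peaks (default 2).
#' @param motif_width Motif width in bp (default 6).
#' @param motif_info_bits_per_column Target per-column information content
#'   (default 1.86 bits).
#' @param n_peaks_per_tf Peaks per TF, including those covering planted
#'   motifs (default 5).
#' @param n_index_snps Index SNPs for the LD stage (default 2).
#' @param partner_r2_targets Target r-squared of each LD partner per index
#'   (default c(0.9, 0.7, 0.5, 0.3), spanning the 0.6 cutoff).
#' @param n_samples_panel Diploid samples in the haplotype panel (default 500).
#' @param n_disrupting_snps Planted TF-binding-disrupting SNPs (default 4).
#' @param n_decoy_in_peak SNPs inside a peak but with no motif (default 2).
#' @param n_decoy_motif_no_peak SNPs breaking a planted motif outside any
#'   peak (default 2).
#' @param n_decoy_background Plain background SNPs (default 4).
#' @param n_eqtl_datasets eQTL cohorts (default 5).
#' @param n_samples_per_dataset Samples per cohort (default 200).
#' @param eqtl_beta Per-alt-allele expression effect (default 1.0).
#' @param noise_sd Expression noise SD in the eQTL cohorts (default 1.0).
#' @param n_consensus_snps SNPs whose gene effect is shared by all cohorts
#'   (default 3).
#' @param n_specific_snps SNPs with an effect in exactly one cohort
#'   (default 2).
#' @param ase_depth Total allelic read depth per SNP (default 100).
#' @param ase_imbalance_delta Allele-1 probability excess over 0.5 for
#'   ASE-positive SNPs (default 0.2).
#' @param de_shift Case-minus-control log2 expression shift of affected
#'   genes (default 0.5).
#' @param de_noise_sd Expression noise SD in the case/control cohort
#'   (default 0.2).
#' @param n_case,n_control Case/control sample sizes (default 50 each).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(seed,
                            reference_length = 20000L, gc_content = 0.5,
                            n_tfs = 2L, motif_width = 6L,
                            motif_info_bits_per_column = 1.86,
                            n_peaks_per_tf = 5L,
                            n_index_snps = 2L,
                            partner_r2_targets = c(0.9, 0.7, 0.5, 0.3),
                            n_samples_panel = 500L,
                            n_disrupting_snps = 4L, n_decoy_in_peak = 2L,
                            n_decoy_motif_no_peak = 2L, n_decoy_background = 4L,
                            n_eqtl_datasets = 5L, n_samples_per_dataset = 200L,
                            eqtl_beta = 1.0, noise_sd = 1.0,
                            n_consensus_snps = 3L, n_specific_snps = 2L,
                            ase_depth = 100L, ase_imbalance_delta = 0.2,
                            de_shift = 0.5, de_noise_sd = 0.2,
                            n_case = 50L, n_control = 50L) {
  if (missing(seed)) abort("seed is mandatory")
  if (gc_content <= 0 || gc_content >= 1) abort("gc_content must be in (0, 1)")
  if (any(partner_r2_targets <= 0 | partner_r2_targets > 1)) {
    abort("partner r2 targets must be in (0, 1]")
  }
  counts <- c(reference_length, n_tfs, motif_width, n_peaks_per_tf,
              n_index_snps, n_samples_panel, n_disrupting_snps,
              n_decoy_in_peak, n_decoy_motif_no_peak, n_decoy_background,
              n_eqtl_datasets, n_samples_per_dataset, ase_depth,
              n_case, n_control)
  if (any(counts < 0)) abort("counts must be non-negative")
  structure(as.list(environment()), class = "scenario_config")
}

tf_name_pool <- function(n) {
  pool <- c("CTCF", "REST", "TAF1", "PBX3", "SMC3", "POLR2A", "EZH2", "RAD21")
  if (n <= length(pool)) pool[seq_len(n)] else c(pool, paste0("TF", seq_len(n - length(pool))))
}

# consensus-base probability giving the requested information content
consensus_prob_for_info <- function(bits) {
  if (bits <= 0 || bits >= 2) abort("per-column information must be in (0, 2) bits")
  f <- function(q) 2 + q * log2(q) + (1 - q) * log2((1 - q) / 3) - bits
  stats::uniroot(f, c(0.2500001, 1 - 1e-9), tol = 1e-12)$root
}

#' Generate a random reference sequence
#'
#' i.i.d. bases with P(G) = P(C) = gc/2 and P(A) = P(T) = (1-gc)/2.
#'
#' @param length Sequence length (>= 100).
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed.
#' @param name Record name (default "chr1").
#' @return A one-row tibble (name, sequence), as from [read_fasta()].
#' @export
generate_reference <- function(length, gc, seed, name = "chr1") {
  if (length < 100L) abort("reference length must be >= 100")
  if (gc <= 0 || gc >= 1) abort("gc must be in (0, 1)")
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  tibble(name = name,
         sequence = paste(sample(BASES, length, replace = TRUE, prob = p),
                          collapse = ""))
}

#' Generate a sharp PWM for each TF
#'
#' Each motif has a random consensus word and per-column probability
#' `q` on the consensus base, `(1-q)/3` elsewhere, with `q` solved from the
#' configured information content.
#'
#' @param cfg A [scenario_config()].
#' @return A list of [pwm()] objects, one per TF.
#' @export
generate_motifs <- function(cfg) {
  set.seed(cfg$seed + 11L)
  q <- consensus_prob_for_info(cfg$motif_info_bits_per_column)
  tfs <- tf_name_pool(cfg$n_tfs)
  lapply(seq_len(cfg$n_tfs), function(t) {
    consensus <- sample(BASES, cfg$motif_width, replace = TRUE)
    probs <- matrix((1 - q) / 3, nrow = cfg$motif_width, ncol = 4L)
    probs[cbind(seq_len(cfg$motif_width), match(consensus, BASES))] <- q
    pwm(probs, motif_id = paste0("M_", tfs[[t]]), tf_name = tfs[[t]])
  })
}

#' Generate the LD haplotype panel around the index SNPs
#'
#' For each index SNP a haplotype vector is drawn at a MAF uniform in
#' \[0.2, 0.5\]; each partner copies the index haplotype and independently
#' resamples each entry from the marginal frequency with mixing probability
#' `m = 1 - sqrt(r2_target)`, so the expected allele correlation is
#' `sqrt(r2_target)`. Realized r-squared is recorded from [r_squared()].
#'
#' @param cfg A [scenario_config()] (`n_samples_panel` must be >= 50).
#' @return A list: `panel` (a [haplotype_panel()] of index + partner
#'   columns) and `truth` (tibble: snp_id, index_id, target_r2,
#'   realized_r2; index SNPs have target and realized 1).
#' @export
generate_ld_panel <- function(cfg) {
  if (cfg$n_samples_panel < 50L) abort("n_samples_panel must be >= 50")
  if (any(cfg$partner_r2_targets <= 0 | cfg$partner_r2_targets > 1)) {
    abort("partner r2 targets must be in (0, 1]")
  }
  set.seed(cfg$seed + 23L)
  n_hap <- 2L * cfg$n_samples_panel
  cols <- list(); ids <- character(); truth <- list()
  for (i in seq_len(cfg$n_index_snps)) {
    maf <- stats::runif(1, 0.2, 0.5)
    repeat {
      idx_hap <- stats::rbinom(n_hap, 1L, maf)
      if (any(idx_hap == 1L) && any(idx_hap == 0L)) break
    }
    idx_id <- paste0("rsIDX", i)
    cols <- c(cols, list(idx_hap)); ids <- c(ids, idx_id)
    truth <- c(truth, list(tibble(snp_id = idx_id, index_id = idx_id,
                                  target_r2 = 1, realized_r2 = 1)))
    for (j in seq_along(cfg$partner_r2_targets)) {
      r2t <- cfg$partner_r2_targets[[j]]
      m <- 1 - sqrt(r2t)
      repeat {
        resample <- stats::runif(n_hap) < m
        part <- idx_hap
        part[resample] <- stats::rbinom(sum(resample), 1L, maf)
        if (any(part == 1L) && any(part == 0L)) break
      }
      pid <- paste0("rsP", i, "_", j)
      cols <- c(cols, list(part)); ids <- c(ids, pid)
      truth <- c(truth, list(tibble(
        snp_id = pid, index_id = idx_id, target_r2 = r2t,
        realized_r2 = r_squared(idx_hap, part)$r2)))
    }
  }
  panel <- haplotype_panel(do.call(cbind, cols), ids,
                           paste0("S", seq_len(cfg$n_samples_panel)))
  list(panel = panel, truth = bind_rows(truth))
}

#' Diploid dosages from a haplotype panel
#'
#' Sums the two haplotypes of each sample.
#'
#' @param panel A [haplotype_panel()].
#' @return Variants-by-samples integer matrix of alternate-allele counts.
#' @export
panel_dosages <- function(panel) {
  n_samp <- length(panel$sample_ids)
  odd <- seq(1L, 2L * n_samp, by = 2L)
  d <- t(panel$haplotypes[odd, , drop = FALSE] +
           panel$haplotypes[odd + 1L, , drop = FALSE])
  rownames(d) <- panel$variant_ids
  colnames(d) <- panel$sample_ids
  d
}

#' Generate the full regulatory scenario with ground truth
#'
#' Builds the reference, motifs, peaks and SNP panel; plants disrupting
#' SNPs at the maximum-information motif column with the alternate allele
#' chosen to minimize the column probability; places the decoy classes
#' (in-peak-no-motif, motif-no-peak, background) and the LD block; and
#' writes every input file the pipeline consumes plus a machine-readable
#' truth table. All files parse back through the package's own readers.
#'
#' @param cfg A [scenario_config()].
#' @param dir Output directory (created if absent).
#' @return A list with `files` (named paths: fasta, vcf, meme, index_snps,
#'   truth, config and one BED per TF), `truth` (per-SNP tibble), and the
#'   in-memory objects (`reference`, `motifs`, `peaks`, `variants`,
#'   `panel`, `ld_truth`).
#' @export
generate_regulatory_scenario <- function(cfg, dir = tempfile("scenario")) {
  stopifnot(inherits(cfg, "scenario_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tfs <- tf_name_pool(cfg$n_tfs)
  motifs <- generate_motifs(cfg)
  names(motifs) <- vapply(motifs, function(m) m$tf_name, character(1))

  # locus layout: disjoint windows, one per planted entity
  peak_half <- 100L
  stride <- 500L
  n_ld_snps <- cfg$n_index_snps * (1L + length(cfg$partner_r2_targets))
  n_extra_peaks <- max(0L, cfg$n_tfs * cfg$n_peaks_per_tf -
                         (cfg$n_disrupting_snps + cfg$n_decoy_in_peak))
  n_loci <- cfg$n_disrupting_snps + cfg$n_decoy_in_peak +
    cfg$n_decoy_motif_no_peak + cfg$n_decoy_background + n_ld_snps + n_extra_peaks
  if (n_loci * stride + stride > cfg$reference_length) {
    abort(sprintf("scenario demands %d loci but the reference (%d bp) fits %d",
                  n_loci, cfg$reference_length,
                  (cfg$reference_length - stride) %/% stride))
  }
  centers <- stride %/% 2L + stride * (seq_len(n_loci) - 1L) + stride %/% 4L

  set.seed(cfg$seed + 37L)
  reference <- generate_reference(cfg$reference_length, cfg$gc_content,
                                  seed = cfg$seed + 41L)
  seq_str <- reference$sequence

  plant_motif <- function(center, motif) {
    # embed the consensus; returns (snp_pos, ref, alt) for the broken column
    cons <- seq_chars(pwm_consensus(motif))
    w <- motif$width
    start <- center  # 1-based start of the embedded site
    substr(seq_str, start, start + w - 1L) <<- paste(cons, collapse = "")
    col <- which.max(pwm_information(motif))
    snp_pos <- start + col - 1L
    ref <- cons[[col]]
    alt_candidates <- BASES[BASES != ref]
    alt <- alt_candidates[[which.min(motif$probs[col, alt_candidates])]]
    list(pos = snp_pos, ref = ref, alt = alt)
  }

  li <- 0L
  next_center <- function() { li <<- li + 1L; centers[[li]] }
  peaks <- list(); snps <- list()
  tf_cycle <- function(k) tfs[[((k - 1L) %% cfg$n_tfs) + 1L]]

  for (k in seq_len(cfg$n_disrupting_snps)) {
    tf <- tf_cycle(k); c0 <- next_center()
    pl <- plant_motif(c0, motifs[[tf]])
    peaks <- c(peaks, list(tibble(chrom = "chr1", start = c0 - peak_half,
                                  end = c0 + motifs[[tf]]$width + peak_half,
                                  tf_name = tf)))
    snps <- c(snps, list(tibble(id = paste0("rsDIS", k), pos = pl$pos,
                                ref = pl$ref, alt = pl$alt,
                                class = "disrupting", tf_name = tf)))
  }
  for (k in seq_len(cfg$n_decoy_in_peak)) {
    tf <- tf_cycle(k); c0 <- next_center()
    peaks <- c(peaks, list(tibble(chrom = "chr1", start = c0 - peak_half,
                                  end = c0 + peak_half, tf_name = tf)))
    ref <- substr(seq_str, c0, c0)
    alt <- sample(BASES[BASES != ref], 1L)
    snps <- c(snps, list(tibble(id = paste0("rsPK", k), pos = c0, ref = ref,
                                alt = alt, class = "in_peak_no_motif",
                                tf_name = tf)))
  }
  for (k in seq_len(cfg$n_decoy_motif_no_peak)) {
    tf <- tf_cycle(k); c0 <- next_center()
    pl <- plant_motif(c0, motifs[[tf]])
    snps <- c(snps, list(tibble(id = paste0("rsMNP", k), pos = pl$pos,
                                ref = pl$ref, alt = pl$alt,
                                class = "motif_no_peak", tf_name = tf)))
  }
  for (k in seq_len(cfg$n_decoy_background)) {
    c0 <- next_center()
    ref <- substr(seq_str, c0, c0)
    alt <- sample(BASES[BASES != ref], 1L)
    snps <- c(snps, list(tibble(id = paste0("rsBG", k), pos = c0, ref = ref,
                                alt = alt, class = "background",
                                tf_name = NA_character_)))
  }
  for (k in seq_len(n_extra_peaks)) {
    tf <- tf_cycle(k); c0 <- next_center()
    peaks <- c(peaks, list(tibble(chrom = "chr1", start = c0 - peak_half,
                                  end = c0 + peak_half, tf_name = tf)))
  }

  ld <- generate_ld_panel(cfg)
  ld_pos <- integer(0)
  for (k in seq_along(ld$panel$variant_ids)) {
    c0 <- next_center()
    ld_pos <- c(ld_pos, c0)
  }
  ld_snps <- tibble(id = ld$panel$variant_ids, pos = ld_pos,
                    ref = substr(rep(seq_str, length(ld_pos)), ld_pos, ld_pos),
                    class = "background", tf_name = NA_character_) |>
    rowwise() |>
    mutate(alt = sample(BASES[BASES != .data$ref], 1L)) |>
    ungroup() |>
    select("id", "pos", "ref", "alt", "class", "tf_name")

  snp_tab <- bind_rows(bind_rows(snps), ld_snps) |>
    mutate(chrom = "chr1", .before = 1L) |>
    arrange(.data$pos)

  # haplotypes: LD block from the panel generator, all other SNPs independent
  set.seed(cfg$seed + 53L)
  n_hap <- 2L * cfg$n_samples_panel
  hap_cols <- lapply(seq_len(nrow(snp_tab)), function(j) {
    id <- snp_tab$id[[j]]
    m <- match(id, ld$panel$variant_ids)
    if (!is.na(m)) return(ld$panel$haplotypes[, m])
    repeat {
      h <- stats::rbinom(n_hap, 1L, 0.3)
      if (any(h == 1L) && any(h == 0L)) return(h)
    }
  })
  panel <- haplotype_panel(do.call(cbind, hap_cols), snp_tab$id,
                           paste0("S", seq_len(cfg$n_samples_panel)))

  reference$sequence <- seq_str
  peaks <- bind_rows(peaks)
  truth <- snp_tab |>
    select("id", "chrom", "pos", "ref", "alt", "class", "tf_name") |>
    rename(snp_id = "id") |>
    left_join(ld$truth, by = "snp_id")

  # write every input file the pipeline consumes
  files <- list(
    fasta = file.path(dir, "reference.fa"),
    vcf = file.path(dir, "panel.vcf"),
    meme = file.path(dir, "motifs.meme"),
    index_snps = file.path(dir, "index_snps.txt"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.tsv")
  )
  write_fasta(reference, files$fasta)
  write_vcf_snps(snp_tab |> select("chrom", "pos", "id", "ref", "alt"),
                 panel, files$vcf)
  write_meme_motifs(motifs, files$meme)
  writeLines(paste0("rsIDX", seq_len(cfg$n_index_snps)), files$index_snps)
  readr::write_tsv(truth, files$truth)
  cfg_flat <- tibble(
    field = names(unclass(cfg)),
    value = vapply(unclass(cfg), function(v) paste(format(v), collapse = ","),
                   character(1))
  )
  readr::write_tsv(cfg_flat, files$config)
  for (tf in tfs) {
    p <- file.path(dir, paste0("peaks_", tf, ".bed"))
    write_peaks_bed(peaks |> filter(.data$tf_name == tf), p)
    files[[paste0("bed_", tf)]] <- p
  }

  list(files = files, truth = truth, reference = reference, motifs = motifs,
       peaks = peaks, variants = snp_tab, panel = panel, ld_truth = ld$truth,
       dir = dir)
}

#' Generate multi-dataset expression with planted eQTL effects
#'
#' One gene per SNP; expression is `beta * dosage + Normal(0, noise_sd)`.
#' The first `n_consensus_snps` SNPs share their effect across all
#' datasets, the next `n_specific_snps` have the effect in exactly one
#' dataset (assigned round-robin), and the rest are null everywhere.
#'
#' @param cfg A [scenario_config()].
#' @param snp_ids SNPs to plant effects for.
#' @param dosages Optional variants-by-samples dosage matrix reused for all
#'   datasets; by default each dataset draws its own cohort at MAF 0.3.
#' @return A list: `datasets` (list of [expression_dataset()]) and `truth`
#'   (tibble: snp_id, gene_id, dataset_id, beta).
#' @export
generate_eqtl_expression <- function(cfg, snp_ids, dosages = NULL) {
  set.seed(cfg$seed + 67L)
  n_snps <- length(snp_ids)
  if (cfg$n_consensus_snps + cfg$n_specific_snps > n_snps) {
    abort("more consensus + specific SNPs than SNPs supplied")
  }
  gene_ids <- paste0("GENE_", snp_ids)
  ds_ids <- paste0("DS", seq_len(cfg$n_eqtl_datasets))
  beta_mat <- matrix(0, nrow = n_snps, ncol = cfg$n_eqtl_datasets,
                     dimnames = list(snp_ids, ds_ids))
  if (cfg$n_consensus_snps > 0L) beta_mat[seq_len(cfg$n_consensus_snps), ] <- cfg$eqtl_beta
  if (cfg$n_specific_snps > 0L) {
    for (j in seq_len(cfg$n_specific_snps)) {
      ds <- ((j - 1L) %% cfg$n_eqtl_datasets) + 1L
      beta_mat[cfg$n_consensus_snps + j, ds] <- cfg$eqtl_beta
    }
  }
  datasets <- lapply(seq_len(cfg$n_eqtl_datasets), function(d) {
    n <- cfg$n_samples_per_dataset
    g <- if (is.null(dosages)) {
      matrix(stats::rbinom(n_snps * n, 2L, 0.3), nrow = n_snps,
             dimnames = list(snp_ids, paste0(ds_ids[[d]], "_S", seq_len(n))))
    } else {
      dosages[snp_ids, , drop = FALSE]
    }
    y <- beta_mat[, d] * g +
      matrix(stats::rnorm(n_snps * ncol(g), sd = cfg$noise_sd), nrow = n_snps)
    rownames(y) <- gene_ids; colnames(y) <- colnames(g)
    expression_dataset(ds_ids[[d]], y, dosages = g)
  })
  truth <- tidyr::expand_grid(snp_id = snp_ids, dataset_id = ds_ids) |>
    mutate(gene_id = paste0("GENE_", .data$snp_id),
           beta = beta_mat[cbind(.data$snp_id, .data$dataset_id)]) |>
    select("snp_id", "gene_id", "dataset_id", "beta")
  list(datasets = datasets, truth = truth)
}

#' Generate a case/control expression cohort with planted shifts
#'
#' @param cfg A [scenario_config()].
#' @param gene_ids Genes to simulate.
#' @param shifted_genes Subset of `gene_ids` whose case mean is raised by
#'   `cfg$de_shift` on the log2 scale.
#' @return A list: `dataset` (an [expression_dataset()] with labels) and
#'   `truth` (tibble: gene_id, shift).
#' @export
generate_case_control_expression <- function(cfg, gene_ids, shifted_genes) {
  set.seed(cfg$seed + 79L)
  if (any(!shifted_genes %in% gene_ids)) abort("shifted_genes must be a subset of gene_ids")
  n <- cfg$n_case + cfg$n_control
  labels <- c(rep("case", cfg$n_case), rep("control", cfg$n_control))
  shift <- ifelse(gene_ids %in% shifted_genes, cfg$de_shift, 0)
  y <- matrix(stats::rnorm(length(gene_ids) * n, sd = cfg$de_noise_sd),
              nrow = length(gene_ids),
              dimnames = list(gene_ids, paste0("CC_S", seq_len(n))))
  y[, labels == "case"] <- y[, labels == "case"] + shift
  list(dataset = expression_dataset("CASECTRL", y, group_labels = labels),
       truth = tibble(gene_id = gene_ids, shift = shift))
}

#' Generate binomial allelic read counts
#'
#' ASE-positive SNPs draw `count_allele1 ~ Binomial(depth, 0.5 + delta)`,
#' others `Binomial(depth, 0.5)`.
#'
#' @param cfg A [scenario_config()] (`ase_depth` must be >= 10 and
#'   `0.5 + ase_imbalance_delta` inside (0, 1)).
#' @param snp_ids SNP identifiers.
#' @param ase_flags Logical vector: which SNPs truly show ASE.
#' @return Tibble: snp_id, tissue, count_allele1, count_allele2, true_ase.
#' @export
generate_ase_counts <- function(cfg, snp_ids, ase_flags) {
  if (cfg$ase_depth < 10L) abort("ase_depth must be >= 10")
  p1 <- 0.5 + cfg$ase_imbalance_delta
  if (p1 <= 0 || p1 >= 1) abort("0.5 + ase_imbalance_delta must be inside (0, 1)")
  if (length(ase_flags) != length(snp_ids)) abort("one ASE flag per SNP required")
  set.seed(cfg$seed + 97L)
  a1 <- stats::rbinom(length(snp_ids), cfg$ase_depth, ifelse(ase_flags, p1, 0.5))
  tibble(snp_id = snp_ids, tissue = "brain",
         count_allele1 = a1, count_allele2 = cfg$ase_depth - a1,
         true_ase = ase_flags)
}
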