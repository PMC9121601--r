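# Readers and writers for the standard formats the pipeline touches:
# FASTA, VCF (GT field only), BED3+, MEME minimal motif format, TSV tables.
# All readers return tibbles (or tibble-carrying lists); coordinates follow
# the format standards (VCF 1-based, BED 0-based half-open).

#' Read a FASTA file into a tibble of sequence records
#'
#' Sequences are uppercased and validated against the alphabet
#' \{A, C, G, T, N\}; any other residue is an error naming the offending
#' record and position.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) abort("no records in FASTA file")
  seqs <- toupper(as.character(set))
  nm <- sub("\\s.*$", "", names(set))
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0L) {
      abort(sprintf("illegal residue '%s' at position %d of record '%s'",
                    substr(seqs[[i]], bad, bad), bad, nm[[i]]))
    }
    if (nchar(seqs[[i]]) < 1L) abort(sprintf("empty sequence in record '%s'", nm[[i]]))
  }
  tibble(name = unname(nm), sequence = unname(seqs))
}

#' Write sequence records to a FASTA file
#'
#' @param records Tibble with columns `name`, `sequence`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- records$name
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read biallelic SNPs and phased haplotypes from a VCF
#'
#' Parses the fixed columns and the GT subfield of a VCF into a variant table
#' plus a haplotype panel for LD computation. Multi-allelic rows and indels
#' are skipped with one summary warning and counted. Phased genotypes
#' (`"|"` separator) are required unless `assume_phased = TRUE`, in which
#' case `/`-separated genotypes are accepted and treated as phased.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param assume_phased Accept unphased `/` genotype separators as-is.
#' @return A list with elements
#'   `variants` (tibble: chrom, pos, id, ref, alt),
#'   `panel` (a [haplotype_panel()]), and
#'   `skipped` (count of multi-allelic/indel rows dropped).
#' @export
read_vcf_snps <- function(path, assume_phased = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  # v@fix stays a matrix even for a single record (getFIX drops dimensions)
  fix <- as.data.frame(v@fix[, 1:7, drop = FALSE], stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) abort("no variant records in VCF")
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L) abort("VCF has no genotype (GT) columns")

  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% BASES & fix$ALT %in% BASES & !grepl(",", fix$ALT, fixed = TRUE)
  skipped <- sum(!snp)
  if (skipped > 0L) {
    warn(sprintf("skipped %d non-biallelic-SNP record(s) (indel or multi-allelic)", skipped))
  }
  if (!any(snp)) abort("no biallelic SNP records in VCF")

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) abort("VCF records carry no GT field")
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = nrow(fix),
                                   dimnames = list(NULL, colnames(gt_raw)[-1]))
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  sample_ids <- colnames(gt)

  if (any(is.na(gt))) abort("missing GT calls are not supported")
  if (any(grepl("/", gt, fixed = TRUE)) && !assume_phased) {
    abort("unphased genotypes ('/') found; phased haplotypes are required (set assume_phased = TRUE to override)")
  }
  alle <- strsplit(gsub("/", "|", gt, fixed = TRUE), "|", fixed = TRUE)
  if (any(lengths(alle) != 2L)) abort("GT fields must be diploid (two alleles)")
  am <- matrix(as.integer(unlist(alle)), nrow = 2L)
  if (any(is.na(am)) || any(!am %in% c(0L, 1L))) {
    abort("GT alleles must be 0 or 1 for biallelic SNPs")
  }
  # am columns run over (variant, sample) in column-major order of gt
  n_var <- nrow(gt); n_samp <- ncol(gt)
  haps <- matrix(0L, nrow = 2L * n_samp, ncol = n_var)
  for (s in seq_len(n_samp)) {
    block <- am[, ((s - 1L) * n_var + 1L):(s * n_var), drop = FALSE]
    haps[2L * s - 1L, ] <- block[1L, ]
    haps[2L * s, ] <- block[2L, ]
  }

  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS), id = ids,
    ref = fix$REF, alt = fix$ALT
  )
  panel <- haplotype_panel(haps, variants$id, sample_ids)
  list(variants = variants, panel = panel, skipped = skipped)
}

#' Write biallelic SNPs with phased genotypes to a VCF file
#'
#' @param variants Tibble with columns chrom, pos, id, ref, alt.
#' @param panel A [haplotype_panel()] whose variant order matches `variants`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_snps <- function(variants, panel, path) {
  stopifnot(nrow(variants) == length(panel$variant_ids))
  n_samp <- length(panel$sample_ids)
  gt_cols <- vapply(seq_len(nrow(variants)), function(j) {
    a1 <- panel$haplotypes[seq(1L, 2L * n_samp, by = 2L), j]
    a2 <- panel$haplotypes[seq(2L, 2L * n_samp, by = 2L), j]
    paste(paste0(a1, "|", a2), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            panel$sample_ids), collapse = "\t")
  )
  body <- paste(variants$chrom, variants$pos, variants$id, variants$ref,
                variants$alt, ".", ".", ".", "GT", gt_cols, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read ChIP-Seq peaks from a BED3+ file
#'
#' Coordinates are kept 0-based half-open as in the BED standard. Extra
#' columns beyond the third are ignored, except that column 4 supplies the
#' TF name when `tf_name` is empty.
#'
#' @param path Path to a BED file (>= 3 tab-separated columns, no header).
#' @param tf_name TF to tag every peak with; when `""`, column 4 is used.
#' @return Tibble with columns chrom, start, end, tf_name.
#' @export
read_peaks_bed <- function(path, tf_name = "") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(tibble(chrom = character(), start = integer(),
                                         end = integer(), tf_name = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    abort(sprintf("line %d has fewer than 3 tab-separated columns",
                  which(lengths(fields) < 3L)[1]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (any(is.na(start)) || any(is.na(end))) abort("non-numeric BED coordinates")
  bad <- which(start >= end | start < 0L)
  if (length(bad) > 0L) {
    abort(sprintf("line %d: empty or inverted interval [%d, %d)", bad[1], start[bad[1]], end[bad[1]]))
  }
  name <- if (nzchar(tf_name)) {
    rep(tf_name, length(lines))
  } else {
    vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "", character(1))
  }
  tibble(chrom = chrom, start = start, end = end, tf_name = name)
}

#' Write peaks to a BED file
#'
#' @param peaks Tibble with columns chrom, start, end, tf_name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  writeLines(paste(peaks$chrom, peaks$start, peaks$end, peaks$tf_name, sep = "\t"), path)
  invisible(path)
}

#' Read motifs from a MEME minimal-format file
#'
#' Accepts the minimal motif exchange format: a `MEME version` line, an
#' `ALPHABET= ACGT` line, and one `MOTIF` block per motif with a
#' `letter-probability matrix` header followed by `w` rows of four
#' probabilities (A C G T order). Rows are renormalized to sum to one;
#' a row sum deviating from 1 by more than 0.01 is an error.
#'
#' @param path Path to a MEME minimal file.
#' @return A list of [pwm()] objects, in file order.
#' @export
read_meme_motifs <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path))
  if (!any(grepl("^MEME version", lines))) abort("not a MEME minimal file (missing 'MEME version')")
  alph <- grep("^ALPHABET=", lines, value = TRUE)
  if (length(alph) > 0L && !grepl("ACGT", gsub(" ", "", alph[1]), fixed = TRUE)) {
    abort(sprintf("unsupported alphabet: %s", alph[1]))
  }
  starts <- grep("^MOTIF ", lines)
  if (length(starts) == 0L) abort("no MOTIF blocks found")
  out <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:(bounds[k + 1L] - 1L)]
    toks <- strsplit(sub("^MOTIF ", "", block[1]), "\\s+")[[1]]
    motif_id <- toks[1]
    tf <- if (length(toks) >= 2L) toks[2] else toks[1]
    hdr <- grep("^letter-probability matrix", block)
    if (length(hdr) == 0L) abort(sprintf("motif '%s' lacks a letter-probability matrix", motif_id))
    w_decl <- suppressWarnings(as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", block[hdr[1]])))
    rows <- block[(hdr[1] + 1L):length(block)]
    num <- grepl("^[0-9.eE+ \t-]+$", rows) & nzchar(rows)
    if (any(!num)) {
      first_non <- which(!num)[1]
      rows <- if (first_non > 1L) rows[1:(first_non - 1L)] else character()
    }
    if (length(rows) == 0L) abort(sprintf("motif '%s' has an empty probability matrix", motif_id))
    mat <- do.call(rbind, lapply(rows, function(r) as.numeric(strsplit(r, "\\s+")[[1]])))
    if (ncol(mat) != 4L) abort(sprintf("motif '%s': expected 4 probability columns", motif_id))
    if (!is.na(w_decl) && nrow(mat) != w_decl) {
      abort(sprintf("motif '%s': declared w=%d but %d rows found", motif_id, w_decl, nrow(mat)))
    }
    sums <- rowSums(mat)
    if (any(abs(sums - 1) > 0.01)) {
      abort(sprintf("motif '%s': probability row %d sums to %.4f (not 1)",
                    motif_id, which(abs(sums - 1) > 0.01)[1], sums[which(abs(sums - 1) > 0.01)[1]]))
    }
    mat <- mat / sums
    out[[k]] <- pwm(mat, motif_id = motif_id, tf_name = tf)
  }
  out
}

#' Write motifs to a MEME minimal-format file
#'
#' @param pwms A list of [pwm()] objects.
#' @param path Output path.
#' @param background Background frequencies written to the header.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(pwms, path, background = uniform_background()) {
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f",
            background$freq[["A"]], background$freq[["C"]],
            background$freq[["G"]], background$freq[["T"]]), ""
  )
  for (p in pwms) {
    lines <- c(lines,
      sprintf("MOTIF %s %s", p$motif_id, p$tf_name),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", p$width),
      apply(p$probs, 1L, function(r) sprintf("%.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}
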