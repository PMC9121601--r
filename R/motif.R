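# Position weight matrices, background-normalized log-odds scoring, and the
# exact null distribution of match scores. The null distribution is built by
# per-column convolution over an integer score lattice (scores rounded at a
# granularity of epsilon bits); both scanning and the table use the same
# rounded integer matrix, so reported p-values are exact for that matrix.

#' Background base composition
#'
#' Zero-order background model used for log-odds scoring and the exact score
#' null distribution. All four frequencies must be positive and sum to one.
#'
#' @param A,C,G,T Base frequencies.
#' @return An object of class `background`.
#' @export
background <- function(A = 0.25, C = 0.25, G = 0.25, T = 0.25) {
  freq <- c(A = A, C = C, G = G, T = T)
  if (any(freq <= 0)) abort("background frequencies must be positive")
  if (abs(sum(freq) - 1) > 1e-9) abort("background frequencies must sum to 1")
  structure(list(freq = freq), class = "background")
}

#' @rdname background
#' @export
uniform_background <- function() background()

#' Construct a position weight matrix
#'
#' @param probs `w x 4` matrix of per-position base probabilities, columns in
#'   A, C, G, T order; each row must sum to 1 (tolerance 1e-6).
#' @param motif_id Motif identifier.
#' @param tf_name Transcription factor the motif belongs to.
#' @return An object of class `pwm`.
#' @export
pwm <- function(probs, motif_id, tf_name = motif_id) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) abort("PWM must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 1L) abort("PWM width must be >= 1")
  if (any(probs < 0)) abort("PWM probabilities must be non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) abort("each PWM row must sum to 1")
  colnames(probs) <- BASES
  rownames(probs) <- NULL
  structure(
    list(motif_id = as.character(motif_id), tf_name = as.character(tf_name),
         width = nrow(probs), probs = probs),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm %s (TF %s), width %d, consensus %s>\n",
              x$motif_id, x$tf_name, x$width, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base per position)
#' @param x A [pwm()].
#' @return A character string of length `x$width`.
#' @export
pwm_consensus <- function(x) {
  paste(BASES[apply(x$probs, 1L, which.max)], collapse = "")
}

#' Per-column information content of a PWM, in bits
#' @param x A [pwm()].
#' @return Numeric vector of length `x$width` (2 - entropy per column).
#' @export
pwm_information <- function(x) {
  apply(x$probs, 1L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Reverse-complement a PWM
#' @param x A [pwm()].
#' @return A [pwm()] for the opposite strand.
#' @export
pwm_revcomp <- function(x) {
  pwm(x$probs[rev(seq_len(x$width)), rev(seq_len(4L)), drop = FALSE],
      motif_id = x$motif_id, tf_name = x$tf_name)
}

#' Scan configuration
#'
#' Parameters of the allele-specific motif scan: window half-width around the
#' SNP, the match p-value threshold, strand handling, whether a hit must
#' cover the SNP base to count, the pseudocount fraction mixed into PWM
#' probabilities before log-odds, the integer-lattice granularity of the
#' exact null distribution (bits), and the background model.
#'
#' @param flank Bases of reference sequence on each side of the SNP (default
#'   20, giving 41-mer windows).
#' @param p_threshold Match p-value cutoff, strict (default 0.001).
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @param require_snp_overlap Only hits whose span covers the SNP base are
#'   candidates (default TRUE): a hit not covering the SNP cannot differ
#'   between alleles.
#' @param pseudocount_fraction Fraction `pc` of the background added to PWM
#'   probabilities: score = log2((p + pc*bg) / ((1+pc)*bg)) (default 0.01).
#' @param epsilon Score granularity in bits for the integer lattice
#'   (default 1e-4).
#' @param bg A [background()].
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(flank = 20L, p_threshold = 0.001, both_strands = TRUE,
                        require_snp_overlap = TRUE, pseudocount_fraction = 0.01,
                        epsilon = 1e-4, bg = uniform_background()) {
  if (!(p_threshold > 0 && p_threshold < 1)) abort("p_threshold must be in (0, 1)")
  if (epsilon <= 0) abort("epsilon must be positive")
  if (pseudocount_fraction < 0) abort("pseudocount_fraction must be >= 0")
  if (flank < 1L) abort("flank must be >= 1")
  structure(
    list(flank = as.integer(flank), p_threshold = p_threshold,
         both_strands = isTRUE(both_strands),
         require_snp_overlap = isTRUE(require_snp_overlap),
         pseudocount_fraction = pseudocount_fraction, epsilon = epsilon,
         bg = bg),
    class = "scan_config"
  )
}

#' Build a PWM from aligned binding-site sequences
#'
#' Per-position probabilities are `(count + pseudocount) / (n_sites + 4 *
#' pseudocount)`. Sites must be equal-length strings over A/C/G/T.
#'
#' @param sites Character vector of aligned site sequences (>= 1).
#' @param pseudocount Added to each base count (default 0).
#' @param motif_id,tf_name Identifiers for the resulting [pwm()].
#' @return A [pwm()].
#' @export
#' @examples
#' build_pwm_from_sites(c("ACG", "ACG"))
build_pwm_from_sites <- function(sites, pseudocount = 0, motif_id = "derived",
                                 tf_name = motif_id) {
  if (length(sites) == 0L) abort("no sites given")
  sites <- toupper(sites)
  w <- unique(nchar(sites))
  if (length(w) != 1L) abort("sites have ragged lengths")
  if (w < 1L) abort("sites must be non-empty")
  mat <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  if (any(!mat %in% BASES)) abort("sites contain characters outside {A,C,G,T}")
  counts <- vapply(seq_len(w), function(i) {
    tabulate(factor(mat[, i], levels = BASES), nbins = 4L)
  }, numeric(4))
  probs <- t(counts + pseudocount) / (length(sites) + 4 * pseudocount)
  pwm(probs, motif_id = motif_id, tf_name = tf_name)
}

#' Log-odds scoring matrix of a PWM under a background model
#'
#' Scores in bits: `score(i, a) = log2((p(i,a) + pc * bg(a)) / ((1 + pc) *
#' bg(a)))` with pseudocount fraction `pc` from the configuration. The matrix
#' is also rounded onto the integer lattice `round(score / epsilon)` used for
#' both scanning and the exact p-value table. With `pc = 0` a zero
#' probability gives an infinite score, which is rejected.
#'
#' @param x A [pwm()].
#' @param cfg A [scan_config()].
#' @return An object of class `log_odds_matrix` with elements `scores`
#'   (bits), `int_scores`, `epsilon`, `motif_id`, `tf_name`, `width`.
#' @export
log_odds <- function(x, cfg = scan_config()) {
  stopifnot(inherits(x, "pwm"))
  bg <- rep(cfg$bg$freq, each = x$width)
  dim(bg) <- dim(x$probs)
  pc <- cfg$pseudocount_fraction
  scores <- log2((x$probs + pc * bg) / ((1 + pc) * bg))
  if (any(!is.finite(scores))) {
    abort("infinite log-odds score (zero probability with pseudocount_fraction = 0)")
  }
  int_scores <- round(scores / cfg$epsilon)
  storage.mode(int_scores) <- "integer"
  structure(
    list(motif_id = x$motif_id, tf_name = x$tf_name, width = x$width,
         scores = scores, int_scores = int_scores, epsilon = cfg$epsilon,
         pseudocount_fraction = pc, bg = cfg$bg),
    class = "log_odds_matrix"
  )
}

#' Exact null distribution of integer match scores
#'
#' Builds the exact distribution of the total integer score of a random
#' background word by convolving the per-column score distributions over the
#' integer lattice, and derives the upper-tail p-value `P(S >= s)`. Exact for
#' the rounded integer matrix: scanning uses the same matrix, so scan
#' p-values carry no further approximation.
#'
#' @param lom A [log_odds_matrix()].
#' @param cfg A [scan_config()] (supplies the background).
#' @param max_lattice Guard on lattice size; widen `epsilon` if exceeded.
#' @return An object of class `score_pvalue_table`.
#' @export
score_pvalue_table <- function(lom, cfg = scan_config(), max_lattice = 5e7) {
  stopifnot(inherits(lom, "log_odds_matrix"))
  ints <- lom$int_scores
  mins <- apply(ints, 1L, min)
  maxs <- apply(ints, 1L, max)
  lo <- sum(mins); hi <- sum(maxs)
  width_lattice <- hi - lo + 1
  if (width_lattice > max_lattice) {
    abort(sprintf(
      "score lattice of %g entries exceeds the guard; use a larger epsilon",
      width_lattice))
  }
  bgf <- cfg$bg$freq
  # probability vector over offsets (score - lo); start with the point mass 0
  prob <- 1
  cur_lo <- 0L
  for (i in seq_len(lom$width)) {
    row <- ints[i, ]
    new_lo <- cur_lo + min(row)
    new_len <- length(prob) + (max(row) - min(row))
    acc <- numeric(new_len)
    for (a in seq_len(4L)) {
      off <- row[[a]] - min(row)
      acc[(1L + off):(length(prob) + off)] <-
        acc[(1L + off):(length(prob) + off)] + prob * bgf[[a]]
    }
    prob <- acc
    cur_lo <- new_lo
  }
  pvals <- rev(cumsum(rev(prob)))
  structure(
    list(motif_id = lom$motif_id, epsilon = lom$epsilon,
         min_score = cur_lo, max_score = cur_lo + length(prob) - 1L,
         probs = prob, pvalues = pvals),
    class = "score_pvalue_table"
  )
}

#' @export
print.score_pvalue_table <- function(x, ...) {
  cat(sprintf("<score_pvalue_table %s: integer scores [%d, %d], epsilon %g bits>\n",
              x$motif_id, x$min_score, x$max_score, x$epsilon))
  invisible(x)
}

#' Upper-tail p-value of an integer match score
#'
#' @param table A [score_pvalue_table()].
#' @param int_score Integer score(s) on the table's lattice.
#' @return `P(S >= int_score)` under the background model: 1 below the
#'   minimum achievable score, 0 above the maximum.
#' @export
score_pvalue <- function(table, int_score) {
  stopifnot(inherits(table, "score_pvalue_table"))
  idx <- int_score - table$min_score + 1
  out <- numeric(length(int_score))
  out[idx < 1] <- 1
  inside <- idx >= 1 & idx <= length(table$pvalues)
  out[inside] <- table$pvalues[idx[inside]]
  out[idx > length(table$pvalues)] <- 0
  out
}

#' Ungapped similarity between two PWMs
#'
#' Maximum mean column-wise Pearson correlation of probability vectors over
#' all ungapped offsets with at least `min_overlap` aligned columns, trying
#' both orientations of `pwm_b` (as given and reverse-complemented).
#' Zero-variance columns contribute 0 to the mean. Ties are broken by
#' smallest absolute offset, then by the `+` orientation.
#'
#' @param pwm_a,pwm_b [pwm()] objects.
#' @param min_overlap Minimum aligned columns (default 5).
#' @return One-row tibble: similarity, offset, orientation.
#' @export
motif_similarity <- function(pwm_a, pwm_b, min_overlap = 5L) {
  stopifnot(inherits(pwm_a, "pwm"), inherits(pwm_b, "pwm"))
  if (min_overlap > pwm_a$width || min_overlap > pwm_b$width) {
    abort("min_overlap exceeds a motif width")
  }
  col_cor <- function(u, v) {
    if (stats::sd(u) == 0 || stats::sd(v) == 0) return(0)
    stats::cor(u, v)
  }
  score_orientation <- function(mb) {
    offsets <- seq.int(-(pwm_b$width - min_overlap), pwm_a$width - min_overlap)
    vapply(offsets, function(off) {
      ia <- max(1L, 1L + off):min(pwm_a$width, pwm_b$width + off)
      ib <- ia - off
      mean(vapply(seq_along(ia), function(k) {
        col_cor(pwm_a$probs[ia[k], ], mb[ib[k], ])
      }, numeric(1)))
    }, numeric(1)) |> stats::setNames(offsets)
  }
  cand <- bind_rows(
    tibble(orientation = "+", offset = as.integer(names(score_orientation(pwm_b$probs))),
           similarity = unname(score_orientation(pwm_b$probs))),
    tibble(orientation = "-", offset = as.integer(names(score_orientation(pwm_revcomp(pwm_b)$probs))),
           similarity = unname(score_orientation(pwm_revcomp(pwm_b)$probs)))
  )
  best <- cand |>
    arrange(desc(.data$similarity), abs(.data$offset), .data$orientation) |>
    slice(1L)
  tibble(similarity = best$similarity, offset = best$offset,
         orientation = best$orientation)
}
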