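# Independent oracles used across the suite. These deliberately share no
# code with the package: brute-force tabulation, exhaustive enumeration and
# hand-written step-up formulas.

# r2 from an explicit 2x2 haplotype table
oracle_r2 <- function(a, b) {
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  n <- n11 + n10 + n01 + n00
  pa <- (n11 + n10) / n; pb <- (n11 + n01) / n; pab <- n11 / n
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# BH step-up by the textbook definition: sort ascending, q_(i) =
# min_{j >= i} p_(j) * m / j, capped at 1, back in input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive minimum-likelihood two-sided binomial tail
oracle_min_lik_binom <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# exact score distribution by enumerating all 4^w words
oracle_score_table <- function(int_scores, bg_freq) {
  w <- nrow(int_scores)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- apply(words, 1, function(letters) {
    sum(int_scores[cbind(seq_len(w), letters)])
  })
  probs <- apply(words, 1, function(letters) prod(bg_freq[letters]))
  list(scores = scores, probs = probs)
}

oracle_score_pvalue <- function(enum, s) {
  sum(enum$probs[enum$scores >= s])
}

random_pwm <- function(width, sharp = FALSE) {
  probs <- t(vapply(seq_len(width), function(i) {
    x <- if (sharp) {
      v <- rep(0.02, 4); v[sample(4, 1)] <- 0.94; v
    } else {
      stats::rgamma(4, 1)
    }
    x / sum(x)
  }, numeric(4)))
  pwm(probs, motif_id = paste0("RND", width))
}

local_scenario <- function(seed = 1, ..., env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  generate_regulatory_scenario(scenario_config(seed = seed, ...), dir = dir)
}

scenario_beds <- function(sc) {
  idx <- grep("^bed_", names(sc$files))
  stats::setNames(unlist(sc$files[idx]),
                  sub("^bed_", "", names(sc$files)[idx]))
}
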