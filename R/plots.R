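# ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_line
#'   geom_hline labs theme_minimal scale_x_continuous facet_wrap
NULL

#' Plot per-column information content of a PWM
#'
#' @param object A [pwm()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pwm <- function(object, ...) {
  df <- tibble(position = seq_len(object$width),
               bits = pwm_information(object))
  ggplot(df, aes(x = .data$position, y = .data$bits)) +
    geom_col(fill = "steelblue") +
    scale_x_continuous(breaks = df$position) +
    labs(title = sprintf("%s (%s): information content", object$motif_id, object$tf_name),
         x = "motif position", y = "bits") +
    theme_minimal()
}

#' Plot per-TF disruption counts
#'
#' Bar chart of the number of SNPs disrupting each TF's binding.
#'
#' @param object A [summarize_disruptions()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.disruption_summary <- function(object, ...) {
  ggplot(object$per_tf,
         aes(x = stats::reorder(.data$tf_name, -.data$n_snps), y = .data$n_snps)) +
    geom_col(fill = "firebrick") +
    labs(x = "transcription factor", y = "SNPs disrupting binding",
         title = "TF binding-disrupting SNPs per TF") +
    theme_minimal()
}

#' Plot cross-dataset eQTL consensus tallies
#'
#' @param object A [consensus_tally()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.consensus_summary <- function(object, ...) {
  ggplot(object$tally, aes(x = .data$k, y = .data$n_snps_at_least_k)) +
    geom_col(fill = "darkorange") +
    scale_x_continuous(breaks = object$tally$k) +
    labs(x = "supported in at least k datasets", y = "SNPs",
         title = "eQTL consensus across datasets") +
    theme_minimal()
}

#' Plot allele-specific score shifts of disruption calls
#'
#' Reference-allele score against alternate-allele score for every call
#' where at least one allele has a significant motif occurrence; points on
#' the axes correspond to allele-discordant (disrupting) calls.
#'
#' @param calls Tibble from [classify_disruption()].
#' @return A ggplot.
#' @export
plot_allele_scores <- function(calls) {
  df <- calls |>
    filter(.data$ref_hit | .data$alt_hit) |>
    mutate(ref_score = tidyr::replace_na(.data$ref_score, 0),
           alt_score = tidyr::replace_na(.data$alt_score, 0))
  ggplot(df, aes(x = .data$ref_score, y = .data$alt_score,
                 shape = .data$verdict)) +
    geom_point(size = 2, colour = "steelblue") +
    facet_wrap(~tf_name) +
    labs(x = "reference-allele score (bits)", y = "alternate-allele score (bits)",
         title = "Allele-specific motif scores") +
    theme_minimal()
}
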