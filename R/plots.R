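#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_hline
#'   geom_vline labs scale_x_log10 theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' @export
autoplot.qc_report <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$rule, y = .data$removed_pairs)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "removed pairs",
         title = sprintf("Read cleaning: %d of %d pairs survive",
                         object$surviving_pairs, object$input_pairs)) +
    theme_minimal()
}

#' @export
autoplot.de_table <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = (.data$rpkm1 + .data$rpkm2) / 2, y = .data$log2fold,
                colour = .data$call)) +
    geom_point(alpha = 0.6, size = 1) +
    scale_x_log10() +
    geom_hline(yintercept = c(-1, 1), linetype = "dashed",
               colour = "grey40") +
    labs(x = "mean RPKM (log scale)", y = "log2 fold change (phase2/phase1)",
         colour = "call",
         title = "Digital differential abundance") +
    theme_minimal()
}

#' @export
autoplot.enrichment_table <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(term = stats::reorder(.data$term, -.data$p_bonf))
  ggplot(d, aes(x = -log10(pmax(.data$p_bonf, 1e-300)), y = .data$term,
                size = .data$m, colour = .data$significant)) +
    geom_point() +
    geom_vline(xintercept = -log10(attr(object, "alpha") %||% 0.05),
               linetype = "dashed", colour = "grey40") +
    facet_wrap(~direction) +
    labs(x = "-log10 Bonferroni-adjusted p", y = NULL, size = "DE members",
         title = "Term over-representation") +
    theme_minimal()
}

#' Plot match efficiency by length bin
#'
#' @param match_rates A [length_binned_match_rate()] tibble.
#' @return A ggplot object.
#' @export
plot_match_rates <- function(match_rates) {
  ggplot(match_rates, aes(x = .data$bin, y = .data$pct_matched)) +
    geom_col(fill = "darkgreen", alpha = 0.8) +
    labs(x = "sequence length (bp)", y = "% with database match",
         title = "Annotation match efficiency by length") +
    theme_minimal()
}

#' Plot assembled sequence length distributions
#'
#' @param result A `pipeline_result` with assembly outputs.
#' @return A ggplot object.
#' @export
plot_length_distributions <- function(result) {
  d <- bind_rows(
    tibble(stage = "contigs", phase = "1", length = result$asm1$contigs$length),
    tibble(stage = "contigs", phase = "2", length = result$asm2$contigs$length),
    tibble(stage = "unigenes", phase = "1", length = result$asm1$unigenes$length),
    tibble(stage = "unigenes", phase = "2", length = result$asm2$unigenes$length),
    tibble(stage = "distinct", phase = "all",
           length = result$clusters$all_unigenes$length)
  )
  ggplot(d, aes(x = .data$length, fill = .data$phase)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
    facet_wrap(~stage, scales = "free_y") +
    labs(x = "length (bp)", y = "sequences",
         title = "Assembly length distributions") +
    theme_minimal()
}
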