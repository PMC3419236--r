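#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.qc_report <- function(x, ...) {
  tibble(
    rule = c("chastity", "adaptor", "ambiguous", "lowq"),
    removed_pairs = c(x$removed_chastity, x$removed_adaptor,
                      x$removed_ambiguous, x$removed_lowq)
  ) |>
    mutate(fraction = .data$removed_pairs / max(1, x$input_pairs))
}

#' @export
glance.qc_report <- function(x, ...) {
  tibble(
    input_pairs = x$input_pairs,
    surviving_pairs = x$surviving_pairs,
    survival_rate = x$surviving_pairs / max(1, x$input_pairs)
  )
}

#' @export
tidy.de_table <- function(x, ...) {
  as_tibble(x) |>
    select("unigene", "length", "x", "y", "rpkm1", "rpkm2",
           "fold", "log2fold", "p", "fdr", "call", "unique_to")
}

#' @export
glance.de_table <- function(x, ...) {
  tibble(
    n_unigenes = nrow(x),
    n1 = attr(x, "n1"), n2 = attr(x, "n2"),
    n_differential = sum(x$call != "NS"),
    up_phase1 = sum(x$call == "UP1"),
    up_phase2 = sum(x$call == "UP2"),
    unique_phase1 = sum(x$call == "UP1" & x$unique_to == "1"),
    unique_phase2 = sum(x$call == "UP2" & x$unique_to == "2")
  )
}

#' @export
tidy.enrichment_table <- function(x, ...) as_tibble(x)

#' @export
glance.enrichment_table <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha") %||% NA_real_,
    min_p_bonf = if (nrow(x) > 0) min(x$p_bonf) else NA_real_
  )
}

#' @export
tidy.cluster_set <- function(x, ...) x$clusters

#' @export
glance.cluster_set <- function(x, ...) {
  tibble(
    n_input = nrow(x$clusters),
    n_clusters = nrow(x$all_unigenes),
    n_both_phases = sum(x$all_unigenes$phase_origin == "both")
  )
}
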