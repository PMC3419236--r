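#' Hypergeometric over-representation p-value
#'
#' For `N` annotated unigenes of which `n` are differentially abundant, and
#' a term annotated to `M` unigenes of which `m` are differentially
#' abundant, returns the right tail
#' `P(X >= m) = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M, n-i) / C(N,n)` for
#' `X ~ Hypergeometric(N, M, n)`. Terms with impossible `i` contribute
#' zero. `m = 0` gives exactly 1.
#'
#' @param N Total annotated unigenes.
#' @param n Differentially abundant unigenes within `N`.
#' @param M Unigenes annotated to the term.
#' @param m Differentially abundant unigenes within `M`.
#' @return The raw p-value (vectorized over the arguments).
#' @export
hypergeom_p <- function(N, n, M, m) {
  ok <- m >= 0 & m <= pmin(n, M) & n <= N & M <= N & n >= 0 & M >= 0
  if (!all(ok)) {
    abort("invalid contingency: need 0 <= m <= min(n, M), n <= N, M <= N")
  }
  phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Term-enrichment testing over differentially abundant unigene sets
#'
#' Runs one hypergeometric over-representation test per (term, direction)
#' for every term with at least one differentially abundant member in that
#' direction. The background `N` is the set of annotated unigenes (those
#' appearing in `assignments`); `n` is the annotated portion of the
#' direction's differential set. Raw p-values receive a Bonferroni
#' correction whose divisor is, by default, the number of tests performed
#' within the direction (set `correction = "global"` to divide by the total
#' across both directions); significance means `p_bonf < alpha` strictly.
#'
#' @param de A `de_table` from [call_differential()], or any tibble with
#'   `unigene` and `call` (`"UP1"`/`"UP2"`/`"NS"`) columns.
#' @param assignments Tibble with `gene` and `term` columns (e.g. slim-mapped
#'   GO assignments or KO assignments) restricted to one ontology scope.
#' @param alpha Familywise significance threshold (default 0.05).
#' @param correction `"per_direction"` (default) or `"global"` Bonferroni
#'   divisor scope.
#' @return Tibble of class `enrichment_table`, sorted by adjusted p-value:
#'   `term`, `direction`, `N`, `n`, `M`, `m`, `p_raw`, `p_bonf`,
#'   `significant`.
#' @export
run_enrichment <- function(de, assignments, alpha = 0.05,
                           correction = c("per_direction", "global")) {
  correction <- match.arg(correction)
  empty <- structure(
    tibble(term = character(0), direction = character(0),
           N = integer(0), n = integer(0), M = integer(0), m = integer(0),
           p_raw = numeric(0), p_bonf = numeric(0), significant = logical(0)),
    class = c("enrichment_table", "tbl_df", "tbl", "data.frame")
  )
  annotated <- unique(assignments$gene)
  N <- length(annotated)
  de_sets <- list(
    UP1 = intersect(de$unigene[de$call == "UP1"], annotated),
    UP2 = intersect(de$unigene[de$call == "UP2"], annotated)
  )
  if (all(lengths(de_sets) == 0)) {
    warn("empty differential set: no enrichment tests performed")
    return(empty)
  }
  term_members <- split(assignments$gene, assignments$term)
  rows <- purrr::imap(de_sets, function(de_genes, dir) {
    n <- length(de_genes)
    if (n == 0) return(NULL)
    m <- vapply(term_members, function(g) length(intersect(g, de_genes)),
                integer(1))
    M <- lengths(term_members)
    keep <- m >= 1 # terms without differential members are not tested
    Mk <- unname(M[keep])
    mk <- unname(m[keep])
    tibble(
      term = names(term_members)[keep], direction = dir,
      N = N, n = n, M = Mk, m = mk,
      p_raw = hypergeom_p(N, n, Mk, mk)
    )
  })
  res <- bind_rows(rows)
  if (nrow(res) == 0) {
    warn("no term had a differential member; empty result")
    return(empty)
  }
  res <- res |>
    group_by(.data$direction) |>
    mutate(n_tests = if (correction == "per_direction") n() else nrow(res)) |>
    ungroup() |>
    mutate(
      p_bonf = pmin(1, .data$p_raw * .data$n_tests),
      significant = .data$p_bonf < alpha
    ) |>
    select(-"n_tests") |>
    arrange(.data$p_bonf, .data$p_raw, .data$term)
  structure(res, alpha = alpha, correction = correction,
            class = c("enrichment_table", class(res)))
}
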