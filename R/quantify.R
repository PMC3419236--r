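#' Count uniquely mapped reads per unigene
#'
#' Maps clean reads of each phase onto the distinct (All-unigene) sequence
#' set by exact full-length matching on either strand. A read contributes a
#' count only when it matches exactly one unigene; reads matching several
#' unigenes are excluded from the counts and reported in a multimap tally.
#' The library totals `N1`/`N2` are the sums of unique counts, i.e. the
#' total number of clean reads mapped to All-unigenes in each sample.
#'
#' @param reads1,reads2 Clean read tibbles for phase 1 and phase 2.
#' @param unigenes Distinct-sequence tibble (`id`, `sequence`, `length`),
#'   e.g. `cluster_unigenes(...)$all_unigenes`.
#' @return Tibble of class `count_table`: `unigene`, `length`, `x`, `y`,
#'   with attributes `n1`, `n2` (mapped-unique totals) and `multimap`
#'   (per-phase multi-matching read tally).
#' @export
count_table <- function(reads1, reads2, unigenes) {
  assert_that(nrow(unigenes) > 0, "empty unigene index")
  per_phase <- function(reads) {
    reads <- filter(reads, !grepl("N", .data$bases, fixed = TRUE))
    hits <- map_exact(reads, unigenes) |>
      distinct(.data$id, .data$mate, .data$ref)
    per_read <- count(hits, .data$id, .data$mate, name = "n_refs")
    multi <- sum(per_read$n_refs > 1)
    uniq <- hits |>
      inner_join(filter(per_read, .data$n_refs == 1L),
                 by = c("id", "mate"))
    counts <- count(uniq, .data$ref, name = "n")
    list(counts = counts, multimap = multi, total = sum(counts$n))
  }
  p1 <- per_phase(reads1)
  p2 <- per_phase(reads2)
  out <- unigenes |>
    select("id", "length") |>
    left_join(rename(p1$counts, x = "n"), by = c(id = "ref")) |>
    left_join(rename(p2$counts, y = "n"), by = c(id = "ref")) |>
    mutate(x = dplyr::coalesce(.data$x, 0L), y = dplyr::coalesce(.data$y, 0L)) |>
    rename(unigene = "id")
  structure(
    out,
    n1 = p1$total, n2 = p2$total,
    multimap = c(phase1 = p1$multimap, phase2 = p2$multimap),
    class = c("count_table", class(out))
  )
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = 1e9 * c / (n * l)` for `c` reads on a transcript of length `l` bp
#' in a library with `n` mapped reads.
#'
#' @param c Read count(s) on the transcript.
#' @param n Library total of mapped reads (> 0).
#' @param l Transcript length in bp (> 0).
#' @return Numeric RPKM value(s).
#' @export
rpkm <- function(c, n, l) {
  assert_that(all(n > 0), "library total n must be > 0")
  assert_that(all(l > 0), "transcript length l must be > 0")
  1e9 * c / (n * l)
}

#' Fold change between phases with the small-value substitution
#'
#' Computes the phase-2 over phase-1 RPKM ratio. A zero RPKM on either side
#' is replaced by 0.001 before taking the ratio, so fold changes remain
#' finite for transcripts detected in only one phase.
#'
#' @param rpkm1,rpkm2 RPKM values in phase 1 and phase 2 (>= 0).
#' @param floor Substitution value for zeros.
#' @return Tibble with columns `fold` and `log2fold`.
#' @export
fold_change <- function(rpkm1, rpkm2, floor = 0.001) {
  assert_that(all(rpkm1 >= 0) && all(rpkm2 >= 0), "RPKM values must be >= 0")
  r1 <- ifelse(rpkm1 == 0, floor, rpkm1)
  r2 <- ifelse(rpkm2 == 0, floor, rpkm2)
  tibble(fold = r2 / r1, log2fold = log2(r2 / r1))
}

#' Digital expression test for two libraries (Audic-Claverie type)
#'
#' Given `x` reads on a transcript in a library of `n1` mapped reads and `y`
#' in a library of `n2`, the conditional distribution of `y` given `x` is
#' `p(y|x) = (n2/n1)^y (x+y)! / (x! y! (1 + n2/n1)^(x+y+1))`, the classical
#' digital-expression model generalized to unequal library sizes. This is
#' exactly a negative binomial with size `x + 1` and success probability
#' `n1/(n1+n2)`, so tails are evaluated through the stable [stats::pnbinom]
#' machinery rather than term-by-term summation. The reported p-value is the
#' two-sided doubled tail `2 * min(P(Y <= y), P(Y >= y))` capped at 1;
#' one-sided tails are available via `alternative`.
#'
#' @param x,y Read counts (non-negative integers, vectorized).
#' @param n1,n2 Library totals (> 0).
#' @param alternative `"two.sided"` (default), `"less"` (P(Y <= y)) or
#'   `"greater"` (P(Y >= y)).
#' @return Numeric vector of p-values.
#' @export
digital_p <- function(x, y, n1, n2, alternative = "two.sided") {
  assert_that(all(x >= 0) && all(y >= 0), "counts must be non-negative")
  assert_that(all(n1 > 0) && all(n2 > 0), "library totals must be > 0")
  prob <- n1 / (n1 + n2)
  lower <- pnbinom(y, size = x + 1, prob = prob)
  upper <- ifelse(y == 0, 1, pnbinom(y - 1, size = x + 1, prob = prob,
                                     lower.tail = FALSE))
  switch(alternative,
    two.sided = pmin(1, 2 * pmin(lower, upper)),
    less = lower,
    greater = upper,
    abort("alternative must be 'two.sided', 'less' or 'greater'")
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment preserving the input order: the i-th smallest p-value
#' becomes `min over j >= i of p_(j) * m / j`, clipped to 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted values in the input order.
#' @export
bh_fdr <- function(p) {
  assert_that(all(p >= 0 & p <= 1, na.rm = FALSE), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Full differential-abundance calling over a count table
#'
#' Computes RPKM for both phases, the floored fold change, the digital
#' expression p-value, the BH-adjusted FDR, the differential call at the
#' inclusive thresholds (fold >= `fold_min` or <= `1/fold_min`, FDR <=
#' `fdr_max`), and the phase-uniqueness flag (a unigene is unique to a phase
#' when it has unique-mapped reads in that phase only).
#'
#' @param counts A [count_table()].
#' @param fold_min Minimum absolute fold change (default 2).
#' @param fdr_max Maximum FDR (default 0.001).
#' @return Tibble of class `de_table`, one row per unigene: counts, RPKM
#'   pair, `fold`, `log2fold`, `p`, `fdr`, `call` in `{"UP1","UP2","NS"}`,
#'   `unique_to` in `{"1","2","none"}`. Attributes `n1`, `n2`, `fold_min`,
#'   `fdr_max` are carried along.
#' @export
call_differential <- function(counts, fold_min = 2, fdr_max = 0.001) {
  n1 <- attr(counts, "n1")
  n2 <- attr(counts, "n2")
  assert_that(!is.null(n1) && !is.null(n2), "counts must come from count_table()")
  out <- counts |>
    mutate(
      rpkm1 = rpkm(.data$x, n1, .data$length),
      rpkm2 = rpkm(.data$y, n2, .data$length)
    )
  fc <- fold_change(out$rpkm1, out$rpkm2)
  out <- out |>
    mutate(
      fold = fc$fold, log2fold = fc$log2fold,
      p = digital_p(.data$x, .data$y, n1, n2),
      fdr = bh_fdr(.data$p),
      call = dplyr::case_when(
        .data$fdr <= fdr_max & .data$fold >= fold_min ~ "UP2",
        .data$fdr <= fdr_max & .data$fold <= 1 / fold_min ~ "UP1",
        .default = "NS"
      ),
      unique_to = dplyr::case_when(
        .data$x > 0 & .data$y == 0 ~ "1",
        .data$y > 0 & .data$x == 0 ~ "2",
        .default = "none"
      )
    )
  structure(
    out, n1 = n1, n2 = n2, fold_min = fold_min, fdr_max = fdr_max,
    class = c("de_table", setdiff(class(out), "count_table"))
  )
}
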