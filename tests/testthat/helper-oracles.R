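# Independent oracles used across the suite. Each recomputes a quantity by a
# route deliberately different from the package implementation.

# reverse complement without Biostrings
rc_oracle <- function(x) {
  chartr("ACGT", "TGCA", vapply(
    strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), character(1)
  ))
}

# brute-force digital-expression p-value: direct log-space summation of the
# conditional series p(y'|x) = r^y' (x+y')! / (x! y'! (1+r)^(x+y'+1))
oracle_digital_p <- function(x, y, n1, n2) {
  r <- n2 / n1
  logp <- function(yy) {
    yy * log(r) + lgamma(x + yy + 1) - lgamma(x + 1) - lgamma(yy + 1) -
      (x + yy + 1) * log1p(r)
  }
  lower <- sum(exp(logp(0:y)))
  # upper tail summed directly until the geometric decay exhausts it
  upper <- 0
  yy <- y
  repeat {
    term <- exp(logp(yy))
    upper <- upper + term
    yy <- yy + 1
    if ((yy > x + y + 10 && term < upper * 1e-18) || yy > y + 1e6) break
  }
  min(1, 2 * min(lower, upper))
}

# definitional Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  run_min <- Inf
  for (i in m:1) {
    run_min <- min(run_min, sorted[i] * m / i)
    q[i] <- min(1, run_min)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# hypergeometric right tail by explicit term summation over achievable i
oracle_hypergeom <- function(N, n, M, m) {
  i <- m:min(M, n)
  i <- i[(n - i) <= (N - M)]
  if (length(i) == 0) return(0)
  sum(exp(lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)))
}

# all-paths slim-mapping oracle: enumerate every upward path from `term`
# (the DAG is small) and take the first slim node on each path, counting the
# start itself
oracle_slim <- function(term, edges, slim) {
  parents_of <- function(t) edges$parent[edges$child == t]
  found <- character(0)
  walk <- function(t) {
    if (t %in% slim) {
      found <<- c(found, t)
      return(invisible())
    }
    for (p in parents_of(t)) walk(p)
  }
  walk(term)
  sort(unique(found))
}

# exact tail probabilities computed once with Python's fractions module
# (N, M, n, m, P(X >= m))
HYPERGEOM_EXACT <- data.frame(
  N = c(10, 60, 47, 100, 30, 60),
  M = c(5, 30, 13, 10, 7, 59),
  n = c(4, 20, 19, 10, 12, 30),
  m = c(4, 15, 7, 10, 3, 29),
  p = c(0.023809523809523808, 0.006349473145896315, 0.20355482985670892,
        5.776904234533874e-14, 0.5971706454465076, 1.0)
)

# binomial two-sided tolerance band half-width for a proportion
binom_band <- function(p, n, z = 3.5) z * sqrt(p * (1 - p) / n)

# quality-string helper: n_low bases below Q20 scattered in a read of given
# length, remainder at Q35
qual_with_low <- function(len, n_low, low_q = 10L, high_q = 35L,
                          offset = 33) {
  q <- rep(high_q, len)
  if (n_low > 0) q[seq_len(n_low)] <- low_q
  rawToChar(as.raw(q + offset))
}

# construct a paired-read tibble from parallel vectors
make_pairs <- function(bases1, bases2, qual1 = NULL, qual2 = NULL,
                       passfilter1 = TRUE, passfilter2 = TRUE,
                       ids = NULL) {
  n <- length(bases1)
  ids <- ids %||% sprintf("p%04d", seq_len(n))
  q1 <- qual1 %||% vapply(nchar(bases1), qual_with_low, character(1), n_low = 0)
  q2 <- qual2 %||% vapply(nchar(bases2), qual_with_low, character(1), n_low = 0)
  dplyr::bind_rows(
    tibble::tibble(id = ids, mate = 1L, bases = bases1, qual = q1,
                   passfilter = rep_len(passfilter1, n)),
    tibble::tibble(id = ids, mate = 2L, bases = bases2, qual = q2,
                   passfilter = rep_len(passfilter2, n))
  ) |> dplyr::arrange(id, mate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic error-free pairs for a set of segments of one transcript:
# fragments of length flen starting at the given positions
pairs_from_positions <- function(seq, starts, flen = 200L, rl = 75L,
                                 prefix = "f") {
  frag <- substring(seq, starts, starts + flen - 1L)
  make_pairs(
    substring(frag, 1L, rl),
    rc_oracle(substring(frag, flen - rl + 1L, flen)),
    ids = sprintf("%s%04d", prefix, seq_along(starts))
  )
}

random_seq <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
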