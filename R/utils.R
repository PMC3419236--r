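#' @keywords internal
#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows distinct n rename count across
#'   row_number pull if_else
#' @importFrom stats rnorm runif setNames p.adjust phyper pnbinom rmultinom
#' @importFrom utils head tail
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# reverse complement for plain character vectors (delegates to Biostrings)
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# canonical form: lexicographic min of a sequence and its reverse complement
canonical <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# round half away from zero, as printed summary tables conventionally do
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# draw random DNA of given lengths
random_dna <- function(lengths) {
  vapply(
    lengths,
    function(L) paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""),
    character(1)
  )
}

# all windows of width w from one sequence (1-based starts)
seq_windows <- function(seq, w) {
  L <- nchar(seq)
  if (L < w) return(character(0))
  starts <- seq_len(L - w + 1L)
  substring(seq, starts, starts + w - 1L)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}
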