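#' Read-cleaning configuration
#'
#' Parameters of the three-rule cleaning procedure applied to raw reads,
#' in order: (1) chastity -- reads flagged by the instrument as having failed
#' the chastity filter (threshold 0.6 over the first 25 cycles; the threshold
#' and cycle count are kept here for documentation, but the decision is read
#' from the FASTQ pass-filter flag because raw intensities are not available
#' downstream of base calling); (2) adaptor contamination or ambiguous bases
#' (any `N`); (3) low quality -- strictly more than `max_lowq_fraction` of
#' bases with Phred quality below `q_cutoff`.
#'
#' @param chastity_threshold,chastity_cycles Documented instrument-filter
#'   parameters (not recomputable from FASTQ).
#' @param adaptor_seqs Adaptor sequences screened at either read end.
#' @param adaptor_max_mismatch Mismatches tolerated in an adaptor overlap.
#' @param adaptor_min_overlap Minimum adaptor/read overlap (bp) to call
#'   contamination.
#' @param q_cutoff Phred threshold defining a low-quality base.
#' @param max_lowq_fraction Maximum tolerated fraction of low-quality bases
#'   (strictly exceeded means removal: exactly this fraction is kept).
#' @param phred_offset Quality encoding offset (33 or 64).
#'
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(chastity_threshold = 0.6,
                      chastity_cycles = 25L,
                      adaptor_seqs = "AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAG",
                      adaptor_max_mismatch = 2L,
                      adaptor_min_overlap = 10L,
                      q_cutoff = 20L,
                      max_lowq_fraction = 0.10,
                      phred_offset = 33) {
  assert_that(
    max_lowq_fraction >= 0 && max_lowq_fraction <= 1 && q_cutoff >= 0,
    "thresholds out of range"
  )
  structure(
    list(
      chastity_threshold = chastity_threshold,
      chastity_cycles = as.integer(chastity_cycles),
      adaptor_seqs = adaptor_seqs,
      adaptor_max_mismatch = as.integer(adaptor_max_mismatch),
      adaptor_min_overlap = as.integer(adaptor_min_overlap),
      q_cutoff = as.integer(q_cutoff),
      max_lowq_fraction = max_lowq_fraction,
      phred_offset = phred_offset
    ),
    class = "qc_config"
  )
}

# TRUE for reads showing an adaptor overlap at either end with at most
# max_mismatch mismatches over at least min_overlap bases. Uses partial
# end-overlap trimming with a per-overlap mismatch budget.
detect_adaptor <- function(bases, adaptor, min_overlap, max_mismatch) {
  dss <- Biostrings::DNAStringSet(bases)
  hit <- rep(FALSE, length(bases))
  for (ad in adaptor) {
    la <- nchar(ad)
    budget <- ifelse(seq_len(la) < min_overlap, -1, max_mismatch)
    # 3' end: adaptor prefix overlaps the read suffix
    tr <- Biostrings::trimLRPatterns(
      Rpattern = ad, subject = dss, max.Rmismatch = budget
    )
    hit <- hit | Biostrings::width(tr) < Biostrings::width(dss)
    # 5' end: adaptor suffix overlaps the read prefix
    tl <- Biostrings::trimLRPatterns(
      Lpattern = ad, subject = dss, max.Lmismatch = budget
    )
    hit <- hit | Biostrings::width(tl) < Biostrings::width(dss)
  }
  hit
}

#' Classify individual reads under the cleaning rules
#'
#' Applies the rules in their stated order (chastity, then adaptor/ambiguous,
#' then low quality); the first failing rule is the reported reason.
#'
#' @param reads Tibble of read records ([read_fastq()] layout).
#' @param cfg A [qc_config()].
#'
#' @return The input tibble with a `verdict` column:
#'   `"KEEP"`, `"CHASTITY"`, `"ADAPTOR"`, `"AMBIGUOUS"` or `"LOWQ"`.
#' @export
filter_reads <- function(reads, cfg = qc_config()) {
  if (any(nchar(reads$bases) != nchar(reads$qual))) {
    bad <- which(nchar(reads$bases) != nchar(reads$qual))[1]
    abort(sprintf("malformed quality string for read '%s'", reads$id[bad]))
  }
  quals <- decode_quals(reads$qual, cfg$phred_offset)
  if (any(unlist(lapply(quals, function(q) any(q < 0 | q > 60))))) {
    bad <- which(vapply(quals, function(q) any(q < 0 | q > 60), logical(1)))[1]
    abort(sprintf(
      "quality values outside [0, 60] for read '%s' (wrong phred_offset?)",
      reads$id[bad]
    ))
  }
  fail_chastity <- !reads$passfilter
  # adaptor screening cannot use reads containing N in the DNA alphabet scan;
  # those reads fail the ambiguity rule anyway
  has_n <- grepl("N", reads$bases, fixed = TRUE)
  fail_adaptor <- rep(FALSE, nrow(reads))
  clean_idx <- which(!has_n)
  if (length(clean_idx) > 0) {
    fail_adaptor[clean_idx] <- detect_adaptor(
      reads$bases[clean_idx], cfg$adaptor_seqs,
      cfg$adaptor_min_overlap, cfg$adaptor_max_mismatch
    )
  }
  frac_lowq <- vapply(
    quals, function(q) mean(q < cfg$q_cutoff), numeric(1)
  )
  fail_lowq <- frac_lowq > cfg$max_lowq_fraction # strictly more than 10%
  verdict <- dplyr::case_when(
    fail_chastity ~ "CHASTITY",
    fail_adaptor ~ "ADAPTOR",
    has_n ~ "AMBIGUOUS",
    fail_lowq ~ "LOWQ",
    .default = "KEEP"
  )
  mutate(reads, verdict = verdict)
}

#' Clean a set of read pairs and account for every removal
#'
#' Filtering is pair-aware: if either mate fails any rule, the whole pair is
#' removed (downstream scaffolding needs intact pairs). Each removed pair is
#' attributed to the highest-precedence rule failed by either mate
#' (chastity, then adaptor, then ambiguous, then low quality), so the report
#' counts satisfy the exact identity
#' `input_pairs = surviving_pairs + sum(removed_*)`.
#'
#' @param reads Tibble of read records carrying both mates (`mate` column);
#'   mates of a pair share an `id`.
#' @param cfg A [qc_config()].
#'
#' @return List of class `qc_result` with `reads` (surviving records) and
#'   `report` (a `qc_report`: one-row tibble of pair counts).
#' @export
run_qc <- function(reads, cfg = qc_config()) {
  counts <- count(reads, .data$id)
  if (any(counts$n != 2)) {
    abort("desynchronized mates: every read id must occur exactly twice")
  }
  flagged <- filter_reads(reads, cfg)
  prec <- c(CHASTITY = 1, ADAPTOR = 2, AMBIGUOUS = 3, LOWQ = 4, KEEP = 5)
  pair <- flagged |>
    group_by(.data$id) |>
    summarise(reason = names(prec)[min(prec[.data$verdict])])
  keep_ids <- pair$id[pair$reason == "KEEP"]
  report <- structure(
    tibble(
      input_pairs = nrow(pair),
      removed_chastity = sum(pair$reason == "CHASTITY"),
      removed_adaptor = sum(pair$reason == "ADAPTOR"),
      removed_ambiguous = sum(pair$reason == "AMBIGUOUS"),
      removed_lowq = sum(pair$reason == "LOWQ"),
      surviving_pairs = length(keep_ids)
    ),
    class = c("qc_report", "tbl_df", "tbl", "data.frame")
  )
  structure(
    list(reads = filter(reads, .data$id %in% keep_ids), report = report),
    class = "qc_result"
  )
}

#' Clean a pair of FASTQ files
#'
#' Thin file-level wrapper around [run_qc()].
#'
#' @param in1,in2 Input FASTQ paths (mate 1 / mate 2), record-synchronized.
#' @param out1,out2 Output FASTQ paths for surviving pairs.
#' @param cfg A [qc_config()].
#' @return The `qc_report`, invisibly returning the full `qc_result`.
#' @export
run_qc_files <- function(in1, in2, out1, out2, cfg = qc_config()) {
  r1 <- mutate(read_fastq(in1, cfg$phred_offset), mate = 1L)
  r2 <- mutate(read_fastq(in2, cfg$phred_offset), mate = 2L)
  if (nrow(r1) != nrow(r2) || any(r1$id != r2$id)) {
    abort("desynchronized mate files: ids must match record-by-record")
  }
  res <- run_qc(bind_rows(r1, r2), cfg)
  write_fastq(filter(res$reads, .data$mate == 1L), out1)
  write_fastq(filter(res$reads, .data$mate == 2L), out2)
  invisible(res)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Read-cleaning report (pairs)\n")
  cat(sprintf("  input:     %d\n", x$input_pairs))
  cat(sprintf("  chastity:  -%d\n", x$removed_chastity))
  cat(sprintf("  adaptor:   -%d\n", x$removed_adaptor))
  cat(sprintf("  ambiguous: -%d\n", x$removed_ambiguous))
  cat(sprintf("  low qual:  -%d\n", x$removed_lowq))
  cat(sprintf("  surviving: %d (%.2f%%)\n", x$surviving_pairs,
              100 * x$surviving_pairs / max(1, x$input_pairs)))
  invisible(x)
}
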