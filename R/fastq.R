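#' Read a FASTQ file into a tibble of read records
#'
#' Parses plain 4-line FASTQ records. Headers in the CASAVA-1.8 dialect
#' (`@id mate:filterflag:control:index`) are understood: the mate number and
#' the pass-filter flag (`N` = passed, `Y` = failed the instrument's chastity
#' filter) are pulled out into their own columns. Files written by other
#' software still load; `mate` defaults to `NA` and `passfilter` to `TRUE`.
#'
#' @param path Path to an uncompressed or gzip-compressed FASTQ file.
#' @param phred_offset ASCII offset of the quality encoding (33 or 64).
#'
#' @return A tibble with columns `id`, `mate`, `bases`, `qual` (raw quality
#'   string) and `passfilter`.
#' @export
read_fastq <- function(path, phred_offset = 33) {
  lines <- readr::read_lines(path)
  if (length(lines) %% 4 != 0) {
    abort(sprintf("FASTQ file '%s' does not contain complete 4-line records", path))
  }
  n <- length(lines) / 4
  hdr <- lines[seq(1, length(lines), by = 4)]
  bases <- lines[seq(2, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  bad <- which(nchar(bases) != nchar(qual))
  if (length(bad) > 0) {
    abort(sprintf(
      "FASTQ record '%s': sequence and quality strings differ in length",
      sub("^@", "", hdr[bad[1]])
    ))
  }
  id <- sub("^@", "", sub("\\s.*$", "", hdr))
  comment <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), NA_character_)
  mate <- suppressWarnings(as.integer(sub(":.*$", "", comment)))
  flag <- stringr::str_match(comment, "^[0-9]+:([YN]):")[, 2]
  passfilter <- ifelse(is.na(flag), TRUE, flag == "N")
  tibble(
    id = id, mate = mate, bases = toupper(bases), qual = qual,
    passfilter = passfilter
  )
}

#' Write read records to a FASTQ file
#'
#' Emits CASAVA-1.8 style headers `@id mate:flag:0:1`, where `flag` is `N`
#' for reads that passed the chastity filter and `Y` for reads that failed it,
#' so the pass-filter state survives a round trip through [read_fastq()].
#'
#' @param reads Tibble with columns `id`, `mate`, `bases`, `qual`, `passfilter`.
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "bases", "qual") %in% names(reads)))
  mate <- if ("mate" %in% names(reads)) reads$mate else 1L
  pf <- if ("passfilter" %in% names(reads)) reads$passfilter else TRUE
  hdr <- sprintf("@%s %d:%s:0:1", reads$id, mate, ifelse(pf, "N", "Y"))
  out <- character(4L * nrow(reads))
  out[seq(1, length(out), by = 4)] <- hdr
  out[seq(2, length(out), by = 4)] <- reads$bases
  out[seq(3, length(out), by = 4)] <- "+"
  out[seq(4, length(out), by = 4)] <- reads$qual
  readr::write_lines(out, path)
  invisible(path)
}

# decode a vector of quality strings into a list of integer Phred scores
decode_quals <- function(qual, phred_offset = 33) {
  if (!phred_offset %in% c(33, 64)) abort("phred_offset must be 33 or 64")
  lapply(qual, function(q) as.integer(charToRaw(q)) - as.integer(phred_offset))
}

# encode integer Phred scores to a quality string
encode_quals <- function(q, phred_offset = 33) {
  rawToChar(as.raw(q + phred_offset))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble with columns `id` and `sequence`, or a named character
#'   vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    seqs <- tibble(id = names(seqs), sequence = unname(seqs))
  }
  x <- Biostrings::DNAStringSet(setNames(seqs$sequence, seqs$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a tibble
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(x)), sequence = as.character(x))
}
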