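DB_PRIORITY <- c("Nr", "SwissProt", "KEGG", "COG")

#' Read a 12-column tabular homology-hit file
#'
#' The ubiquitous tab-separated alignment layout: query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, E-value, bit score.
#'
#' @param path Path to a tab-separated hit file without header.
#' @param db Database label for these hits (one of `Nr`, `SwissProt`,
#'   `KEGG`, `COG`).
#' @return Tibble with a `db` column prepended.
#' @export
read_hits <- function(path, db) {
  cols <- c("query", "subject", "identity", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE)
  mutate(x, db = db, .before = 1)
}

# longest open reading frame (maximal stop-free codon run) over six frames;
# returns the strand of the longest run, ties preferring "+" then lower frame
orf_direction <- function(seq) {
  stops <- c("TAA", "TAG", "TGA")
  best_len <- -1L
  best_strand <- "unknown"
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      sub <- substr(s, frame + 1L, nchar(s))
      nc <- floor(nchar(sub) / 3)
      if (nc == 0) next
      codons <- substring(sub, 3 * (seq_len(nc) - 1) + 1, 3 * seq_len(nc))
      is_stop <- codons %in% stops
      runs <- rle(is_stop)
      open <- runs$lengths[!runs$values]
      run_len <- if (length(open) > 0) max(open) else 0L
      if (run_len > best_len) {
        best_len <- run_len
        best_strand <- strand
      }
    }
  }
  list(direction = best_strand, orf_codons = best_len)
}

#' Select one annotation per query from homology hits
#'
#' Hits at or above the E-value cutoff are discarded (the cutoff is strict:
#' `evalue < cutoff` passes). Per query, the winning hit comes from the
#' highest-priority database holding any passing hit (Nr, then SwissProt,
#' then KEGG, then COG); within that database ties are broken by lowest
#' E-value, then highest bit score, then lexicographic subject id, which
#' makes the selection invariant to input order. Sequence direction is taken
#' from the winning hit's query coordinate order (`qstart > qend` denotes a
#' minus-frame protein hit). Queries without a passing hit fall back to the
#' longest-open-reading-frame heuristic when their sequence is supplied
#' (`source = "orf_fallback"`).
#'
#' @param hits Tibble of hits ([read_hits()] layout, several databases
#'   stacked).
#' @param cutoff E-value cutoff (default 1e-5, strict).
#' @param sequences Optional tibble (`id`, `sequence`) enabling the ORF
#'   fallback for unmatched queries.
#' @return Tibble of class `annotation_table`: `query`, `db`, `subject`,
#'   `evalue`, `bitscore`, `identity`, `direction`, `source`.
#' @export
select_annotations <- function(hits, cutoff = 1e-5, sequences = NULL) {
  unknown <- setdiff(unique(hits$db), DB_PRIORITY)
  if (length(unknown) > 0) {
    abort(sprintf("unknown database label(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  chosen <- hits |>
    filter(.data$evalue < cutoff) |>
    mutate(priority = match(.data$db, DB_PRIORITY)) |>
    arrange(.data$query, .data$priority, .data$evalue,
            -.data$bitscore, .data$subject) |>
    group_by(.data$query) |>
    dplyr::slice(1) |>
    ungroup() |>
    mutate(
      direction = if_else(.data$qend >= .data$qstart, "+", "-"),
      source = "hit"
    ) |>
    select("query", "db", "subject", "evalue", "bitscore", "identity",
           "direction", "source")
  if (!is.null(sequences)) {
    missing <- filter(sequences, !.data$id %in% chosen$query)
    if (nrow(missing) > 0) {
      orf <- purrr::map(missing$sequence, orf_direction)
      fb <- tibble(
        query = missing$id, db = NA_character_, subject = NA_character_,
        evalue = NA_real_, bitscore = NA_real_, identity = NA_real_,
        direction = vapply(orf, `[[`, character(1), "direction"),
        source = "orf_fallback"
      )
      chosen <- bind_rows(chosen, fb) |> arrange(.data$query)
    }
  }
  structure(chosen, class = c("annotation_table", class(chosen)))
}

#' Match efficiency by sequence-length bin
#'
#' Proportion of sequences holding a homology-based annotation, tallied in
#' the half-open length bins [100, 500), [500, 1000), [1000, 2000) and
#' [2000, Inf). Sequences below 100 bp fall into an `"<100"` bin and are
#' flagged with a message.
#'
#' @param lengths Tibble with `id` and `length` columns for every sequence.
#' @param annotations An [select_annotations()] result (only rows with
#'   `source == "hit"` count as matched).
#' @return Tibble: `bin`, `n`, `n_matched`, `pct_matched`.
#' @export
length_binned_match_rate <- function(lengths, annotations) {
  matched_ids <- annotations$query[annotations$source == "hit"]
  breaks <- c(100, 500, 1000, 2000, Inf)
  labels <- c("100-500", "500-1000", "1000-2000", ">2000")
  bin <- cut(lengths$length, c(-Inf, breaks), right = FALSE,
             labels = c("<100", labels))
  if (any(bin == "<100")) {
    inform(sprintf("%d sequence(s) below the 100 bp bin floor",
                   sum(bin == "<100")))
  }
  tibble(bin = bin, matched = lengths$id %in% matched_ids) |>
    group_by(.data$bin, .drop = FALSE) |>
    summarise(n = n(), n_matched = sum(.data$matched)) |>
    mutate(pct_matched = if_else(.data$n > 0, 100 * .data$n_matched / .data$n,
                                 NA_real_)) |>
    filter(!(.data$bin == "<100" & .data$n == 0))
}

#' Summarize E-value and identity classes of chosen hits
#'
#' Classes follow the conventional reporting of transcriptome annotation:
#' strong homology means `evalue < 1e-50`, moderate means
#' `1e-50 <= evalue < 1e-5`; high identity means strictly above 80%, the
#' mid class covers the rest (in practice bounded below by the weakest
#' observed hit, around 23%). Proportions are over matched queries and sum
#' to 100% within each class type.
#'
#' @param annotations An [select_annotations()] result.
#' @return Tibble: `class_type` (`evalue`/`identity`), `class`, `n`, `pct`.
#' @export
homology_class_summary <- function(annotations) {
  hits <- filter(annotations, .data$source == "hit")
  ev <- tibble(
    class_type = "evalue",
    class = if_else(hits$evalue < 1e-50, "strong", "moderate")
  )
  idc <- tibble(
    class_type = "identity",
    class = if_else(hits$identity > 80, "high", "mid")
  )
  bind_rows(ev, idc) |>
    count(.data$class_type, .data$class) |>
    group_by(.data$class_type) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    ungroup()
}
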