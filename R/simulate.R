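#' Simulation configuration for paired-end read generation
#'
#' Bundles the sequencing-model parameters used by [sim_reads()] and
#' [sim_tiling_reads()]. The defaults emulate an early-Illumina paired-end
#' cDNA library: 75 bp reads from fragments whose size was selected by gel
#' excision at 200 +/- 25 bp, modelled as Normal(200, 12.5) truncated to
#' [175, 225] so that ~95% of the mass falls inside the excision window.
#'
#' Artifact rates are per read: `adaptor_rate` replaces the 3' end of a read
#' with adaptor sequence (read-through), `n_rate` introduces at least one
#' ambiguous base, `lowq_rate` degrades strictly more than `lowq_fraction` of
#' the bases below Q20, and `fail_chastity_rate` marks the read as having
#' failed the instrument chastity filter (recorded in the FASTQ header; base
#' calls are unaffected). `error_rate` is the per-base substitution
#' probability applied to every read.
#'
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Fragment-size distribution (bp).
#' @param insert_window Hard truncation window for fragment sizes (bp).
#' @param error_rate Per-base substitution probability.
#' @param adaptor_rate,n_rate,lowq_rate,fail_chastity_rate Per-read artifact
#'   probabilities.
#' @param lowq_fraction Fraction of bases degraded below Q20 in a low-quality
#'   read (strictly exceeded, so such reads are removed by the default QC).
#' @param adaptor_seq Adaptor sequence used for read-through contamination.
#' @param phred_offset Quality-string encoding offset (33 or 64).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(read_length = 75L,
                       insert_mean = 200,
                       insert_sd = 12.5,
                       insert_window = c(175, 225),
                       error_rate = 0.001,
                       adaptor_rate = 0.01,
                       n_rate = 0.02,
                       lowq_rate = 0.02,
                       fail_chastity_rate = 0.01,
                       lowq_fraction = 0.10,
                       adaptor_seq = "AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAG",
                       phred_offset = 33) {
  rates <- c(error_rate, adaptor_rate, n_rate, lowq_rate, fail_chastity_rate)
  assert_that(all(rates >= 0 & rates <= 1), "all rates must lie in [0, 1]")
  assert_that(insert_mean > read_length, "insert_mean must exceed read_length")
  cfg <- list(
    read_length = as.integer(read_length), insert_mean = insert_mean,
    insert_sd = insert_sd, insert_window = insert_window,
    error_rate = error_rate, adaptor_rate = adaptor_rate, n_rate = n_rate,
    lowq_rate = lowq_rate, fail_chastity_rate = fail_chastity_rate,
    lowq_fraction = lowq_fraction, adaptor_seq = adaptor_seq,
    phred_offset = phred_offset
  )
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic transcriptome
#'
#' Draws `n_transcripts` random DNA sequences with lengths uniform over
#' `length_range`. A shared repeat can be requested via `repeat_spec`: one
#' random block of the stated length is inserted verbatim into the stated
#' number of transcripts, which creates the branch structure that breaks
#' de Bruijn assembly paths.
#'
#' @param n_transcripts Number of transcripts (>= 1).
#' @param length_range Two-element bp range; the minimum must be at least
#'   three read lengths so that fragments fit comfortably.
#' @param repeat_spec Optional `list(length =, copies =)` shared repeat.
#' @param seed Integer seed; the same seed reproduces the same transcriptome.
#' @param read_length Used only to validate `length_range`.
#'
#' @return Tibble of class `sim_txome` with columns `id`, `sequence`, `length`.
#' @export
sim_transcriptome <- function(n_transcripts, length_range = c(300L, 2000L),
                              repeat_spec = NULL, seed = 1L,
                              read_length = 75L) {
  assert_that(n_transcripts >= 1, "n_transcripts must be >= 1")
  assert_that(
    min(length_range) >= 3 * read_length,
    sprintf("transcript lengths must be >= %d bp (3 read lengths)", 3 * read_length)
  )
  withr::with_seed(seed, {
    lens <- if (length_range[1] == length_range[2]) {
      rep(length_range[1], n_transcripts)
    } else {
      sample(seq(length_range[1], length_range[2]), n_transcripts, replace = TRUE)
    }
    seqs <- random_dna(lens)
    if (!is.null(repeat_spec)) {
      block <- random_dna(repeat_spec$length)
      idx <- sample(n_transcripts, repeat_spec$copies, replace = FALSE)
      for (i in idx) {
        pos <- sample(nchar(seqs[i]) - repeat_spec$length, 1)
        substr(seqs[i], pos + 1, pos + repeat_spec$length) <- block
      }
      attr(seqs, "repeat_block") <- block
    }
    out <- tibble(
      id = sprintf("TX%04d", seq_len(n_transcripts)),
      sequence = as.character(seqs),
      length = nchar(seqs)
    )
    if (!is.null(repeat_spec)) {
      attr(out, "repeat_block") <- attr(seqs, "repeat_block")
      attr(out, "repeat_spec") <- repeat_spec
    }
    class(out) <- c("sim_txome", class(out))
    out
  })
}

#' Two-phase abundance profile with a known differential subset
#'
#' Assigns each transcript a positive baseline (expected read-pair weight) and
#' marks a subset as truly differential: half of the differential transcripts
#' are up-regulated in phase 2 by `fold`, the other half down-regulated by
#' `1/fold` (i.e. up in phase 1).
#'
#' @param txome A [sim_transcriptome()] tibble.
#' @param de_fraction Fraction of transcripts that are differential.
#' @param fold Fold change (>= 2) applied to differential transcripts.
#' @param baseline_range Range of baseline weights (uniform draw).
#' @param seed Integer seed.
#'
#' @return Tibble with columns `id`, `baseline`, `de`, `direction`
#'   (1, 2 or NA) and `phase2_multiplier`.
#' @export
sim_profile <- function(txome, de_fraction = 0.1, fold = 8,
                        baseline_range = c(50, 200), seed = 1L) {
  assert_that(fold >= 2, "fold must be >= 2 for differential transcripts")
  withr::with_seed(seed, {
    n <- nrow(txome)
    n_de <- round(de_fraction * n)
    de_idx <- if (n_de > 0) sample(n, n_de) else integer(0)
    direction <- rep(NA_integer_, n)
    if (n_de > 0) {
      # alternate directions so both phases gain a differential set
      direction[de_idx] <- rep(c(2L, 1L), length.out = n_de)
    }
    baseline <- runif(n, baseline_range[1], baseline_range[2])
    mult <- dplyr::case_when(
      is.na(direction) ~ 1,
      direction == 2L ~ fold,
      direction == 1L ~ 1 / fold
    )
    tibble(
      id = txome$id, baseline = baseline, de = !is.na(direction),
      direction = direction, phase2_multiplier = mult
    )
  })
}

# sample fragment lengths: truncated normal within the excision window and
# within what the transcript can accommodate
sample_fragments <- function(n, cfg, max_len) {
  lo <- max(cfg$read_length, cfg$insert_window[1])
  hi <- min(cfg$insert_window[2], max_len)
  f <- round(rnorm(n, cfg$insert_mean, cfg$insert_sd))
  pmin(pmax(f, lo), hi)
}

# inject substitution errors at a per-base rate (vectorized over reads)
inject_errors <- function(bases, rate) {
  if (rate <= 0) return(bases)
  L <- nchar(bases[1])
  n_err <- stats::rbinom(length(bases), L, rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample(L, n_err[i])
    for (p in pos) {
      old <- substr(bases[i], p, p)
      substr(bases[i], p, p) <- sample(setdiff(DNA_BASES, old), 1)
    }
  }
  bases
}

#' Simulate paired-end reads from a transcriptome under a two-phase profile
#'
#' Read pairs are drawn fragment-wise: a transcript is chosen with probability
#' proportional to `baseline` (times `phase2_multiplier` in phase 2), a
#' fragment length is drawn from the truncated insert distribution, a start is
#' uniform, and the fragment strand is random (unstranded library). Mate 1 is
#' the first `read_length` bases of the fragment; mate 2 is the reverse
#' complement of its last `read_length` bases. Artifacts (substitutions,
#' adaptor read-through, ambiguous bases, low-quality stretches, chastity
#' failures) are injected at the configured per-read rates and logged in the
#' truth table.
#'
#' @param txome A [sim_transcriptome()] tibble; every transcript must be long
#'   enough to hold the largest plausible fragment
#'   (`insert_mean + 3 * insert_sd`).
#' @param profile A [sim_profile()] tibble.
#' @param cfg A [sim_config()].
#' @param phase 1 or 2.
#' @param n_pairs Total number of read pairs to draw.
#' @param seed Integer seed.
#'
#' @return List with `reads` (tibble: `id`, `mate`, `bases`, `qual`,
#'   `passfilter`) and `truth` (tibble: one row per pair with the true origin
#'   in 0-based half-open fragment coordinates, the fragment strand, the true
#'   differential status and the artifact flags).
#' @export
sim_reads <- function(txome, profile, cfg = sim_config(), phase, n_pairs,
                      seed = 1L) {
  assert_that(phase %in% c(1, 2), "phase must be 1 or 2")
  min_len <- cfg$insert_mean + 3 * cfg$insert_sd
  if (any(txome$length < min_len)) {
    abort(sprintf(
      "transcripts shorter than insert_mean + 3*insert_sd (%.0f bp): %s",
      min_len, paste(head(txome$id[txome$length < min_len], 3), collapse = ", ")
    ))
  }
  prof <- profile[match(txome$id, profile$id), ]
  w <- prof$baseline * if (phase == 2) prof$phase2_multiplier else 1
  withr::with_seed(seed, {
    tx_idx <- sample.int(nrow(txome), n_pairs, replace = TRUE, prob = w)
    flen <- sample_fragments(n_pairs, cfg, max_len = min(txome$length))
    tx_len <- txome$length[tx_idx]
    fstart <- floor(runif(n_pairs) * (tx_len - flen + 1)) + 1L # 1-based
    strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
    frag <- substring(txome$sequence[tx_idx], fstart, fstart + flen - 1L)
    frag <- ifelse(strand == "-", revcomp(frag), frag)
    rl <- cfg$read_length
    m1 <- substring(frag, 1L, rl)
    m2 <- revcomp(substring(frag, nchar(frag) - rl + 1L, nchar(frag)))

    pair_id <- sprintf("P%d_%06d", phase, seq_len(n_pairs))
    build_mate <- function(bases, mate) {
      n <- length(bases)
      bases <- inject_errors(bases, cfg$error_rate)
      adaptor <- runif(n) < cfg$adaptor_rate
      if (any(adaptor)) {
        # read-through: fragment shorter than the read; 3' end is adaptor
        keep <- pmax(10L, rl - sample(15:40, sum(adaptor), replace = TRUE))
        ad <- substring(
          paste0(cfg$adaptor_seq, strrep("A", rl)), 1L, rl - keep
        )
        bases[adaptor] <- paste0(substring(bases[adaptor], 1L, keep), ad)
      }
      ambig <- runif(n) < cfg$n_rate
      if (any(ambig)) {
        pos <- sample.int(rl, sum(ambig), replace = TRUE)
        b <- bases[ambig]
        substr(b, pos, pos) <- strrep("N", 1)
        bases[ambig] <- b
      }
      lowq <- runif(n) < cfg$lowq_rate
      n_low_needed <- floor(cfg$lowq_fraction * rl) + 1L
      qv <- sample(30:40, n * rl, replace = TRUE) # read-major layout
      for (i in which(lowq)) {
        k <- sample(n_low_needed:min(rl, n_low_needed + 10L), 1)
        qv[(i - 1L) * rl + sample(rl, k)] <- sample(2:19, k, replace = TRUE)
      }
      big <- rawToChar(as.raw(qv + cfg$phred_offset))
      qual <- substring(big, seq(1L, n * rl, by = rl), seq(rl, n * rl, by = rl))
      chastity_fail <- runif(n) < cfg$fail_chastity_rate
      tibble(
        id = pair_id, mate = mate, bases = bases, qual = qual,
        passfilter = !chastity_fail,
        art_adaptor = adaptor, art_n = ambig, art_lowq = lowq
      )
    }
    r1 <- build_mate(m1, 1L)
    r2 <- build_mate(m2, 2L)
    reads <- bind_rows(r1, r2) |> arrange(.data$id, .data$mate)

    truth <- tibble(
      pair_id = pair_id,
      transcript = txome$id[tx_idx],
      frag_start0 = fstart - 1L,
      frag_end0 = fstart - 1L + flen,
      strand = strand,
      phase = phase,
      de = prof$de[tx_idx],
      direction = prof$direction[tx_idx]
    )
    art <- reads |>
      group_by(.data$id) |>
      summarise(
        any_adaptor = any(.data$art_adaptor), any_n = any(.data$art_n),
        any_lowq = any(.data$art_lowq), any_chastity = any(!.data$passfilter)
      )
    truth <- left_join(truth, art, by = c(pair_id = "id"))
    list(
      reads = select(reads, -dplyr::starts_with("art_")),
      truth = truth
    )
  })
}

#' Deterministic error-free tiling read pairs
#'
#' Generates pairs whose fragments start at every `step` positions along each
#' transcript (step chosen from the requested depth), with fragment length
#' fixed at `insert_mean` and no artifacts. The first and last fragment are
#' always included, so every base -- including the transcript ends -- is
#' covered and an error-free assembly can recover each transcript exactly.
#'
#' @param txome A [sim_transcriptome()] tibble.
#' @param cfg A [sim_config()]; only `read_length`, `insert_mean` and
#'   `phred_offset` are used.
#' @param depth Target per-base coverage (>= 1).
#'
#' @return Same shape as [sim_reads()].
#' @export
sim_tiling_reads <- function(txome, cfg = sim_config(), depth = 20) {
  rl <- cfg$read_length
  flen <- as.integer(cfg$insert_mean)
  step <- max(1L, as.integer(floor(2 * rl / depth)))
  rows <- purrr::pmap(
    list(txome$id, txome$sequence, txome$length),
    function(id, seq, L) {
      starts <- unique(c(seq(1L, L - flen + 1L, by = step), L - flen + 1L))
      frag <- substring(seq, starts, starts + flen - 1L)
      tibble(
        transcript = id, fstart = starts,
        m1 = substring(frag, 1L, rl),
        m2 = revcomp(substring(frag, flen - rl + 1L, flen))
      )
    }
  ) |> bind_rows()
  qual <- encode_quals(rep(40L, rl), cfg$phred_offset)
  pair_id <- sprintf("T_%06d", seq_len(nrow(rows)))
  reads <- bind_rows(
    tibble(id = pair_id, mate = 1L, bases = rows$m1, qual = qual, passfilter = TRUE),
    tibble(id = pair_id, mate = 2L, bases = rows$m2, qual = qual, passfilter = TRUE)
  ) |> arrange(.data$id, .data$mate)
  truth <- tibble(
    pair_id = pair_id, transcript = rows$transcript,
    frag_start0 = rows$fstart - 1L, frag_end0 = rows$fstart - 1L + flen,
    strand = "+", phase = NA_integer_, de = FALSE, direction = NA_integer_,
    any_adaptor = FALSE, any_n = FALSE, any_lowq = FALSE, any_chastity = FALSE
  )
  list(reads = reads, truth = truth)
}

#' Write a truth table as TSV
#'
#' Coordinates are 0-based half-open, as recorded by the simulators.
#'
#' @param truth Truth tibble from [sim_reads()] or [sim_tiling_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' Generate a random ontology fixture with a slim subset
#'
#' Builds an acyclic term DAG organised in levels: every non-root term has one
#' or two parents drawn from the level above (`is_a`, occasionally `part_of`).
#' A fraction of terms is designated as the slim subset (the root term is
#' always included so slim mapping can never come back empty), and random
#' gene-to-term assignments are drawn.
#'
#' @param n_terms Number of terms (>= 2).
#' @param depth Number of levels in the DAG.
#' @param slim_fraction Fraction of terms placed in the slim subset.
#' @param n_genes Number of genes to assign terms to.
#' @param terms_per_gene Mean number of terms per gene (Poisson, min 1).
#' @param seed Integer seed.
#'
#' @return List of class `ontology_fixture` with elements `dag` (an
#'   `ontology_dag`, see [read_obo()]), `slim` (character vector of term ids)
#'   and `assignments` (tibble `gene`, `term`).
#' @export
sim_ontology <- function(n_terms = 50, depth = 5, slim_fraction = 0.3,
                         n_genes = 0, terms_per_gene = 2, seed = 1L) {
  assert_that(n_terms >= 2, "n_terms must be >= 2")
  withr::with_seed(seed, {
    ids <- sprintf("GO:%07d", seq_len(n_terms))
    # assign levels: root at level 1, at least one term per level
    lev <- c(1L, sort(sample(2:min(depth, n_terms), n_terms - 1L, replace = TRUE)))
    edges <- purrr::map(which(lev > 1), function(i) {
      cand <- which(lev < lev[i])
      np <- min(length(cand), sample(1:2, 1))
      parents <- sample(cand, np)
      tibble(
        child = ids[i], parent = ids[parents],
        rel = sample(c("is_a", "part_of"), np, replace = TRUE, prob = c(0.85, 0.15))
      )
    }) |> bind_rows()
    dag <- new_ontology_dag(ids, edges)
    n_slim <- max(1L, round(slim_fraction * n_terms))
    slim <- union(ids[1], sample(ids, n_slim))
    assignments <- NULL
    if (n_genes > 0) {
      k <- pmax(1L, stats::rpois(n_genes, terms_per_gene))
      assignments <- tibble(
        gene = rep(sprintf("UN%05d", seq_len(n_genes)), k),
        term = unlist(lapply(k, function(m) sample(ids, min(m, n_terms))))
      ) |> distinct()
    }
    structure(
      list(dag = dag, slim = slim, assignments = assignments),
      class = "ontology_fixture"
    )
  })
}

#' Random term assignments for a set of genes
#'
#' @param genes Character vector of gene/unigene ids.
#' @param terms Character vector of ontology term ids to draw from.
#' @param terms_per_gene Mean assigned terms per gene (Poisson, min 1).
#' @param seed Integer seed.
#' @return Tibble with `gene` and `term`, one row per distinct pair.
#' @export
sim_assignments <- function(genes, terms, terms_per_gene = 2, seed = 1L) {
  withr::with_seed(seed, {
    k <- pmax(1L, stats::rpois(length(genes), terms_per_gene))
    tibble(
      gene = rep(genes, k),
      term = unlist(lapply(k, function(m) sample(terms, min(m, length(terms)))))
    ) |> distinct()
  })
}

#' Generate a synthetic homology-hit table
#'
#' Produces 12-column-style tabular hits for a random subset of queries, with
#' longer sequences more likely to be matched (mirroring how match efficiency
#' grows with length in real transcriptome annotation). E-values span the
#' strong (<1e-50) and moderate ([1e-50, 1e-5)) homology classes; identities
#' span 23-100%.
#'
#' @param unigenes Tibble with `id` and `length` columns.
#' @param databases Database labels to draw hits from.
#' @param base_rate Match probability for the shortest sequences; the rate
#'   approaches 1 for sequences beyond ~2 kb.
#' @param seed Integer seed.
#'
#' @return Tibble in the layout of [read_hits()] with a `db` column.
#' @export
sim_hits <- function(unigenes, databases = c("Nr", "SwissProt", "KEGG", "COG"),
                     base_rate = 0.45, seed = 1L) {
  withr::with_seed(seed, {
    p_match <- pmin(0.99, base_rate + (1 - base_rate) * pmin(unigenes$length, 2500) / 2500)
    matched <- runif(nrow(unigenes)) < p_match
    idx <- which(matched)
    rows <- purrr::map(idx, function(i) {
      ndb <- sample(seq_along(databases), 1)
      dbs <- sample(databases, ndb)
      log10e <- -runif(ndb, 5.001, 80)
      minus <- runif(1) < 0.5
      alen <- sample(50:200, ndb, replace = TRUE)
      tibble(
        db = dbs,
        query = unigenes$id[i],
        subject = sprintf("%s_%05d", tolower(dbs), sample(99999, ndb)),
        identity = runif(ndb, 23, 100),
        length = alen,
        mismatch = sample(0:10, ndb, replace = TRUE),
        gapopen = 0L,
        qstart = if (minus) 3L * alen + 10L else 10L,
        qend = if (minus) 10L else 3L * alen + 10L,
        sstart = 1L, send = alen,
        evalue = 10^log10e,
        bitscore = round(-log10e * 2 + runif(ndb, 40, 60), 1)
      )
    })
    bind_rows(rows)
  })
}
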