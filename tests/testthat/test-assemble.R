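# small helper: noiseless tiling pairs for arbitrary transcript tibbles
tiling <- function(tx, depth = 20) {
  sim_tiling_reads(tx, sim_config(), depth = depth)$reads
}

test_that("k-mer accounting matches hand enumeration", {
  # repeat-bearing read: 5 k-mer instances, ACGTA occurring twice
  g <- build_graph("ACGTACGTA", k = 5)
  expect_equal(g$n_instances, 5)

  # repeat-free read: linear path, one contig equal to the read
  read <- "ACGGTCATT"
  g2 <- build_graph(read, k = 5)
  expect_equal(g2$n_instances, 5)
  expect_equal(length(g2$nodes), 5)
  ctg <- extract_contigs(g2, assembly_config(k = 5, min_contig_len = 5))
  expect_equal(nrow(ctg), 1)
  expect_true(ctg$sequence %in% c(read, rc_oracle(read)))
})

test_that("a read and its reverse complement build the identical graph", {
  read <- random_seq(60, seed = 21)
  g1 <- build_graph(read, k = 25)
  g2 <- build_graph(rc_oracle(read), k = 25)
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$counts, g2$counts)
})

test_that("reads with no shared overlap form disconnected components", {
  r1 <- random_seq(60, seed = 22)
  r2 <- random_seq(60, seed = 23)
  ctg <- extract_contigs(build_graph(c(r1, r2), k = 25),
                         assembly_config(min_contig_len = 30))
  expect_equal(nrow(ctg), 2)
})

test_that("k must be odd and smaller than the read length", {
  expect_error(build_graph("ACGTACGTA", k = 9), "smaller than the read")
  expect_error(build_graph("ACGTACGTAACC", k = 6), "odd")
  expect_equal(nrow(extract_contigs(build_graph(character(0), 25),
                                    assembly_config())), 0)
})

test_that("noiseless tiling reads recover a repeat-free transcript exactly", {
  tx <- sim_transcriptome(1, c(900, 900), seed = 24)
  ctg <- extract_contigs(build_graph(tiling(tx)$bases, 25), assembly_config())
  expect_equal(nrow(ctg), 1)
  expect_true(ctg$sequence %in% c(tx$sequence, rc_oracle(tx$sequence)))
})

test_that("contigs terminate at branches created by a shared repeat", {
  withr::with_seed(25, {
    seg <- function(n) random_seq(n)
    block <- seg(100)
    t1 <- paste0(seg(300), block, seg(300))
    t2 <- paste0(seg(300), block, seg(300))
  })
  tx <- tibble::tibble(id = c("T1", "T2"), sequence = c(t1, t2),
                       length = nchar(c(t1, t2)))
  class(tx) <- c("sim_txome", class(tx))
  ctg <- extract_contigs(build_graph(tiling(tx)$bases, 25),
                         assembly_config(min_contig_len = 30))
  # unambiguous paths: two left flanks, two right flanks, one shared block
  expect_equal(nrow(ctg), 5)
  # no invented sequence, and no contig spans a branch point into two sources
  in_t1 <- vapply(ctg$sequence, function(s)
    grepl(s, t1, fixed = TRUE) || grepl(rc_oracle(s), t1, fixed = TRUE),
    logical(1))
  in_t2 <- vapply(ctg$sequence, function(s)
    grepl(s, t2, fixed = TRUE) || grepl(rc_oracle(s), t2, fixed = TRUE),
    logical(1))
  expect_true(all(in_t1 | in_t2))
  # the shared-block contig occurs in both transcripts
  expect_equal(sum(in_t1 & in_t2), 1)
})

test_that("every contig k-mer occurs among the input reads", {
  tx <- sim_transcriptome(3, c(400, 700), seed = 26)
  reads <- tiling(tx, depth = 12)$bases
  ctg <- extract_contigs(build_graph(reads, 25), assembly_config())
  read_kmers <- unique(unlist(lapply(reads, function(r) {
    s <- substring(r, 1:(nchar(r) - 24), 25:nchar(r))
    pmin(s, rc_oracle(s))
  })))
  for (s in ctg$sequence) {
    km <- substring(s, 1:(nchar(s) - 24), 25:nchar(s))
    expect_true(all(pmin(km, rc_oracle(km)) %in% read_kmers))
  }
})

test_that("raising thresholds is monotone in contig and scaffold counts", {
  tx <- sim_transcriptome(4, c(400, 800), seed = 27)
  prof <- sim_profile(tx, de_fraction = 0, seed = 27)
  cfg0 <- sim_config(error_rate = 0.005, adaptor_rate = 0, n_rate = 0,
                     lowq_rate = 0, fail_chastity_rate = 0)
  reads <- sim_reads(tx, prof, cfg0, phase = 1, n_pairs = 1500, seed = 28)$reads
  g <- build_graph(reads$bases, 25)
  n_by_len <- vapply(c(50, 100, 200, 400), function(ml) {
    nrow(extract_contigs(g, assembly_config(min_contig_len = ml)))
  }, numeric(1))
  expect_true(all(diff(n_by_len) <= 0))

  ctg <- extract_contigs(g, assembly_config(min_contig_len = 100))
  n_scaf <- vapply(c(1, 3, 10, 50), function(mpl) {
    sc <- scaffold_contigs(ctg, reads,
                           assembly_config(min_pair_links = mpl))
    nrow(sc$scaffolds)
  }, numeric(1))
  expect_true(all(diff(n_scaf) <= 0))
})

# shared fixture for the scaffolding and gap-filling tests: a 900 bp
# transcript whose positions 401-430 are uncovered by the contig-building
# reads, so assembly yields a left contig [1,400] and a right contig
# [431,900]; fragments of length 200 starting in [306,326] span the gap
scaffold_fixture <- function(seed = 29) {
  tx_seq <- random_seq(900, seed = seed)
  left <- pairs_from_positions(tx_seq, seq(1, 201, by = 5), prefix = "L")
  right <- pairs_from_positions(tx_seq, seq(431, 701, by = 5), prefix = "R")
  ctg <- extract_contigs(build_graph(c(left$bases, right$bases), 25),
                         assembly_config())
  span <- pairs_from_positions(tx_seq, seq(306, 326, by = 2), prefix = "S")
  list(tx_seq = tx_seq, left = left, right = right, ctg = ctg, span = span)
}

test_that("spanning pairs scaffold two contigs with the oracle gap length", {
  fx <- scaffold_fixture()
  expect_equal(nrow(fx$ctg), 2)
  expect_equal(sort(fx$ctg$length), c(400, 470))
  sc <- scaffold_contigs(fx$ctg, fx$span, assembly_config(),
                         insert_mean = 200)
  expect_equal(nrow(sc$scaffolds), 1)
  expect_equal(nrow(sc$unscaffolded), 0)
  # truth-derived oracle: the uncovered interspace is exactly 30 bp, and the
  # fragment length equals insert_mean, so the estimate is exact
  gaps <- sc$scaffolds$members[[1]]$gap_after
  expect_equal(gaps[!is.na(gaps)], 30L)
  expect_equal(stringr::str_count(sc$scaffolds$sequence, "N"), 30)

  # no spanning pairs: contigs pass through unchanged
  sc0 <- scaffold_contigs(fx$ctg, fx$left, assembly_config())
  expect_equal(nrow(sc0$scaffolds), 0)
  expect_equal(nrow(sc0$unscaffolded), 2)

  # a single spanning pair is below the default link threshold
  sc1 <- scaffold_contigs(fx$ctg, fx$span[fx$span$id == "S0001", ],
                          assembly_config(min_pair_links = 3))
  expect_equal(nrow(sc1$scaffolds), 0)
})

test_that("gap filling closes a tiled gap exactly and leaves conflicts alone", {
  fx <- scaffold_fixture()
  sc <- scaffold_contigs(fx$ctg, fx$span, assembly_config(),
                         insert_mean = 200)
  # reads tiling across the gap close it to the source segment exactly
  cover <- pairs_from_positions(fx$tx_seq, seq(250, 480, by = 5),
                                prefix = "C")
  filled <- fill_gaps(sc, cover, assembly_config())
  s <- filled$scaffolds$sequence
  expect_equal(stringr::str_count(s, "N"), 0)
  expect_true(s %in% c(fx$tx_seq, rc_oracle(fx$tx_seq)))

  # no anchoring reads near the gap: unchanged
  same <- fill_gaps(sc, fx$left, assembly_config())
  expect_equal(same$scaffolds$sequence, sc$scaffolds$sequence)

  # conflicting tilings: a mutated copy of the gap region forks the walk
  mut <- fx$tx_seq
  substr(mut, 415, 415) <- if (substr(mut, 415, 415) == "A") "C" else "A"
  conflict <- dplyr::bind_rows(
    cover,
    pairs_from_positions(mut, seq(250, 480, by = 5), prefix = "M")
  )
  still <- fill_gaps(sc, conflict, assembly_config())
  expect_equal(stringr::str_count(still$scaffolds$sequence, "N"), 30)
})

test_that("unigenes inherit phase origin and noiseless libraries yield the transcript", {
  tx <- sim_transcriptome(1, c(700, 700), seed = 31)
  reads <- tiling(tx)
  asm <- assemble_phase(reads, assembly_config(), phase = 1)
  expect_equal(nrow(asm$unigenes), 1)
  expect_true(asm$unigenes$sequence %in% c(tx$sequence, rc_oracle(tx$sequence)))
  expect_equal(asm$unigenes$phase_origin, 1L)
})

test_that("clustering merges duplicates, links chains, and keeps strangers apart", {
  withr::with_seed(32, {
    x1 <- random_seq(300); x2 <- random_seq(300)
    x3 <- random_seq(300); x4 <- random_seq(300)
  })
  a <- paste0(x1, x2); b <- paste0(x2, x3); c_ <- paste0(x3, x4)
  uni <- tibble::tibble(
    id = c("A", "B", "C", "DUP1", "DUP2", "LONER"),
    sequence = c(a, b, c_, a, rc_oracle(a), random_seq(500, seed = 33)),
    length = nchar(c(a, b, c_, a, a, random_seq(500, seed = 33))),
    phase_origin = c(1L, 1L, 2L, 1L, 2L, 2L)
  )
  cs <- cluster_unigenes(uni, assembly_config())
  memb <- setNames(cs$clusters$cluster, cs$clusters$unigene)
  # single linkage: A~B via x2, B~C via x3 -> one cluster with both DUPs
  expect_equal(length(unique(memb[c("A", "B", "C", "DUP1", "DUP2")])), 1)
  expect_false(memb[["LONER"]] %in% memb[c("A", "B", "C")])
  expect_equal(nrow(cs$all_unigenes), 2)
  # representative is the longest member; cross-phase cluster flagged "both"
  big <- cs$all_unigenes[cs$all_unigenes$length == 600, ]
  expect_equal(big$phase_origin, "both")
  expect_lte(nrow(cs$all_unigenes), nrow(uni))
})

test_that("full noiseless recovery: distinct unigenes equal the transcript set", {
  tx <- sim_transcriptome(6, c(400, 900), seed = 34)
  reads <- tiling(tx, depth = 12)
  u1 <- assemble_phase(reads, assembly_config(), phase = 1)$unigenes
  u2 <- assemble_phase(reads, assembly_config(), phase = 2)$unigenes
  cs <- cluster_unigenes(dplyr::bind_rows(u1, u2), assembly_config())
  expect_equal(nrow(cs$all_unigenes), nrow(tx))
  got <- sort(pmin(cs$all_unigenes$sequence,
                   rc_oracle(cs$all_unigenes$sequence)))
  want <- sort(pmin(tx$sequence, rc_oracle(tx$sequence)))
  expect_identical(got, want)
})
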