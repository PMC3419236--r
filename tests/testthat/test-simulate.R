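test_that("transcriptome generation is deterministic and respects bounds", {
  tx1 <- sim_transcriptome(1, c(900, 900), seed = 7)
  tx2 <- sim_transcriptome(1, c(900, 900), seed = 7)
  expect_identical(tx1$sequence, tx2$sequence)
  expect_equal(nchar(tx1$sequence), 900)

  tx <- sim_transcriptome(50, c(300, 2000), seed = 11)
  expect_true(all(nchar(tx$sequence) >= 300 & nchar(tx$sequence) <= 2000))
  expect_equal(anyDuplicated(tx$id), 0)
  expect_false(any(grepl("[^ACGT]", tx$sequence)))

  expect_error(sim_transcriptome(3, c(100, 200), seed = 1), "3 read lengths")
})

test_that("a requested repeat block is inserted verbatim at the stated copy count", {
  tx <- sim_transcriptome(4, c(600, 900),
                          repeat_spec = list(length = 100, copies = 2),
                          seed = 5)
  block <- attr(tx, "repeat_block")
  expect_equal(nchar(block), 100)
  n_carriers <- sum(vapply(tx$sequence, grepl, logical(1),
                           pattern = block, fixed = TRUE))
  expect_equal(n_carriers, 2)
})

test_that("zero-noise reads are exact substrings of their recorded origin", {
  tx <- sim_transcriptome(5, c(400, 800), seed = 3)
  prof <- sim_profile(tx, de_fraction = 0, seed = 3)
  cfg <- sim_config(error_rate = 0, adaptor_rate = 0, n_rate = 0,
                    lowq_rate = 0, fail_chastity_rate = 0)
  sim <- sim_reads(tx, prof, cfg, phase = 1, n_pairs = 300, seed = 9)
  seq_of <- setNames(tx$sequence, tx$id)
  for (i in seq_len(nrow(sim$truth))) {
    t <- sim$truth[i, ]
    frag <- substr(unname(seq_of[t$transcript]), t$frag_start0 + 1, t$frag_end0)
    if (t$strand == "-") frag <- rc_oracle(frag)
    mates <- sim$reads[sim$reads$id == t$pair_id, ]
    expect_identical(mates$bases[mates$mate == 1], substr(frag, 1, 75))
    expect_identical(mates$bases[mates$mate == 2],
                     rc_oracle(substr(frag, nchar(frag) - 74, nchar(frag))))
  }
})

test_that("forced artifacts appear in every read and FASTQ output is seed-stable", {
  tx <- sim_transcriptome(3, c(400, 600), seed = 2)
  prof <- sim_profile(tx, de_fraction = 0, seed = 2)
  cfg <- sim_config(error_rate = 0, adaptor_rate = 0, n_rate = 1,
                    lowq_rate = 0, fail_chastity_rate = 0)
  sim <- sim_reads(tx, prof, cfg, phase = 1, n_pairs = 50, seed = 4)
  expect_true(all(grepl("N", sim$reads$bases, fixed = TRUE)))

  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim_reads(tx, prof, cfg, 1, 50, seed = 4)$reads, f1)
  write_fastq(sim_reads(tx, prof, cfg, 1, 50, seed = 4)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("pass-filter flags survive a FASTQ round trip", {
  tx <- sim_transcriptome(2, c(400, 500), seed = 8)
  prof <- sim_profile(tx, de_fraction = 0, seed = 8)
  cfg <- sim_config(fail_chastity_rate = 0.5, error_rate = 0,
                    adaptor_rate = 0, n_rate = 0, lowq_rate = 0)
  sim <- sim_reads(tx, prof, cfg, phase = 1, n_pairs = 80, seed = 5)
  expect_gt(sum(!sim$reads$passfilter), 0)
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, f)
  back <- read_fastq(f)
  expect_equal(back$passfilter, sim$reads$passfilter)
  expect_equal(back$bases, sim$reads$bases)
  expect_equal(back$qual, sim$reads$qual)
  expect_equal(back$mate, sim$reads$mate)
})

test_that("a fold-4 transcript shows a phase-2/phase-1 count ratio near 4", {
  n_tx <- 100
  tx <- sim_transcriptome(n_tx, c(400, 600), seed = 21)
  # uniform baselines; one focal transcript at fold 4 in phase 2
  prof <- sim_profile(tx, de_fraction = 0, seed = 21)
  prof$baseline <- rep(100, n_tx)
  prof$de[1] <- TRUE
  prof$direction[1] <- 2L
  prof$phase2_multiplier[1] <- 4
  cfg <- sim_config(error_rate = 0, adaptor_rate = 0, n_rate = 0,
                    lowq_rate = 0, fail_chastity_rate = 0)
  n_pairs <- 10000
  s1 <- sim_reads(tx, prof, cfg, phase = 1, n_pairs, seed = 31)
  s2 <- sim_reads(tx, prof, cfg, phase = 2, n_pairs, seed = 32)
  x <- sum(s1$truth$transcript == "TX0001")
  y <- sum(s2$truth$transcript == "TX0001")
  # exact binomial oracle: true sampling proportions per phase
  p1 <- 100 / (100 * n_tx)
  p2 <- 400 / (100 * (n_tx - 1) + 400)
  expect_gte(x, qbinom(1e-5, n_pairs, p1))
  expect_lte(x, qbinom(1 - 1e-5, n_pairs, p1))
  expect_gte(y, qbinom(1e-5, n_pairs, p2))
  expect_lte(y, qbinom(1 - 1e-5, n_pairs, p2))
  lo <- qbinom(1e-5, n_pairs, p2) / qbinom(1 - 1e-5, n_pairs, p1)
  hi <- qbinom(1 - 1e-5, n_pairs, p2) / qbinom(1e-5, n_pairs, p1)
  expect_gt(y / x, lo)
  expect_lt(y / x, hi)
})

test_that("realized pair counts match multinomial expectations", {
  n_tx <- 30
  tx <- sim_transcriptome(n_tx, c(400, 700), seed = 13)
  prof <- sim_profile(tx, de_fraction = 0, seed = 13)
  cfg <- sim_config(error_rate = 0, adaptor_rate = 0, n_rate = 0,
                    lowq_rate = 0, fail_chastity_rate = 0)
  sim <- sim_reads(tx, prof, cfg, phase = 1, n_pairs = 10000, seed = 17)
  obs <- table(factor(sim$truth$transcript, levels = tx$id))
  p <- prof$baseline / sum(prof$baseline)
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("ontology fixtures are acyclic, slim-consistent and OBO round-trips", {
  fx <- sim_ontology(100, depth = 5, slim_fraction = 0.3, seed = 6)
  expect_true(all(fx$slim %in% fx$dag$terms))
  # acyclicity is enforced at construction; a round trip preserves edges
  f <- withr::local_tempfile(fileext = ".obo")
  write_obo(fx$dag, f)
  back <- read_obo(f)
  expect_setequal(back$terms, fx$dag$terms)
  orig_edges <- with(fx$dag$edges, sort(paste(child, parent, rel)))
  back_edges <- with(back$edges, sort(paste(child, parent, rel)))
  expect_identical(back_edges, orig_edges)
})

test_that("tiling reads cover every transcript base", {
  tx <- sim_transcriptome(3, c(400, 700), seed = 19)
  tr <- sim_tiling_reads(tx, sim_config(), depth = 20)
  cover <- lapply(setNames(tx$length, tx$id), function(L) logical(L))
  for (i in seq_len(nrow(tr$truth))) {
    t <- tr$truth[i, ]
    # mate 1 covers the fragment head, mate 2 the fragment tail
    cover[[t$transcript]][(t$frag_start0 + 1):(t$frag_start0 + 75)] <- TRUE
    cover[[t$transcript]][(t$frag_end0 - 74):t$frag_end0] <- TRUE
  }
  expect_true(all(vapply(cover, all, logical(1))))
})
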