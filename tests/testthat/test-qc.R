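test_that("low-quality rule uses a strict 10% threshold", {
  base <- random_seq(75, seed = 1)
  reads <- tibble::tibble(
    id = c("r8", "r7"), mate = 1L,
    bases = base,
    qual = c(qual_with_low(75, 8), qual_with_low(75, 7)),
    passfilter = TRUE
  )
  out <- filter_reads(reads, qc_config())
  # 8/75 = 10.67% > 10% -> removed; 7/75 = 9.33% -> kept
  expect_equal(out$verdict, c("LOWQ", "KEEP"))
})

test_that("the boundary at exactly 10% low-quality bases keeps the read", {
  base <- random_seq(80, seed = 2)
  reads <- tibble::tibble(
    id = c("exact10", "above10"), mate = 1L, bases = base,
    qual = c(qual_with_low(80, 8), qual_with_low(80, 9)),
    passfilter = TRUE
  )
  out <- filter_reads(reads, qc_config())
  expect_equal(out$verdict, c("KEEP", "LOWQ"))
})

test_that("a failed chastity flag removes the read regardless of bases", {
  reads <- tibble::tibble(
    id = "pf", mate = 1L, bases = random_seq(75, seed = 3),
    qual = qual_with_low(75, 0), passfilter = FALSE
  )
  expect_equal(filter_reads(reads, qc_config())$verdict, "CHASTITY")
})

test_that("rules are applied in order: chastity, adaptor, ambiguous, low quality", {
  cfg <- qc_config()
  ad <- cfg$adaptor_seqs[1]
  contaminated <- paste0(random_seq(50, seed = 4), substr(ad, 1, 25))
  with_n <- sub("A", "N", random_seq(75, seed = 5))
  reads <- tibble::tibble(
    id = c("chas_and_adaptor", "adaptor_and_lowq", "n_and_lowq"),
    mate = 1L,
    bases = c(contaminated, contaminated, with_n),
    qual = c(qual_with_low(75, 0), qual_with_low(75, 20), qual_with_low(75, 20)),
    passfilter = c(FALSE, TRUE, TRUE)
  )
  # adaptor/N share the middle tier; low quality is tested last, so the
  # read with both an N and many low-quality bases reports AMBIGUOUS
  expect_equal(filter_reads(reads, cfg)$verdict,
               c("CHASTITY", "ADAPTOR", "AMBIGUOUS"))
})

test_that("adaptor detection tolerates mismatches over a minimum overlap", {
  cfg <- qc_config(adaptor_seqs = "AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAG")
  stem <- random_seq(55, seed = 6)
  ov20 <- paste0(stem, "AGATCGGAAGAGCGGTTCAG")          # exact 20 bp overlap
  ov20mm2 <- paste0(stem, "AGATCGGAACAGCGGTTCAC")        # 2 mismatches
  ov9 <- paste0(random_seq(66, seed = 7), "AGATCGGAA")   # 9 bp: below floor
  reads <- tibble::tibble(
    id = c("a", "b", "c"), mate = 1L,
    bases = c(ov20, ov20mm2, ov9),
    qual = qual_with_low(75, 0), passfilter = TRUE
  )
  expect_equal(filter_reads(reads, cfg)$verdict,
               c("ADAPTOR", "ADAPTOR", "KEEP"))
})

test_that("pair-level removal attributes one reason per pair and accounts exactly", {
  cfg <- qc_config()
  ad <- cfg$adaptor_seqs[1]
  good <- random_seq(75, seed = 8)
  pairs <- make_pairs(
    bases1 = c(good, paste0(random_seq(50, seed = 9), substr(ad, 1, 25)), good),
    bases2 = c(good, good, good),
    qual2 = c(qual_with_low(75, 0), qual_with_low(75, 0), qual_with_low(75, 12))
  )
  res <- run_qc(pairs, cfg)
  r <- res$report
  expect_equal(r$input_pairs, 3)
  expect_equal(r$removed_adaptor, 1)
  expect_equal(r$removed_lowq, 1)
  expect_equal(r$surviving_pairs, 1)
  expect_equal(
    r$input_pairs,
    r$surviving_pairs + r$removed_chastity + r$removed_adaptor +
      r$removed_ambiguous + r$removed_lowq
  )
  # the adaptor-contaminated pair is absent from the output
  expect_false("p0002" %in% res$reads$id)
})

test_that("accounting identity holds on random simulated input and QC is idempotent", {
  tx <- sim_transcriptome(4, c(400, 700), seed = 10)
  prof <- sim_profile(tx, de_fraction = 0, seed = 10)
  cfg <- sim_config() # default artifact rates exercise every rule
  sim <- sim_reads(tx, prof, cfg, phase = 1, n_pairs = 800, seed = 11)
  res <- run_qc(sim$reads, qc_config())
  r <- res$report
  expect_equal(
    r$input_pairs,
    r$surviving_pairs + r$removed_chastity + r$removed_adaptor +
      r$removed_ambiguous + r$removed_lowq
  )
  again <- run_qc(res$reads, qc_config())
  expect_equal(again$report$surviving_pairs, r$surviving_pairs)
  expect_equal(
    again$report$removed_chastity + again$report$removed_adaptor +
      again$report$removed_ambiguous + again$report$removed_lowq, 0
  )
})

test_that("ambiguous-base pair removal matches the 1-(1-r)^2 oracle", {
  tx <- sim_transcriptome(4, c(400, 700), seed = 12)
  prof <- sim_profile(tx, de_fraction = 0, seed = 12)
  cfg <- sim_config(error_rate = 0, adaptor_rate = 0, n_rate = 0.5,
                    lowq_rate = 0, fail_chastity_rate = 0)
  n_pairs <- 2000
  sim <- sim_reads(tx, prof, cfg, phase = 1, n_pairs, seed = 13)
  r <- run_qc(sim$reads, qc_config())$report
  expect_equal(r$removed_chastity + r$removed_lowq, 0)
  # a handful of random reads can resemble an adaptor end within the
  # mismatch budget; fold them into the removal tally for the oracle check
  p_remove <- 1 - (1 - 0.5)^2
  frac <- (r$removed_ambiguous + r$removed_adaptor) / r$input_pairs
  expect_lt(r$removed_adaptor / r$input_pairs, 0.02)
  expect_lt(abs(frac - p_remove), binom_band(p_remove, n_pairs))
})

test_that("malformed input is rejected with informative errors", {
  bad <- tibble::tibble(id = "x", mate = 1L, bases = "ACGT",
                        qual = "III", passfilter = TRUE)
  expect_error(filter_reads(bad, qc_config()), "malformed quality.*'x'")
  solo <- tibble::tibble(id = "only", mate = 1L, bases = random_seq(75, seed = 1),
                         qual = qual_with_low(75, 0), passfilter = TRUE)
  expect_error(run_qc(solo, qc_config()), "desynchronized")
})

test_that("file-level QC round-trips synchronized FASTQ pairs", {
  tx <- sim_transcriptome(3, c(400, 600), seed = 14)
  prof <- sim_profile(tx, de_fraction = 0, seed = 14)
  sim <- sim_reads(tx, prof, sim_config(), phase = 1, n_pairs = 150, seed = 15)
  d <- withr::local_tempdir()
  write_fastq(dplyr::filter(sim$reads, mate == 1), file.path(d, "r1.fastq"))
  write_fastq(dplyr::filter(sim$reads, mate == 2), file.path(d, "r2.fastq"))
  res <- run_qc_files(file.path(d, "r1.fastq"), file.path(d, "r2.fastq"),
                      file.path(d, "c1.fastq"), file.path(d, "c2.fastq"))
  c1 <- read_fastq(file.path(d, "c1.fastq"))
  c2 <- read_fastq(file.path(d, "c2.fastq"))
  expect_equal(nrow(c1), res$report$surviving_pairs)
  expect_identical(c1$id, c2$id)
  in_memory <- run_qc(sim$reads, qc_config())
  expect_equal(res$report, in_memory$report)
})
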