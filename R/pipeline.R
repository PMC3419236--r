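#' Count / mean / total length accounting for a sequence set
#'
#' Completes whichever of `total_length` and `mean_length` is missing from
#' the other, with mean lengths rounded half-up to the nearest integer as
#' summary tables conventionally print them. An empty set reports zero
#' means with a warning.
#'
#' @param n Number of sequences.
#' @param total_length Total length in bp (optional if `mean_length` given).
#' @param mean_length Mean length in bp (optional if `total_length` given).
#' @return One-row tibble: `n`, `total_length`, `mean_length`.
#' @export
seq_stats <- function(n, total_length = NULL, mean_length = NULL) {
  if (n == 0) {
    warn("empty sequence set: lengths reported as 0")
    return(tibble(n = 0L, total_length = 0, mean_length = 0))
  }
  if (is.null(total_length) && is.null(mean_length)) {
    abort("provide total_length or mean_length")
  }
  if (is.null(total_length)) total_length <- n * mean_length
  mean_length <- round_half_up(total_length / n)
  tibble(n = n, total_length = total_length, mean_length = mean_length)
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. The defaults
#' describe a small two-phase experiment: 20 transcripts, 20,000 read pairs
#' per phase, 10% truly differential transcripts at fold 8.
#'
#' @param n_transcripts,length_range,repeat_spec Transcriptome parameters
#'   ([sim_transcriptome()]).
#' @param pairs_per_phase Read pairs simulated per phase.
#' @param de_fraction,fold,baseline_range Abundance profile parameters
#'   ([sim_profile()]).
#' @param sim,qc,asm Stage configurations ([sim_config()], [qc_config()],
#'   [assembly_config()]).
#' @param n_terms,slim_fraction Ontology fixture parameters.
#' @param fold_min,fdr_max Differential-call thresholds.
#' @param alpha Enrichment significance threshold.
#' @param seed Master seed; every stochastic stage derives its own stream
#'   from it.
#' @param out_dir Optional directory for FASTA/TSV stage outputs.
#' @param stages Named logical list switching stages on or off.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_transcripts = 20L,
                            length_range = c(300L, 2000L),
                            repeat_spec = NULL,
                            pairs_per_phase = 20000L,
                            de_fraction = 0.1,
                            fold = 8,
                            baseline_range = c(50, 200),
                            sim = sim_config(),
                            qc = qc_config(),
                            asm = assembly_config(min_kmer_cov = 2L),
                            n_terms = 60L,
                            slim_fraction = 0.3,
                            fold_min = 2,
                            fdr_max = 0.001,
                            alpha = 0.05,
                            seed = 1L,
                            out_dir = NULL,
                            stages = list()) {
  default_stages <- list(simulate = TRUE, qc = TRUE, assemble = TRUE,
                         quantify = TRUE, annotate = TRUE, enrich = TRUE)
  stages <- utils::modifyList(default_stages, stages)
  structure(
    list(
      n_transcripts = n_transcripts, length_range = length_range,
      repeat_spec = repeat_spec, pairs_per_phase = pairs_per_phase,
      de_fraction = de_fraction, fold = fold,
      baseline_range = baseline_range, sim = sim, qc = qc, asm = asm,
      n_terms = n_terms, slim_fraction = slim_fraction,
      fold_min = fold_min, fdr_max = fdr_max, alpha = alpha,
      seed = as.integer(seed), out_dir = out_dir, stages = stages
    ),
    class = "pipeline_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full desk-scale pipeline
#'
#' Orchestrates simulate, qc, assemble (per phase), cross-phase clustering,
#' quantify, annotate and enrich with one seed, and assembles a Table-1-style
#' summary report whose internal arithmetic is verified by
#' [summarize_run()]. With every stage switched off an empty report is
#' returned with a warning.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` holding every stage output and
#'   `summary` (the verified report tibble).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  st <- config$stages
  out <- list(config = config)
  if (!any(unlist(st))) {
    warn("all stages are switched off: empty report")
    out$summary <- tibble(statistic = character(0), phase1 = numeric(0),
                          phase2 = numeric(0), total = numeric(0))
    return(structure(out, class = "pipeline_result"))
  }
  need <- function(what, stage) {
    if (is.null(out[[what]])) {
      abort(sprintf("stage '%s' needs missing upstream output '%s'",
                    stage, what))
    }
    out[[what]]
  }
  seed <- config$seed
  if (st$simulate) {
    out$txome <- run_stage("simulate", sim_transcriptome(
      config$n_transcripts, config$length_range, config$repeat_spec,
      seed = seed + 11L, read_length = config$sim$read_length
    ))
    out$profile <- sim_profile(out$txome, config$de_fraction, config$fold,
                               config$baseline_range, seed = seed + 12L)
    out$raw1 <- run_stage("simulate", sim_reads(
      out$txome, out$profile, config$sim, phase = 1,
      n_pairs = config$pairs_per_phase, seed = seed + 13L
    ))
    out$raw2 <- run_stage("simulate", sim_reads(
      out$txome, out$profile, config$sim, phase = 2,
      n_pairs = config$pairs_per_phase, seed = seed + 14L
    ))
    out$ontology <- sim_ontology(config$n_terms, slim_fraction =
                                   config$slim_fraction, seed = seed + 15L)
  }
  if (st$qc) {
    r1 <- need("raw1", "qc"); r2 <- need("raw2", "qc")
    out$qc1 <- run_stage("qc", run_qc(r1$reads, config$qc))
    out$qc2 <- run_stage("qc", run_qc(r2$reads, config$qc))
  }
  if (st$assemble) {
    q1 <- need("qc1", "assemble"); q2 <- need("qc2", "assemble")
    out$asm1 <- run_stage("assemble", assemble_phase(
      q1$reads, config$asm, phase = 1, insert_mean = config$sim$insert_mean
    ))
    out$asm2 <- run_stage("assemble", assemble_phase(
      q2$reads, config$asm, phase = 2, insert_mean = config$sim$insert_mean
    ))
    out$clusters <- run_stage("cluster", cluster_unigenes(
      bind_rows(out$asm1$unigenes, out$asm2$unigenes), config$asm
    ))
  }
  if (st$quantify) {
    cl <- need("clusters", "quantify")
    counts <- run_stage("quantify", count_table(
      need("qc1", "quantify")$reads, need("qc2", "quantify")$reads,
      cl$all_unigenes
    ))
    out$counts <- counts
    out$de <- run_stage("quantify", call_differential(
      counts, config$fold_min, config$fdr_max
    ))
  }
  if (st$annotate) {
    cl <- need("clusters", "annotate")
    out$hits <- run_stage("annotate", sim_hits(
      cl$all_unigenes, seed = seed + 21L
    ))
    out$annotations <- run_stage("annotate", select_annotations(
      out$hits, sequences = cl$all_unigenes[, c("id", "sequence")]
    ))
    out$match_rates <- length_binned_match_rate(
      cl$all_unigenes[, c("id", "length")], out$annotations
    )
    out$homology_classes <- homology_class_summary(out$annotations)
    ont <- need("ontology", "annotate")
    annotated <- out$annotations$query[out$annotations$source == "hit"]
    out$assignments <- run_stage("annotate", sim_assignments(
      annotated, ont$dag$terms, seed = seed + 22L
    ))
    out$slim_assignments <- run_stage("annotate", map_to_slim(
      out$assignments, ont$dag, ont$slim
    ))
  }
  if (st$enrich) {
    out$enrichment <- run_stage("enrich", run_enrichment(
      need("de", "enrich"), need("assignments", "enrich"),
      alpha = config$alpha
    ))
  }
  out <- structure(out, class = "pipeline_result")
  out$summary <- run_stage("summarize", summarize_run(out))
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(out, config$out_dir)
  }
  out
}

#' Build and verify the Table-1-style summary report
#'
#' Collects per-phase read, contig, scaffold and unigene accounting plus the
#' differential-abundance tallies, and verifies the arithmetic identities of
#' the report (count times mean length reproduces total length within
#' rounding; the differential total is the sum of the per-direction counts).
#' Any violated identity is a hard error naming the identity.
#'
#' @param result A `pipeline_result` (possibly partial).
#' @return Tibble: `statistic`, `phase1`, `phase2`, `total` (NA where a
#'   quantity does not apply).
#' @export
summarize_run <- function(result) {
  rows <- list()
  add <- function(stat, p1 = NA_real_, p2 = NA_real_, tot = NA_real_) {
    rows[[length(rows) + 1L]] <<- tibble(
      statistic = stat, phase1 = p1, phase2 = p2, total = tot
    )
  }
  check_stats <- function(label, stats) {
    if (stats$n > 0 &&
        abs(stats$total_length - stats$mean_length * stats$n) >
        0.5 * stats$n + 1) {
      abort(sprintf(
        "summary identity violated for %s: count x mean != total", label
      ))
    }
  }
  if (!is.null(result$raw1)) {
    add("Number of raw read pairs", nrow(result$raw1$truth),
        nrow(result$raw2$truth))
  }
  if (!is.null(result$qc1)) {
    for (r in list(result$qc1$report, result$qc2$report)) {
      if (r$input_pairs != r$surviving_pairs + r$removed_chastity +
          r$removed_adaptor + r$removed_ambiguous + r$removed_lowq) {
        abort("summary identity violated: QC pair accounting")
      }
    }
    add("Number of clean reads", 2 * result$qc1$report$surviving_pairs,
        2 * result$qc2$report$surviving_pairs)
    rl1 <- nchar(result$qc1$reads$bases[1])
    add("Average read length (bp)", rl1, nchar(result$qc2$reads$bases[1]))
    add("Total length of clean reads (bp)",
        sum(nchar(result$qc1$reads$bases)),
        sum(nchar(result$qc2$reads$bases)))
  }
  if (!is.null(result$asm1)) {
    for (ph in 1:2) {
      asm <- result[[paste0("asm", ph)]]
      cs <- seq_stats(nrow(asm$contigs), sum(asm$contigs$length))
      check_stats(sprintf("phase %d contigs", ph), cs)
      scaf <- asm$scaffolding$scaffolds
      ss <- seq_stats(nrow(scaf), sum(scaf$length))
      check_stats(sprintf("phase %d scaffolds", ph), ss)
      us <- seq_stats(nrow(asm$unigenes), sum(asm$unigenes$length))
      check_stats(sprintf("phase %d unigenes", ph), us)
      result[[paste0("stats", ph)]] <- list(cs = cs, ss = ss, us = us)
    }
    s1 <- result$stats1; s2 <- result$stats2
    add("Number of contigs", s1$cs$n, s2$cs$n)
    add("Average length of contigs (bp)", s1$cs$mean_length, s2$cs$mean_length)
    add("Number of scaffolds", s1$ss$n, s2$ss$n)
    add("Average length of scaffolds (bp)", s1$ss$mean_length,
        s2$ss$mean_length)
    all_u <- result$clusters$all_unigenes
    as_ <- seq_stats(nrow(all_u), sum(all_u$length))
    check_stats("distinct unigenes", as_)
    add("Number of unigenes", s1$us$n, s2$us$n, as_$n)
    add("Average length of unigenes (bp)", s1$us$mean_length,
        s2$us$mean_length, as_$mean_length)
    add("Total length of unigenes (bp)", sum(result$asm1$unigenes$length),
        sum(result$asm2$unigenes$length), as_$total_length)
  }
  if (!is.null(result$de)) {
    up1 <- sum(result$de$call == "UP1")
    up2 <- sum(result$de$call == "UP2")
    uniq1 <- sum(result$de$call == "UP1" & result$de$unique_to == "1")
    uniq2 <- sum(result$de$call == "UP2" & result$de$unique_to == "2")
    total_de <- sum(result$de$call != "NS")
    if (total_de != up1 + up2) {
      abort("summary identity violated: differential total != UP1 + UP2")
    }
    add("Differentially abundant unigenes", up1, up2, total_de)
    add("Unique to phase", uniq1, uniq2)
  }
  bind_rows(rows)
}

# write stage outputs in their standard formats
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  if (!is.null(result$txome)) write_fasta(result$txome, p("transcriptome.fasta"))
  for (ph in 1:2) {
    qc <- result[[paste0("qc", ph)]]
    if (!is.null(qc)) {
      write_fastq(filter(qc$reads, .data$mate == 1L),
                  p(sprintf("clean_phase%d_1.fastq", ph)))
      write_fastq(filter(qc$reads, .data$mate == 2L),
                  p(sprintf("clean_phase%d_2.fastq", ph)))
      readr::write_tsv(qc$report, p(sprintf("qc_report_phase%d.tsv", ph)))
    }
    asm <- result[[paste0("asm", ph)]]
    if (!is.null(asm)) {
      write_fasta(asm$contigs, p(sprintf("contigs_phase%d.fasta", ph)))
      write_fasta(asm$unigenes, p(sprintf("unigenes_phase%d.fasta", ph)))
    }
  }
  if (!is.null(result$clusters)) {
    write_fasta(result$clusters$all_unigenes, p("all_unigenes.fasta"))
  }
  if (!is.null(result$de)) {
    readr::write_tsv(as_tibble(result$de), p("abundance.tsv"))
  }
  if (!is.null(result$enrichment)) {
    readr::write_tsv(as_tibble(result$enrichment), p("enrichment.tsv"))
  }
  if (!is.null(result$summary)) {
    readr::write_tsv(result$summary, p("summary.tsv"))
  }
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Desk-scale transcriptome pipeline result\n")
  if (!is.null(x$summary) && nrow(x$summary) > 0) {
    print(as.data.frame(x$summary), row.names = FALSE)
  } else {
    cat("  (empty report)\n")
  }
  invisible(x)
}
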