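---
title: "Methods: desk-scale de novo transcriptome assembly and digital expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale de novo transcriptome assembly and digital expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(florasm)
```

`florasm` reconstructs, at desk scale, the reference-free workflow used in
early two-condition plant transcriptome studies: whole-read cleaning, k-mer
de Bruijn assembly to unigenes, digital differential-expression testing,
annotation summarization with GO-slim mapping, and hypergeometric term
enrichment. This vignette explains the models and procedures, the parameters
that matter, the synthetic-data generator that stands in for raw sequencing
lanes, and the numerical and design choices made where the workflow's
published descriptions leave room.

## The synthetic experiment

Real studies of this design sequenced two cDNA libraries — here called
phase 1 and phase 2, e.g. young versus older flower buds — on an early
Illumina instrument: ~75 bp paired-end reads from cDNA fragments gel-excised
at 200 ± 25 bp. The generator reproduces those conditions:

* **Reads**: 75 bp pairs; fragment length Normal(200, 12.5) truncated to
  [175, 225]. The ± 25 is read as a hard excision window; the standard
  deviation is set so that ~95% of the untruncated mass falls inside it.
  The library is unstranded, so fragment orientation is random.
* **Abundance**: each transcript gets a positive baseline weight; a chosen
  subset is truly differential, with the fold applied in phase 2 (or its
  reciprocal, so both phases gain a differential set). Pairs are drawn
  multinomially, so realized counts carry genuine sampling noise.
* **Artifacts**, injected per read and logged in a truth table:
  substitution errors at rate 0.001 (the order of magnitude of early
  Illumina chemistry; the error model is substitution-only, an assumption
  recorded here because indel and quality-ramp behaviour of the original
  runs is not documented), adaptor read-through at 0.01, at least one `N`
  at 0.02, a low-quality read (strictly more than 10% of bases below Q20)
  at 0.02, and a failed chastity flag at 0.01. These rates are the package's
  fixed study conditions; they are deliberately not tuned per experiment.
* **Truth tables** record each pair's source transcript, 0-based half-open
  fragment coordinates, strand, differential status and artifact flags, so
  downstream stages can be scored exactly.

Two generators exist on purpose. `sim_reads()` samples fragments uniformly,
which — like any finite random library — can leave the few terminal bases of
a transcript uncovered. `sim_tiling_reads()` places fragments
deterministically at a fixed step including both transcript ends; it is the
generator used for exact-recovery experiments, where "error-free reads tiling
the transcriptome" is the stated premise.

What the generator does *not* emulate: GC bias, coverage waviness,
multi-isoform gene models, indels, quality decay along the read, and optical
duplicates. Tests passing on this generator therefore validate the logic and
the statistics of the pipeline, not its robustness to every failure mode of
real lanes.

## Read cleaning

Three rules are applied in a fixed order — chastity, adaptor/ambiguous,
low quality — and the first failing rule is the reported reason, which makes
per-rule tallies deterministic:

1. **Chastity.** The original criterion (purity ≥ 0.6 over the first 25
   cycles) operates on raw intensities that do not survive base calling, so
   the implementation honors the CASAVA-1.8 pass-filter flag carried in the
   FASTQ header; the 0.6/25 parameters are kept in `qc_config()` as
   documentation of what the flag encodes.
2. **Adaptor or `N`.** Adaptor contamination is detected by ungapped
   end-overlap alignment of each adaptor against either read end, requiring
   ≥ 10 bp overlap with ≤ 2 mismatches (the Biostrings
   `trimLRPatterns` machinery with a per-overlap mismatch budget). Any `N`
   in the read is ambiguous-trace evidence and removes it.
3. **Low quality.** A read is removed when *strictly more than* 10% of its
   bases have Q < 20; a read at exactly 10% is kept. The strictness follows
   the "more than 10%" phrasing and is pinned by boundary tests.

Filtering is pair-aware: if either mate fails, the pair is removed, because
downstream scaffolding needs intact pairs. Whether the original pipelines
were pair-aware is not documented; this choice is flagged here, and the
report's accounting identity (input = surviving + Σ removed) holds either
way.

## Assembly

**Graph.** Nodes are canonical k-mers (lexicographic minimum of a k-mer and
its reverse complement; k odd so no k-mer is its own reverse complement),
with k = 25 by default — the original k is unpublished, so it is a config
value, not a claim. Each read and its reverse complement contribute
symmetrically, giving a strand-symmetric oriented graph. `min_kmer_cov`
optionally drops k-mers below a multiplicity floor: 1 (keep everything) for
error-free libraries, 2 in the default pipeline, where it removes the
singleton k-mers that substitution errors create — the usual de Bruijn
practice when no further graph cleaning (tips, bubbles) is implemented,
and such cleaning is deliberately out of scope.

**Contigs** are maximal paths whose interior nodes have in- and out-degree
one. At a branch the path terminates; the algorithm never chooses a branch
arbitrarily, which is exactly the "unambiguous path" rule made
deterministic. Contigs below `min_contig_len` (default 100 bp, the floor of
the smallest length bin conventionally reported) are dropped. Output is
canonical-strand, sorted by length then sequence, so contig identity is
invariant to read order.

**Scaffolds.** Clean pairs are mapped back to contigs by exact full-length
matching on either strand (mismatch-tolerant mapping is out of scope at desk
scale); pairs whose mates map uniquely to two different contigs vote for an
oriented link. A link needs ≥ `min_pair_links` (3) consistent pairs; bundles
with contradictory orientations are discarded with a message, and any
contig end touched by more than one bundle leaves its contigs unscaffolded
rather than guessing. The gap is written as `N`s of length
round(mean(insert_mean − flank spans)), floored at 1 bp.

**Gap filling** walks the read graph from the last k-mer of the left flank
along unique out-edges; if the walk spells its way to the first k-mer of the
right flank within the expected span (gap + k + 100 steps), the `N`s are
replaced by the walked bases. A branching walk — two conflicting read
tilings — leaves the gap untouched, so the total number of `N`s never
increases.

**Unigenes** are gap-filled scaffolds plus unscaffolded contigs after an
extension closure: each end is extended while a unique single path exists,
under the same unambiguity rule as contig construction, so no read in the
library can extend a unigene further.

**Clustering.** Unigenes from both phases are clustered single-linkage:
two sequences join when a local alignment in either orientation reaches
94% identity over ≥ 40 bp (defaults approximating the published defaults of
the classic TGI clustering tool, recorded as assumptions); components are
taken with igraph and each cluster is represented by its longest member.
An 11-bp shared-word prefilter skips hopeless pairs before alignment, the
standard seed-and-extend shortcut.

## Quantification and the digital expression test

Reads are mapped to the distinct unigene set by exact full-length matching;
a read counts only if it matches exactly one unigene, multi-matching reads
go to a separate tally, and the library totals N₁, N₂ are the sums of
unique counts. RPKM is 10⁹·C/(N·L). The fold change is the phase-2 over
phase-1 RPKM ratio with 0.001 substituted for zero RPKM on either side.

The p-value is the classical conditional test for digital counts: given x
reads in library 1, the count y in library 2 follows

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,\left(1 + N_2/N_1\right)^{x+y+1}},$$

which is exactly a negative binomial with size x + 1 and success probability
N₁/(N₁+N₂). Tails are therefore evaluated through `pnbinom()`, which is
numerically stable for counts up to 10⁶ and beyond; an independent
brute-force series summation backs it in the tests. The reported p-value is
the doubled smaller tail, 2·min(P(Y ≤ y), P(Y ≥ y)) capped at 1 — the
workflow descriptions do not state sidedness, so the two-sided form is the
default and one-sided tails are exposed via `alternative`. One property
worth stating: this conditional construction is *not* exactly invariant
under exchanging (x, N₁) with (y, N₂); the doubled-tail p-values of a pair
and its swap can differ (x = 5, y = 2, equal totals: 0.289 vs 0.453). The
tests therefore pin the construction itself (oracle agreement, tail
monotonicity) rather than a symmetry it does not have.

FDR control is Benjamini–Hochberg (`stats::p.adjust`), and calls use the
inclusive thresholds |fold| ≥ 2 and FDR ≤ 0.001. "Unique to a phase" means
unique-mapped reads in that phase only — the phrase is not defined in the
source workflows, so this reading is recorded here. With one library per
condition the test has no dispersion component; it measures sampling noise
only, which is why modern replicate-aware methods supersede it — the point
here is fidelity to the classic procedure.

## Annotation and slim mapping

Homology hits arrive as the ubiquitous 12-column tabular alignment format,
one file per database. Hits at E-value ≥ 10⁻⁵ are discarded (strict
cutoff); per query the highest-priority database with a passing hit wins
(Nr → SwissProt → KEGG → COG, priority beating E-value), and within it ties
break by E-value, bit score, then subject id, making selection invariant to
input order. Direction comes from the winning hit's query coordinate order
(qstart > qend ⇔ minus frame, the standard tabular convention — the format
carries no frame column). Queries without a passing hit fall back to the
longest open reading frame across six frames, labelled `orf_fallback`; this
is a deliberate, clearly flagged stand-in for HMM-based coding-region
predictors, which are out of scope.

Match efficiency is tallied in half-open length bins [100, 500), [500,
1000), [1000, 2000), [2000, ∞); homology classes split at E < 10⁻⁵⁰
(strong) and identity > 80% (high; the ~23% floor seen in such studies is an
observation, not a filter).

Slim mapping operates on a minimal OBO 1.2 subset reader ([Term], id:,
name:, is_a:, relationship: part_of — both relation types traversed). Each
upward path from an assigned term contributes the *first* slim term it
encounters, counting the term itself; nearer slim terms therefore shadow
their own slim ancestors path by path, and a term that is itself slim maps
exactly to itself. This is the documented behaviour of the canonical
slim-mapping script, and the alternative reading ("no slim term strictly
between"), which would add direct slim parents to slim terms, fails the
identity-slim sanity case; an all-paths enumeration oracle pins the chosen
semantics in the tests.

## Enrichment

For N annotated unigenes, n of them differentially abundant, a term with M
annotated members of which m are differential, the over-representation
p-value is the hypergeometric right tail
P(X ≥ m) = 1 − Σᵢ₌₀^{m−1} C(M,i)·C(N−M, n−i)/C(N,n), evaluated through
`phyper()`. Only terms with m ≥ 1 in a direction are tested. Bonferroni
correction divides by the number of tests within that ontology scope and
direction by default (`correction = "global"` pools them); significance is
strict, p < 0.05. Only over-representation is tested — the formula is a
right tail. Whether the original correction pooled directions is not
documented; per-direction is the default because each direction's set is
interpreted separately.

## Numerical choices and degenerate inputs

* Factorials and binomials in the oracles use `lgamma`/`lchoose`; the
  implementations use `pnbinom`/`phyper` directly.
* Mean lengths in summary reports are rounded half-up to integers, matching
  how such tables are conventionally printed; the report checker allows
  count × mean to differ from the total by at most 0.5·count + 1.
* Ties in hit selection, cluster representatives (longest, then id) and
  branch handling (stop, never choose) are all resolved deterministically,
  so every stage is reproducible under a fixed seed, including byte-identical
  FASTQ output.
* Empty inputs degrade explicitly: empty read sets give empty graphs and
  contig lists; an empty differential set yields an empty enrichment table
  with a warning; an empty sequence set reports zero means with a warning.
* Desynchronized mate files, malformed quality strings, unknown database
  labels and terms absent from the ontology are hard errors naming the
  offending record.

## Problem sizes

The shipped experiments are sized for a single CPU: exact-recovery runs use
20 transcripts of 300–2000 bp tiled at depth 20; the differential-recovery
experiment uses 200 transcripts, 10⁵ pairs per phase and 20 truth-marked
8-fold transcripts; the null calibration uses 2000 unigenes; oracle sweeps
cover every hypergeometric contingency up to N = 60 and 100 random ontology
DAGs of up to 60 terms. These sizes are the package's chosen study
conditions for validation, small enough to run anywhere yet large enough
that the binomial error bands in the tests are meaningful.

## Known limitations

* No error correction, tip/bubble removal, or mismatch-tolerant read
  mapping: with substitution errors present, assembly fidelity rests on the
  k-mer coverage floor alone, and fragmented assemblies at low coverage are
  expected behaviour, not bugs.
* One library per condition: no replicate-aware dispersion; p-values
  reflect sampling noise only.
* The ORF fallback is a direction heuristic, not a coding-region predictor.
* KO terms are treated as generic term assignments; pathway structure is
  out of scope, as is topology-aware enrichment (elim/weight) and
  FDR-based enrichment correction.
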