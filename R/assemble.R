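#' Assembly configuration
#'
#' @param k Odd k-mer size for the de Bruijn graph (must be below the read
#'   length). Odd k rules out reverse-complement-palindromic k-mers, which
#'   keeps the canonical-strand graph well defined.
#' @param min_contig_len Contigs shorter than this are dropped (bp).
#' @param min_kmer_cov Minimum k-mer multiplicity retained in the graph.
#'   The default 1 keeps every observed k-mer (appropriate for error-free
#'   data); for libraries with sequencing errors a floor of 2 removes the
#'   singleton k-mers that substitution errors create, the usual de Bruijn
#'   practice.
#' @param min_pair_links Minimum number of consistent read pairs required to
#'   link two contigs into a scaffold.
#' @param min_cluster_identity,min_cluster_overlap Local-alignment identity
#'   (proportion) and overlap (bp) at which two unigenes from different
#'   phases are clustered into one distinct sequence.
#' @return A list of class `assembly_config`.
#' @export
assembly_config <- function(k = 25L, min_contig_len = 100L,
                            min_kmer_cov = 1L,
                            min_pair_links = 3L,
                            min_cluster_identity = 0.94,
                            min_cluster_overlap = 40L) {
  assert_that(k %% 2 == 1, "k must be odd")
  assert_that(
    min_cluster_identity > 0 && min_cluster_identity <= 1,
    "min_cluster_identity must lie in (0, 1]"
  )
  structure(
    list(
      k = as.integer(k), min_contig_len = as.integer(min_contig_len),
      min_kmer_cov = as.integer(min_kmer_cov),
      min_pair_links = as.integer(min_pair_links),
      min_cluster_identity = min_cluster_identity,
      min_cluster_overlap = as.integer(min_cluster_overlap)
    ),
    class = "assembly_config"
  )
}

# oriented-node encoding over canonical k-mer ids: node i has two orientations
# encoded 2i-1 (+, canonical as stored) and 2i (-, reverse complement)
enc_node <- function(i, plus) 2L * i - as.integer(plus)
enc_flip <- function(e) e + ifelse(e %% 2L == 1L, 1L, -1L)
enc_id <- function(e) (e + 1L) %/% 2L

# k-mer matrix for reads of equal length: one column per offset
kmer_cols <- function(bases, k) {
  L <- nchar(bases[1])
  starts <- seq_len(L - k + 1L)
  vapply(starts, function(s) substr(bases, s, s + k - 1L),
         character(length(bases)))
}

#' Build a canonical-strand de Bruijn graph from reads
#'
#' Nodes are canonical k-mers (the lexicographic minimum of a k-mer and its
#' reverse complement); edges are the (k-1)-overlap successions observed in
#' the reads, stored in oriented form. Each read and its reverse complement
#' contribute symmetrically, so the graph is strand symmetric by
#' construction.
#'
#' @param bases Character vector of N-free read sequences.
#' @param k Odd k-mer size, strictly less than every read length.
#' @param min_kmer_cov Minimum multiplicity for a k-mer to enter the graph
#'   (see [assembly_config()]).
#' @return A list of class `debruijn_graph`: canonical node k-mers, per-node
#'   coverage counts, oriented adjacency, and the total number of k-mer
#'   instances observed in the forward read stream.
#' @export
build_graph <- function(bases, k = 25L, min_kmer_cov = 1L) {
  bases <- bases[nchar(bases) > 0]
  if (length(bases) > 0 && k >= min(nchar(bases))) {
    abort("k must be smaller than the read length")
  }
  assert_that(k %% 2 == 1, "k must be odd")
  if (length(bases) == 0) {
    return(structure(
      list(k = as.integer(k), nodes = character(0), counts = integer(0),
           succ = list(), outdeg = integer(0), n_instances = 0L),
      class = "debruijn_graph"
    ))
  }
  if (any(grepl("[^ACGT]", bases))) {
    abort("reads must be N-free (run QC first)")
  }
  streams <- list(bases, revcomp(bases))
  inst <- character(0)    # forward-stream k-mer instances (for coverage)
  from_w <- character(0); to_w <- character(0)
  for (s in seq_along(streams)) {
    for (grp in split(streams[[s]], nchar(streams[[s]]))) {
      m <- kmer_cols(grp, k)
      if (is.null(dim(m))) m <- matrix(m, nrow = length(grp))
      if (s == 1) inst <- c(inst, as.vector(m))
      if (ncol(m) > 1) {
        from_w <- c(from_w, as.vector(m[, -ncol(m), drop = FALSE]))
        to_w <- c(to_w, as.vector(m[, -1, drop = FALSE]))
      }
    }
  }
  obs <- unique(c(inst, from_w, to_w))
  canon <- canonical(obs)
  nodes <- sort(unique(canon))
  counts_tab <- table(match(canonical(inst), nodes))
  counts <- integer(length(nodes))
  counts[as.integer(names(counts_tab))] <- as.integer(counts_tab)
  if (min_kmer_cov > 1L) {
    keep <- counts >= min_kmer_cov
    nodes <- nodes[keep]
    counts <- counts[keep]
  }
  # oriented encoding of an observed k-mer string (NA once filtered out)
  encode <- function(w) {
    cw <- canonical(w)
    i <- match(cw, nodes)
    enc_node(i, plus = w == cw)
  }
  edges <- unique(data.frame(from = encode(from_w), to = encode(to_w)))
  edges <- edges[!is.na(edges$from) & !is.na(edges$to), , drop = FALSE]
  succ <- vector("list", 2L * length(nodes))
  if (nrow(edges) > 0) {
    sp <- split(edges$to, edges$from)
    succ[as.integer(names(sp))] <- lapply(sp, as.integer)
  }
  structure(
    list(k = as.integer(k), nodes = nodes, counts = counts, succ = succ,
         outdeg = lengths(succ), n_instances = length(inst)),
    class = "debruijn_graph"
  )
}

# sequence spelled by a vector of oriented node encodings
path_sequence <- function(graph, path) {
  i <- enc_id(path)
  kmers <- graph$nodes[i]
  minus <- path %% 2L == 0L
  if (any(minus)) kmers[minus] <- revcomp(kmers[minus])
  if (length(kmers) == 1) return(kmers)
  paste0(kmers[1], paste(substr(kmers[-1], graph$k, graph$k), collapse = ""))
}

# one unambiguous step: the unique successor, provided the step is the
# unique out-edge of `cur` and the unique in-edge of the successor
step_unambiguous <- function(graph, cur) {
  if (graph$outdeg[cur] != 1L) return(NA_integer_)
  nxt <- graph$succ[[cur]][1]
  if (graph$outdeg[enc_flip(nxt)] != 1L) return(NA_integer_) # indeg(nxt) != 1
  nxt
}

#' Extract contigs as maximal unambiguous paths
#'
#' A contig is a maximal path whose interior nodes have in-degree and
#' out-degree one; paths terminate at branches (never choosing a branch
#' arbitrarily). Contigs shorter than `min_contig_len` are dropped. Output
#' sequences are reported on the canonical strand and sorted by decreasing
#' length for deterministic ids.
#'
#' @param graph A [build_graph()] result.
#' @param cfg An [assembly_config()].
#' @return Tibble with columns `id`, `sequence`, `length`, `support`
#'   (mean k-mer coverage, rounded).
#' @export
extract_contigs <- function(graph, cfg = assembly_config()) {
  n <- length(graph$nodes)
  empty <- tibble(id = character(0), sequence = character(0),
                  length = integer(0), support = numeric(0))
  if (n == 0) return(empty)
  outdeg <- graph$outdeg
  indeg <- outdeg[vapply(seq_len(2L * n), enc_flip, integer(1))]
  visited <- logical(n)
  paths <- list()

  is_start <- vapply(seq_len(2L * n), function(u) {
    if (indeg[u] != 1L) return(TRUE)
    # unique predecessor: p -> u  <=>  flip(u) -> flip(p)
    p <- enc_flip(graph$succ[[enc_flip(u)]][1])
    outdeg[p] != 1L
  }, logical(1))

  walk_from <- function(u) {
    path <- u
    repeat {
      nxt <- step_unambiguous(graph, path[length(path)])
      if (is.na(nxt) || nxt %in% path || enc_flip(nxt) %in% path) break
      path <- c(path, nxt)
    }
    path
  }

  for (u in which(is_start)) {
    ids <- enc_id(u)
    if (visited[ids]) next
    path <- walk_from(u)
    visited[enc_id(path)] <- TRUE
    paths[[length(paths) + 1L]] <- path
  }
  # isolated cycles (every node in/out degree 1): walk until return
  for (u in seq(1L, 2L * n, by = 2L)) {
    if (visited[enc_id(u)]) next
    path <- u
    repeat {
      nxt <- graph$succ[[path[length(path)]]][1]
      if (is.na(nxt) || nxt == u || enc_id(nxt) %in% enc_id(path)) break
      path <- c(path, nxt)
    }
    visited[enc_id(path)] <- TRUE
    paths[[length(paths) + 1L]] <- path
  }
  seqs <- vapply(paths, function(p) path_sequence(graph, p), character(1))
  seqs <- canonical(seqs)
  support <- vapply(paths, function(p) {
    round(mean(graph$counts[enc_id(p)]))
  }, numeric(1))
  keep <- !duplicated(seqs) & nchar(seqs) >= cfg$min_contig_len
  if (!any(keep)) return(empty)
  ord <- order(-nchar(seqs[keep]), seqs[keep])
  tibble(
    id = sprintf("CTG%05d", seq_along(ord)),
    sequence = seqs[keep][ord],
    length = nchar(seqs[keep][ord]),
    support = support[keep][ord]
  )
}

# exact full-length mapping of reads onto reference sequences.
# Returns one row per (read, window) hit with the position in the matched
# strand's coordinates; `strand == "-"` means the read matched the reverse
# complement of the stored sequence.
map_exact <- function(reads, refs, unique_only = FALSE) {
  hits_empty <- tibble(id = character(0), mate = integer(0),
                       ref = character(0), strand = character(0),
                       pos = integer(0), ref_len = integer(0))
  if (nrow(reads) == 0 || nrow(refs) == 0) return(hits_empty)
  out <- list()
  for (L in unique(nchar(reads$bases))) {
    rd <- reads[nchar(reads$bases) == L, ]
    idx <- purrr::map2(refs$id, refs$sequence, function(id, s) {
      w_f <- seq_windows(s, L)
      w_r <- seq_windows(revcomp(s), L)
      tibble(
        ref = id, ref_len = nchar(s),
        strand = rep(c("+", "-"), c(length(w_f), length(w_r))),
        pos = c(seq_along(w_f), seq_along(w_r)),
        window = c(w_f, w_r)
      )
    }) |> bind_rows()
    m <- inner_join(
      select(rd, "id", "mate", window = "bases"), idx,
      by = "window", relationship = "many-to-many"
    )
    out[[length(out) + 1L]] <- select(m, -"window")
  }
  hits <- bind_rows(out)
  if (unique_only && nrow(hits) > 0) {
    hits <- hits |>
      group_by(.data$id, .data$mate) |>
      filter(n() == 1L) |>
      ungroup()
  }
  hits
}

# spell out a scaffold sequence from oriented member sequences and gap fills
scaffold_sequence <- function(members) {
  pieces <- character(0)
  for (i in seq_len(nrow(members))) {
    pieces <- c(pieces, members$oriented_sequence[i])
    if (!is.na(members$gap_after[i])) {
      fill <- members$gap_fill[i]
      pieces <- c(pieces,
                  if (is.na(fill)) strrep("N", members$gap_after[i]) else fill)
    }
  }
  paste(pieces, collapse = "")
}

rebuild_scaffolds <- function(members_list) {
  seqs <- vapply(members_list, scaffold_sequence, character(1))
  tibble(
    id = sprintf("SCF%05d", seq_along(members_list)),
    sequence = seqs, length = nchar(seqs),
    n_contigs = vapply(members_list, nrow, integer(1)),
    members = members_list
  )
}

#' Link contigs into scaffolds using paired-end information
#'
#' Clean read pairs are mapped back to the contigs by exact full-length
#' matching. Pairs whose mates map uniquely to two different contigs vote for
#' a link between the corresponding contig ends; a link is accepted when at
#' least `min_pair_links` pairs support it in a consistent relative
#' orientation. The unknown interspace between linked contigs is written as a
#' run of Ns whose length is the rounded mean, over supporting pairs, of
#' `insert_mean` minus the two observed flank spans (floored at 1 bp).
#' Contigs whose link pattern branches are left unscaffolded, and bundles
#' with contradictory orientations are discarded with a message.
#'
#' @param contigs Contig tibble from [extract_contigs()].
#' @param reads Clean paired read tibble (both mates, shared `id`).
#' @param cfg An [assembly_config()].
#' @param insert_mean Library fragment-size mean used for gap estimation (bp).
#' @return List with `scaffolds` (tibble: `id`, `sequence`, `length`,
#'   `n_contigs`, `members` list-column) and `unscaffolded` (contig tibble).
#' @export
scaffold_contigs <- function(contigs, reads, cfg = assembly_config(),
                             insert_mean = 200) {
  no_scaf <- list(
    scaffolds = rebuild_scaffolds(list())[0, ],
    unscaffolded = contigs
  )
  if (nrow(contigs) < 2 || nrow(reads) == 0) return(no_scaf)
  hits <- map_exact(reads, contigs, unique_only = TRUE)
  if (nrow(hits) == 0) return(no_scaf)
  m1 <- filter(hits, .data$mate == 1L)
  m2 <- filter(hits, .data$mate == 2L)
  pairs <- inner_join(m1, m2, by = "id", suffix = c("_1", "_2")) |>
    filter(.data$ref_1 != .data$ref_2)
  if (nrow(pairs) == 0) return(no_scaf)

  rl <- nchar(reads$bases[1])
  links <- pairs |>
    mutate(
      a = .data$ref_1, oa = .data$strand_1,
      b = .data$ref_2, ob = if_else(.data$strand_2 == "+", "-", "+"),
      da = .data$ref_len_1 - .data$pos_1 + 1L,
      db = .data$ref_len_2 - .data$pos_2 + 1L,
      gap = insert_mean - .data$da - .data$db
    )
  # canonical bundle representation: a directed oriented link and its
  # reverse complement describe the same junction
  key1 <- paste(links$a, links$oa, links$b, links$ob)
  flip <- function(o) if_else(o == "+", "-", "+")
  key2 <- paste(links$b, flip(links$ob), links$a, flip(links$oa))
  use2 <- key2 < key1
  links <- mutate(
    links,
    ca = if_else(use2, .data$b, .data$a),
    coa = if_else(use2, flip(.data$ob), .data$oa),
    cb = if_else(use2, .data$a, .data$b),
    cob = if_else(use2, flip(.data$oa), .data$ob)
  )
  # contradictory orientations within an unordered contig pair: discard
  pair_key <- paste(pmin(links$ca, links$cb), pmax(links$ca, links$cb))
  bad_pairs <- tibble(pair_key = pair_key,
                      okey = paste(links$ca, links$coa, links$cb, links$cob)) |>
    distinct() |> count(.data$pair_key) |> filter(.data$n > 1)
  if (nrow(bad_pairs) > 0) {
    inform(sprintf(
      "discarding %d contig pair(s) with contradictory link orientations",
      nrow(bad_pairs)
    ))
    links <- links[!pair_key %in% bad_pairs$pair_key, ]
  }
  bundles <- links |>
    group_by(.data$ca, .data$coa, .data$cb, .data$cob) |>
    summarise(n_links = n(),
              gap = as.integer(max(1, round_half_up(mean(.data$gap)))),
              .groups = "drop") |>
    filter(.data$n_links >= cfg$min_pair_links)
  if (nrow(bundles) == 0) return(no_scaf)

  # an oriented link leaves the "tail" end of (ca, coa) and enters the
  # "head" end of (cb, cob); any end used by more than one bundle is a branch
  end_out <- paste(bundles$ca, if_else(bundles$coa == "+", "E2", "E1"))
  end_in <- paste(bundles$cb, if_else(bundles$cob == "+", "E1", "E2"))
  end_use <- table(c(end_out, end_in))
  branched <- names(end_use)[end_use > 1]
  keep <- !(end_out %in% branched | end_in %in% branched)
  bundles <- bundles[keep, ]
  if (nrow(bundles) == 0) return(no_scaf)

  # traverse simple paths in the oriented link graph
  g <- igraph::graph_from_data_frame(
    tibble(from = bundles$ca, to = bundles$cb),
    directed = FALSE,
    vertices = unique(c(bundles$ca, bundles$cb))
  )
  comp <- igraph::components(g)
  seq_of <- setNames(contigs$sequence, contigs$id)
  len_of <- setNames(contigs$length, contigs$id)
  members_list <- list()
  used <- character(0)
  for (ci in seq_len(comp$no)) {
    cids <- names(comp$membership)[comp$membership == ci]
    sub <- bundles[bundles$ca %in% cids | bundles$cb %in% cids, ]
    deg <- table(c(sub$ca, sub$cb))
    terms <- names(deg)[deg == 1]
    if (length(terms) == 0) next # cyclic component: leave unscaffolded
    # orient the path starting from a terminal contig
    start <- sort(terms)[1]
    chain <- list()
    cur <- start
    cur_or <- NULL
    prev_gap <- NULL
    remaining <- sub
    # starting orientation: as stored if the first bundle leaves cur's ca
    first <- remaining[remaining$ca == cur | remaining$cb == cur, ][1, ]
    cur_or <- if (first$ca == cur) first$coa else flip(first$cob)
    repeat {
      hit <- remaining[remaining$ca == cur | remaining$cb == cur, ]
      if (nrow(hit) == 0) {
        chain[[length(chain) + 1L]] <- list(id = cur, or = cur_or, gap = NA_integer_)
        break
      }
      b <- hit[1, ]
      remaining <- anti_join(remaining, b,
                             by = c("ca", "coa", "cb", "cob"))
      if (b$ca == cur) {
        nxt <- b$cb; nxt_or <- b$cob
      } else {
        nxt <- b$ca; nxt_or <- flip(b$coa)
      }
      chain[[length(chain) + 1L]] <- list(id = cur, or = cur_or, gap = b$gap)
      cur <- nxt; cur_or <- nxt_or
    }
    mem <- tibble(
      contig = vapply(chain, `[[`, character(1), "id"),
      orientation = vapply(chain, `[[`, character(1), "or"),
      gap_after = vapply(chain, `[[`, integer(1), "gap"),
      gap_fill = NA_character_
    ) |>
      mutate(oriented_sequence = if_else(
        .data$orientation == "+", seq_of[.data$contig],
        revcomp(seq_of[.data$contig])
      )) |>
      select("contig", "orientation", "oriented_sequence",
             "gap_after", "gap_fill")
    members_list[[length(members_list) + 1L]] <- mem
    used <- c(used, mem$contig)
  }
  list(
    scaffolds = rebuild_scaffolds(members_list),
    unscaffolded = filter(contigs, !.data$id %in% used)
  )
}

# walk the read graph from `from_kmer` along unique out-edges; stop on a
# branch, a dead end, the step cap, or (if given) upon spelling `to_kmer`
walk_fill <- function(graph, from_kmer, to_kmer, max_steps) {
  cw <- canonical(from_kmer)
  i <- match(cw, graph$nodes)
  if (is.na(i)) return(NULL)
  cur <- enc_node(i, plus = from_kmer == cw)
  ext <- from_kmer
  for (s in seq_len(max_steps)) {
    if (graph$outdeg[cur] != 1L) return(NULL)
    cur <- graph$succ[[cur]][1]
    km <- graph$nodes[enc_id(cur)]
    if (cur %% 2L == 0L) km <- revcomp(km)
    ext <- paste0(ext, substr(km, graph$k, graph$k))
    if (!is.null(to_kmer) && km == to_kmer) return(ext)
  }
  NULL
}

#' Fill scaffold gaps from the reads
#'
#' For each N gap, the read-level de Bruijn graph is walked from the last
#' k-mer of the left flank along unique extensions; if the walk reaches the
#' first k-mer of the right flank within the expected span, the gap Ns are
#' replaced by the walked consensus. Branching walks (conflicting read
#' tilings) and unreachable flanks leave the gap untouched, so the total
#' number of Ns never increases.
#'
#' @param scaffolding A [scaffold_contigs()] result.
#' @param reads Clean read tibble.
#' @param cfg An [assembly_config()].
#' @param graph Optional prebuilt [build_graph()] of `reads` (rebuilt when
#'   omitted).
#' @return The scaffolding list with updated scaffold sequences.
#' @export
fill_gaps <- function(scaffolding, reads, cfg = assembly_config(),
                      graph = NULL) {
  scaf <- scaffolding$scaffolds
  if (nrow(scaf) == 0 || nrow(reads) == 0) return(scaffolding)
  if (is.null(graph)) graph <- build_graph(reads$bases, cfg$k, cfg$min_kmer_cov)
  k <- cfg$k
  members_list <- scaf$members
  for (si in seq_along(members_list)) {
    mem <- members_list[[si]]
    for (gi in seq_len(nrow(mem) - 1L)) {
      if (is.na(mem$gap_after[gi]) || !is.na(mem$gap_fill[gi])) next
      left <- mem$oriented_sequence[gi]
      right <- mem$oriented_sequence[gi + 1L]
      from_kmer <- substr(left, nchar(left) - k + 1L, nchar(left))
      to_kmer <- substr(right, 1L, k)
      ext <- walk_fill(graph, from_kmer, to_kmer,
                       max_steps = mem$gap_after[gi] + k + 100L)
      if (!is.null(ext)) {
        # bases strictly between the two flank k-mers
        fill <- substr(ext, k + 1L, nchar(ext) - k)
        mem$gap_fill[gi] <- fill
        mem$gap_after[gi] <- nchar(fill)
      }
    }
    members_list[[si]] <- mem
  }
  out <- rebuild_scaffolds(members_list)
  out$id <- scaf$id
  list(scaffolds = out, unscaffolded = scaffolding$unscaffolded)
}

#' Define unigenes for one phase
#'
#' Gap-filled scaffolds and unscaffolded contigs become unigenes after the
#' extension closure: each end is extended along the read graph while a
#' unique single path exists (the same unambiguity rule used for contigs),
#' so no read in the library can extend a unigene further.
#'
#' @param scaffolding A [fill_gaps()] (or [scaffold_contigs()]) result.
#' @param reads Clean read tibble for the phase.
#' @param cfg An [assembly_config()].
#' @param phase 1 or 2, recorded as `phase_origin`.
#' @param graph Optional prebuilt [build_graph()] of `reads`.
#' @return Tibble: `id`, `sequence`, `length`, `n_ambiguous` (residual Ns),
#'   `phase_origin`, `provenance` (list of source scaffold/contig ids).
#' @export
define_unigenes <- function(scaffolding, reads, cfg = assembly_config(),
                            phase = 1L, graph = NULL) {
  src <- bind_rows(
    select(scaffolding$scaffolds, "id", "sequence"),
    select(scaffolding$unscaffolded, "id", "sequence")
  )
  if (nrow(src) == 0) {
    return(tibble(id = character(0), sequence = character(0),
                  length = integer(0), n_ambiguous = integer(0),
                  phase_origin = integer(0), provenance = list()))
  }
  if (is.null(graph) && nrow(reads) > 0) {
    graph <- build_graph(reads$bases, cfg$k, cfg$min_kmer_cov)
  }
  k <- cfg$k
  extend_right <- function(s) {
    if (is.null(graph)) return(s)
    tail_kmer <- substr(s, nchar(s) - k + 1L, nchar(s))
    if (grepl("N", tail_kmer, fixed = TRUE)) return(s)
    cw <- canonical(tail_kmer)
    i <- match(cw, graph$nodes)
    if (is.na(i)) return(s)
    cur <- enc_node(i, plus = tail_kmer == cw)
    for (step in seq_len(100000L)) {
      nxt <- step_unambiguous(graph, cur)
      if (is.na(nxt)) break
      km <- graph$nodes[enc_id(nxt)]
      if (nxt %% 2L == 0L) km <- revcomp(km)
      s <- paste0(s, substr(km, k, k))
      cur <- nxt
    }
    s
  }
  seqs <- vapply(src$sequence, function(s) {
    s <- extend_right(s)
    revcomp(extend_right(revcomp(s)))
  }, character(1), USE.NAMES = FALSE)
  ord <- order(-nchar(seqs), seqs)
  tibble(
    id = sprintf("P%dU%05d", phase, seq_along(ord)),
    sequence = seqs[ord],
    length = nchar(seqs[ord]),
    n_ambiguous = stringr::str_count(seqs[ord], "N"),
    phase_origin = as.integer(phase),
    provenance = as.list(src$id[ord])
  )
}

# do two sequences meet the clustering criterion (local alignment in either
# orientation with the required identity and overlap)?
align_linked <- function(s1, s2, min_identity, min_overlap) {
  for (s2x in c(s2, revcomp(s2))) {
    al <- Biostrings::pairwiseAlignment(s1, s2x, type = "local")
    if (Biostrings::nchar(al) >= min_overlap &&
        Biostrings::pid(al) >= 100 * min_identity) {
      return(TRUE)
    }
  }
  FALSE
}

#' Cluster unigenes from both phases into distinct sequences
#'
#' Greedy single-linkage clustering: two unigenes are joined when a local
#' alignment (either orientation) reaches `min_cluster_identity` over at
#' least `min_cluster_overlap` bases; clusters are the connected components
#' of that relation, and each cluster is represented by its longest member.
#'
#' @param unigenes Combined unigene tibble from both phases (columns `id`,
#'   `sequence`, `length`, `phase_origin`).
#' @param cfg An [assembly_config()].
#' @return List of class `cluster_set`: `clusters` (tibble `unigene`,
#'   `cluster`, `representative`) and `all_unigenes` (tibble of distinct
#'   sequences: `id`, `sequence`, `length`, `phase_origin` in
#'   `{"1", "2", "both"}`, `members` list-column).
#' @export
cluster_unigenes <- function(unigenes, cfg = assembly_config()) {
  assert_that(nrow(unigenes) >= 1, "need at least one unigene")
  n <- nrow(unigenes)
  edges <- NULL
  if (n > 1) {
    cand <- t(utils::combn(n, 2))
    # seed prefilter: a pair meeting the identity floor over the minimum
    # overlap almost surely shares an exact 11-bp word; skip pairs that do
    # not (seed-and-extend, as clustering tools do)
    w <- 11L
    words <- lapply(unigenes$sequence, function(s) {
      unique(canonical(seq_windows(s, w)))
    })
    share <- vapply(seq_len(nrow(cand)), function(r) {
      any(words[[cand[r, 1]]] %in% words[[cand[r, 2]]])
    }, logical(1))
    cand <- cand[share, , drop = FALSE]
    hit <- vapply(seq_len(nrow(cand)), function(r) {
      s1 <- unigenes$sequence[cand[r, 1]]
      s2 <- unigenes$sequence[cand[r, 2]]
      if (s1 == s2 || s1 == revcomp(s2)) return(TRUE)
      align_linked(s1, s2, cfg$min_cluster_identity, cfg$min_cluster_overlap)
    }, logical(1))
    edges <- cand[hit, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  memb <- igraph::components(g)$membership
  clusters <- tibble(
    unigene = unigenes$id, cluster = memb,
    length = unigenes$length, phase_origin = unigenes$phase_origin
  ) |>
    group_by(.data$cluster) |>
    mutate(representative = rank(-.data$length, ties.method = "first") == 1L) |>
    ungroup()
  reps <- clusters |>
    filter(.data$representative) |>
    left_join(select(unigenes, "id", "sequence"), by = c(unigene = "id"))
  origin <- clusters |>
    group_by(.data$cluster) |>
    summarise(phase_origin = if (dplyr::n_distinct(.data$phase_origin) > 1)
      "both" else as.character(.data$phase_origin[1]))
  members <- split(clusters$unigene, clusters$cluster)
  reps <- left_join(reps, origin, by = "cluster",
                    suffix = c("_rep", "")) |>
    arrange(-.data$length, .data$unigene)
  all_unigenes <- tibble(
    id = sprintf("UN%05d", seq_len(nrow(reps))),
    source_unigene = reps$unigene,
    sequence = reps$sequence,
    length = reps$length,
    phase_origin = reps$phase_origin,
    members = unname(members[as.character(reps$cluster)])
  )
  structure(
    list(
      clusters = select(clusters, "unigene", "cluster", "representative"),
      all_unigenes = all_unigenes
    ),
    class = "cluster_set"
  )
}

#' Assemble one phase end to end
#'
#' Convenience wrapper: de Bruijn graph, contigs, paired-end scaffolds, gap
#' filling and unigene definition in one call.
#'
#' @param reads Clean paired read tibble for one phase.
#' @param cfg An [assembly_config()].
#' @param phase Phase label (1 or 2).
#' @param insert_mean Fragment-size mean for gap estimation (bp).
#' @return List with `contigs`, `scaffolding` and `unigenes`.
#' @export
assemble_phase <- function(reads, cfg = assembly_config(), phase = 1L,
                           insert_mean = 200) {
  graph <- build_graph(reads$bases, cfg$k, cfg$min_kmer_cov)
  contigs <- extract_contigs(graph, cfg)
  scaffolding <- scaffold_contigs(contigs, reads, cfg, insert_mean)
  scaffolding <- fill_gaps(scaffolding, reads, cfg, graph)
  unigenes <- define_unigenes(scaffolding, reads, cfg, phase, graph)
  list(contigs = contigs, scaffolding = scaffolding, unigenes = unigenes)
}
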