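new_ontology_dag <- function(terms, edges,
                             names = setNames(terms, terms)) {
  edges <- as_tibble(edges)
  stopifnot(all(c("child", "parent", "rel") %in% colnames(edges)))
  missing <- setdiff(unique(c(edges$child, edges$parent)), terms)
  if (length(missing) > 0) {
    abort(sprintf("edge references unknown term(s): %s",
                  paste(head(missing, 3), collapse = ", ")))
  }
  # acyclicity check through igraph
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       vertices = terms)
    if (!igraph::is_dag(g)) abort("ontology edges contain a cycle")
  }
  structure(
    list(terms = terms, edges = edges, names = names),
    class = "ontology_dag"
  )
}

#' Read a minimal OBO 1.2 ontology file
#'
#' Supports the subset needed for term DAGs: `[Term]` stanzas with `id:`,
#' `name:`, `is_a:` and `relationship: part_of` lines. `is_a` and `part_of`
#' are both treated as parent links for ancestor closure, which is how slim
#' mapping conventionally traverses the Gene Ontology graph.
#'
#' @param path Path to an OBO file.
#' @return An `ontology_dag`: list with `terms` (character), `edges`
#'   (tibble `child`, `parent`, `rel`) and `names` (named character).
#' @export
read_obo <- function(path) {
  lines <- readr::read_lines(path)
  in_term <- FALSE
  cur <- NULL
  terms <- character(0)
  names <- character(0)
  ch <- character(0); pa <- character(0); rel <- character(0)
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") { in_term <- TRUE; cur <- NULL; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term || ln == "") next
    if (grepl("^id:", ln)) {
      cur <- trimws(sub("^id:", "", ln))
      terms <- c(terms, cur)
      names[cur] <- cur
    } else if (grepl("^name:", ln) && !is.null(cur)) {
      names[cur] <- trimws(sub("^name:", "", ln))
    } else if (grepl("^is_a:", ln) && !is.null(cur)) {
      ch <- c(ch, cur); pa <- c(pa, trimws(sub("^is_a:", "", ln)))
      rel <- c(rel, "is_a")
    } else if (grepl("^relationship:\\s*part_of", ln) && !is.null(cur)) {
      ch <- c(ch, cur)
      pa <- c(pa, trimws(sub("^relationship:\\s*part_of", "", ln)))
      rel <- c(rel, "part_of")
    }
  }
  new_ontology_dag(terms, tibble(child = ch, parent = pa, rel = rel), names)
}

#' Write an ontology DAG as a minimal OBO 1.2 file
#'
#' @param dag An `ontology_dag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  out <- c("format-version: 1.2", "")
  for (t in dag$terms) {
    e <- dag$edges[dag$edges$child == t, ]
    stanza <- c(
      "[Term]",
      paste0("id: ", t),
      paste0("name: ", dag$names[[t]]),
      if (nrow(e) > 0) ifelse(
        e$rel == "is_a",
        paste0("is_a: ", e$parent),
        paste0("relationship: part_of ", e$parent)
      ),
      ""
    )
    out <- c(out, stanza)
  }
  readr::write_lines(out, path)
  invisible(path)
}

# parent lookup: list mapping term -> character vector of parents
parent_map <- function(dag) {
  pm <- split(dag$edges$parent, dag$edges$child)
  lapply(setNames(dag$terms, dag$terms), function(t) {
    unique(pm[[t]] %||% character(0))
  })
}

# minimal slim ancestors of a single term: on every upward path the first
# slim term encountered (counting the start term itself) absorbs the path,
# so nearer slim terms shadow their own slim ancestors. A slim start term
# therefore maps to exactly itself.
slim_ancestors <- function(term, parents, slim_set) {
  if (term %in% slim_set) return(term)
  found <- character(0)
  frontier <- term
  seen <- character(0)
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (t in frontier) {
      if (t %in% slim_set) {
        found <- c(found, t) # absorbing: do not expand beyond a slim node
        next
      }
      nxt <- c(nxt, parents[[t]])
    }
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(nxt), seen)
  }
  sort(unique(found))
}

#' Map term assignments to their nearest slim terms
#'
#' Implements the conventional slim-mapping semantics: each upward path from
#' an assigned term (following `is_a` and `part_of`) contributes the first
#' slim term it encounters, counting the term itself. Nearer slim terms
#' therefore shadow their own slim ancestors path by path, and a term that
#' is itself in the slim maps to exactly itself.
#'
#' @param assignments Tibble with `gene` and `term` columns.
#' @param dag An `ontology_dag` containing every assigned term.
#' @param slim Character vector of slim term ids (subset of the DAG terms).
#' @return Tibble with `gene` and `slim_term`, one row per distinct pair.
#' @export
map_to_slim <- function(assignments, dag, slim) {
  bad <- setdiff(unique(assignments$term), dag$terms)
  if (length(bad) > 0) {
    abort(sprintf("term(s) absent from the ontology: %s",
                  paste(head(bad, 3), collapse = ", ")))
  }
  assert_that(all(slim %in% dag$terms), "slim must be a subset of the DAG terms")
  parents <- parent_map(dag)
  uniq_terms <- unique(assignments$term)
  slim_of <- lapply(setNames(uniq_terms, uniq_terms), slim_ancestors,
                    parents = parents, slim_set = slim)
  assignments |>
    mutate(slim_term = slim_of[.data$term]) |>
    select("gene", "slim_term") |>
    tidyr::unnest("slim_term") |>
    distinct()
}
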