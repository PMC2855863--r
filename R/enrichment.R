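#' Parse an OBO 1.2 ontology
#'
#' Minimal flat-file OBO reader for enrichment analysis: only `[Term]`
#' stanzas and the `id`, `name`, `namespace`, `is_a` and `is_obsolete` tags
#' are honored (`part_of` and other relationships are ignored by design —
#' the annotation closure uses `is_a` only). Obsolete terms are dropped.
#' The `is_a` graph is validated to be acyclic with no dangling targets, and
#' each term's depth is derived as the longest `is_a` path from a root.
#'
#' @param path Path to an OBO file.
#' @return An object of class `ontology`: a list with `terms` (tibble
#'   `term_id`, `name`, `namespace`, `depth`), `parents` (named list of
#'   character vectors), `children` and `roots`.
#' @export
parse_obo <- function(path) {
  lines <- readr::read_lines(path)
  stanza_starts <- grep("^\\[", lines)
  if (length(stanza_starts) == 0) abort("no stanzas found in OBO file")
  bounds <- c(stanza_starts, length(lines) + 1)
  terms <- list()
  for (k in seq_along(stanza_starts)) {
    if (lines[stanza_starts[k]] != "[Term]") next
    body <- lines[seq(stanza_starts[k] + 1, bounds[k + 1] - 1)]
    tag <- sub(":.*$", "", body)
    val <- trimws(sub("^[^:]+:", "", body))
    get1 <- function(t) if (any(tag == t)) val[tag == t][1] else NA_character_
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) abort("[Term] stanza without an id")
    is_a <- sub("\\s*!.*$", "", val[tag == "is_a"])
    terms[[id]] <- list(id = id, name = get1("name"),
                        namespace = get1("namespace"), parents = is_a)
  }
  build_ontology(
    tibble(
      term_id = unname(vapply(terms, `[[`, "", "id")),
      name = unname(vapply(terms, `[[`, "", "name")),
      namespace = unname(vapply(terms, `[[`, "", "namespace"))
    ),
    lapply(terms, `[[`, "parents")
  )
}

#' Assemble an ontology from term and edge lists
#'
#' Used both by [parse_obo()] and by the synthetic ontology generator.
#' Validates the `is_a` DAG (no dangling parents, acyclic) and computes
#' longest-path depths.
#'
#' @param terms Tibble with `term_id`, `name`, `namespace`.
#' @param parents Named list: term id -> character vector of parent ids.
#' @return An `ontology` object.
#' @export
build_ontology <- function(terms, parents) {
  ids <- terms$term_id
  if (anyDuplicated(ids)) abort("duplicate term ids")
  parents <- parents[ids]
  names(parents) <- ids
  parents <- lapply(parents, function(p) p %||% character())
  dangling <- setdiff(unlist(parents), ids)
  if (length(dangling) > 0) {
    abort(paste0("is_a target(s) not defined (or obsolete): ",
                 toString(head(dangling, 5))))
  }
  # Kahn topological sort from the roots; leftovers indicate a cycle
  n_par <- vapply(parents, length, 0L)
  children <- vector("list", length(ids))
  names(children) <- ids
  for (id in ids) for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  depth <- setNames(rep(NA_real_, length(ids)), ids)
  queue <- ids[n_par == 0]
  depth[queue] <- 0
  remaining <- n_par
  order <- character(0)
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      depth[ch] <- max(depth[ch], depth[v] + 1, na.rm = TRUE)
      remaining[ch] <- remaining[ch] - 1
      if (remaining[ch] == 0) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(ids)) {
    cyc <- setdiff(ids, order)
    abort(paste0("cycle in is_a graph involving: ", toString(head(cyc, 10))))
  }
  terms$depth <- as.numeric(depth[terms$term_id])
  structure(
    list(terms = terms, parents = parents, children = children,
         roots = unname(ids[n_par == 0]), topo_order = order),
    class = "ontology"
  )
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("Ontology: %d terms, %d root(s), max depth %d\n",
              nrow(x$terms), length(x$roots), max(x$terms$depth)))
  invisible(x)
}

#' Ancestors of a term (is_a closure, excluding the term itself)
#'
#' @param ontology An `ontology`.
#' @param term_id A term id.
#' @return Character vector of ancestor ids.
#' @export
term_ancestors <- function(ontology, term_id) {
  out <- character(0)
  frontier <- ontology$parents[[term_id]]
  while (length(frontier) > 0) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(ontology$parents[frontier])), out)
  }
  out
}

#' Propagate direct annotations up the ontology (true-path rule)
#'
#' Every gene directly annotated to a term is also annotated to all of the
#' term's `is_a` ancestors, with set semantics (a gene reaching a term
#' through several paths, e.g. both branches of a diamond, is counted once).
#'
#' @param ontology An `ontology`.
#' @param annotations Tibble `gene_id`, `term_id` of direct annotations.
#' @return Tibble `gene_id`, `term_id` — the propagated closure (a superset
#'   of the direct annotations).
#' @export
propagate_annotations <- function(ontology, annotations) {
  unknown <- setdiff(unique(annotations$term_id), ontology$terms$term_id)
  if (length(unknown) > 0) {
    abort(paste0("annotation(s) to unknown term(s): ",
                 toString(head(unknown, 5))))
  }
  anc <- lapply(setNames(nm = unique(annotations$term_id)),
                function(t) c(t, term_ancestors(ontology, t)))
  annotations |>
    distinct(.data$gene_id, .data$term_id) |>
    mutate(term_id = anc[.data$term_id]) |>
    tidyr::unnest("term_id") |>
    distinct(.data$gene_id, .data$term_id) |>
    arrange(.data$term_id, .data$gene_id)
}

#' Hypergeometric (Fisher) test of one term
#'
#' Classic one-term over/under-representation: with a universe of `N`
#' genes, `K` annotated to the term, and a study set of size `n` containing
#' `k` term genes, the enrichment p-value is the hypergeometric upper tail
#' `P(X >= k)` and the depletion p-value the lower tail `P(X <= k)`;
#' expected is `K * n / N`.
#'
#' @param term_genes Character vector of genes annotated to the term
#'   (subset of the universe).
#' @param study Character vector, the study set (subset of the universe).
#' @param universe Character vector of all measured genes.
#' @param direction `"enriched"` or `"depleted"`.
#' @return One-row tibble `observed`, `expected`, `p_value`.
#' @export
fisher_term <- function(term_genes, study, universe,
                        direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  if (length(universe) == 0) abort("empty universe")
  if (length(setdiff(study, universe)) > 0) abort("study set not contained in universe")
  term_genes <- intersect(term_genes, universe)
  k <- length(intersect(term_genes, study))
  K <- length(term_genes)
  N <- length(universe)
  n <- length(study)
  p <- if (direction == "enriched") {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    phyper(k, K, N - K, n, lower.tail = TRUE)
  }
  tibble(observed = k, expected = K * n / N, p_value = p)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR adjustment (with monotonicity enforcement), preserving the
#' input order.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Ontology enrichment with elim decorrelation
#'
#' Tests every sufficiently annotated term for over- (or under-)
#' representation of a study set, decorrelating the ontology graph with the
#' elim algorithm: terms are processed from the deepest level upward (ties
#' broken by term id); each term's Fisher test is run after removing from
#' its annotated gene set the genes already "claimed" by its significant
#' descendants (study set and universe stay intact, so claimed genes simply
#' stop counting as annotated), and when a term's resulting p-value falls
#' below `cutoff` its propagated gene set is added to the eliminated set of
#' all its ancestors.
#' Classic (non-eliminated) p-values, observed and expected counts are
#' reported alongside, and FDR adjustment of the elim p-values is applied
#' within each namespace (mirroring per-ontology reporting blocks).
#'
#' @param ontology An `ontology`.
#' @param annotations Direct annotations (`gene_id`, `term_id`); propagated
#'   internally via [propagate_annotations()].
#' @param study Study gene set (subset of the universe).
#' @param universe All measured genes.
#' @param direction `"enriched"` or `"depleted"`.
#' @param cutoff Elim elimination threshold on the term p-value
#'   (default 0.01).
#' @param min_annotated Minimum number of annotated universe genes for a
#'   term to be tested (1 for GO-style use; 5 for anatomy-style screens
#'   where only structures expressing at least five genes are considered).
#' @return Tibble, one row per tested term: `term_id`, `name`, `namespace`,
#'   `depth`, `annotated`, `observed`, `expected`, `p_classic`, `p_elim`,
#'   `p_fdr`, `direction`, sorted by `p_elim`.
#' @export
elim_enrichment <- function(ontology, annotations, study, universe,
                            direction = c("enriched", "depleted"),
                            cutoff = 0.01, min_annotated = 1) {
  direction <- match.arg(direction)
  if (cutoff <= 0 || cutoff > 1) abort("cutoff must lie in (0, 1]")
  prop <- propagate_annotations(ontology, annotations)
  prop <- filter(prop, .data$gene_id %in% universe)
  term_genes <- split(prop$gene_id, prop$term_id)
  study <- intersect(study, universe)

  info <- ontology$terms |>
    mutate(annotated = lengths(term_genes[.data$term_id]),
           annotated = tidyr::replace_na(.data$annotated, 0L)) |>
    filter(.data$annotated >= max(min_annotated, 1L)) |>
    arrange(desc(.data$depth), .data$term_id)

  eliminated <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(info))
  for (i in seq_len(nrow(info))) {
    t <- info$term_id[i]
    genes <- term_genes[[t]]
    elim <- if (!is.null(eliminated[[t]])) eliminated[[t]] else character(0)
    classic <- fisher_term(genes, study, universe, direction)
    reduced <- fisher_term(setdiff(genes, elim), study, universe, direction)
    if (reduced$p_value < cutoff) {
      for (a in term_ancestors(ontology, t)) {
        eliminated[[a]] <- union(eliminated[[a]], genes)
      }
    }
    rows[[i]] <- tibble(
      term_id = t, name = info$name[i], namespace = info$namespace[i],
      depth = info$depth[i], annotated = info$annotated[i],
      observed = classic$observed, expected = classic$expected,
      p_classic = classic$p_value, p_elim = reduced$p_value
    )
  }
  empty <- tibble(term_id = character(), name = character(),
                  namespace = character(), depth = double(),
                  annotated = integer(), observed = integer(),
                  expected = double(), p_classic = double(),
                  p_elim = double())
  bind_rows(empty, !!!rows) |>
    mutate(p_fdr = bh_fdr(.data$p_elim), .by = "namespace") |>
    mutate(direction = direction) |>
    arrange(.data$p_elim, .data$term_id)
}

#' Write an ontology as an OBO 1.2 file
#'
#' Emits `[Term]` stanzas with `id`, `name`, `namespace` and `is_a` tags —
#' the subset understood by [parse_obo()], which round-trips the structure
#' exactly.
#'
#' @param ontology An `ontology`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_obo <- function(ontology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(ontology$terms))) {
    id <- ontology$terms$term_id[i]
    par <- ontology$parents[[id]]
    writeLines(c(
      "[Term]",
      paste0("id: ", id),
      paste0("name: ", ontology$terms$name[i]),
      paste0("namespace: ", ontology$terms$namespace[i]),
      if (length(par) > 0) paste0("is_a: ", par),
      ""
    ), con)
  }
  invisible(path)
}
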