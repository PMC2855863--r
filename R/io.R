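#' Read and write the package's TSV dialects
#'
#' Expression and call matrices are exchanged as wide TSV files with a
#' `gene_id` column followed by one column per sample, headed
#' `<stage>:<replicate>`. Values are written as decimal text with enough
#' digits to round-trip doubles bit-exactly; calls are written as `1`/`0`.
#' Stage metadata is a two-column TSV `stage<TAB>hours`.
#'
#' @param expr Long expression tibble (see [expression-data]).
#' @param values_path,calls_path Paths of the value and call matrices.
#' @param path A file path.
#' @param stages Stage metadata tibble.
#' @return `read_expression()` returns a long expression tibble;
#'   `read_stages()` a stage tibble; writers return their input invisibly.
#' @name expression-io
NULL

.wide_matrix <- function(expr, col) {
  expr |>
    mutate(sample = paste(.data$stage, .data$replicate, sep = ":")) |>
    select("gene_id", "sample", all_of(col)) |>
    tidyr::pivot_wider(names_from = "sample", values_from = all_of(col))
}

#' @rdname expression-io
#' @export
write_expression <- function(expr, values_path, calls_path) {
  validate_expression(expr)
  values <- .wide_matrix(expr, "value")
  # 17 significant digits guarantee bit-exact double round-trips
  values[-1] <- lapply(values[-1], function(x) sprintf("%.17g", x))
  readr::write_tsv(values, values_path)
  calls <- .wide_matrix(expr, "call")
  calls[-1] <- lapply(calls[-1], as.integer)
  readr::write_tsv(calls, calls_path)
  invisible(expr)
}

#' @rdname expression-io
#' @export
read_expression <- function(values_path, calls_path) {
  # read as text and convert with base R's correctly rounded strtod, so
  # that 17-digit decimal values round-trip bit-exactly
  chr <- readr::cols(.default = readr::col_character())
  values <- readr::read_tsv(values_path, show_col_types = FALSE,
                            col_types = chr)
  calls <- readr::read_tsv(calls_path, show_col_types = FALSE,
                           col_types = chr)
  if (!identical(names(values), names(calls))) {
    abort("value and call matrices have different layouts")
  }
  long <- function(x, what, f) {
    x |>
      tidyr::pivot_longer(-"gene_id", names_to = "sample",
                          values_to = what) |>
      tidyr::separate_wider_delim("sample", ":",
                                  names = c("stage", "replicate")) |>
      mutate(across(all_of(what), f))
  }
  out <- long(values, "value", as.numeric) |>
    inner_join(long(calls, "call", \(x) as.logical(as.integer(x))),
               by = c("gene_id", "stage", "replicate"))
  validate_expression(out)
  out
}

#' @rdname expression-io
#' @export
write_stages <- function(stages, path) {
  validate_stages(stages)
  readr::write_tsv(stages[c("stage", "hours")], path)
  invisible(stages)
}

#' @rdname expression-io
#' @export
read_stages <- function(path) {
  stages <- readr::read_tsv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              stage = readr::col_character(),
                              hours = readr::col_double()
                            ))
  validate_stages(stages)
  stages
}

#' Read and write two-column pair tables
#'
#' Interaction lists (`gene_a<TAB>gene_b`), one-to-one ortholog maps, and
#' miRNA target maps (`mirna<TAB>gene`) all share a two-column TSV layout.
#'
#' @param path A file path.
#' @param pairs A two-column tibble.
#' @return A tibble with the file's two character columns.
#' @name pair-io
#' @export
read_pairs <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname pair-io
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(pairs)
}

#' Normalize an interaction list
#'
#' Orders each pair lexicographically, removes duplicate pairs and
#' self-interactions, so the result satisfies the undirected-interaction-set
#' invariants (no duplicates under order normalization, no self-loops).
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @return A normalized tibble of distinct unordered pairs.
#' @export
normalize_interactions <- function(pairs) {
  a <- pmin(pairs$gene_a, pairs$gene_b)
  b <- pmax(pairs$gene_a, pairs$gene_b)
  keep <- a != b
  if (any(!keep)) warn(sprintf("dropped %d self-interaction(s)", sum(!keep)))
  out <- distinct(tibble(gene_a = a[keep], gene_b = b[keep]))
  arrange(out, .data$gene_a, .data$gene_b)
}
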