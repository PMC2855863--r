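#' Expression time courses with detection calls
#'
#' A developmental expression dataset is represented as a *long* tibble with
#' one row per (gene, stage, replicate) and columns:
#'
#' * `gene_id` — gene identifier (character),
#' * `stage` — stage label (character),
#' * `replicate` — replicate label within the stage,
#' * `value` — log2-scale expression intensity,
#' * `call` — logical present/absent detection call.
#'
#' Stage metadata travels in a separate tibble with columns `stage` and
#' `hours` (hours post fertilization, strictly increasing and positive).
#' Upstream normalization and call generation (e.g. gcRMA intensities with
#' MAS5 calls) are out of scope: values arrive already log2-normalized,
#' calls arrive precomputed.
#'
#' @param expr A long expression tibble as described above.
#' @param stages A stage metadata tibble (`stage`, `hours`).
#' @return `validate_expression()` and `validate_stages()` return their input
#'   invisibly after checking invariants, and abort with an informative
#'   message otherwise.
#' @name expression-data
NULL

#' @rdname expression-data
#' @export
validate_expression <- function(expr) {
  required <- c("gene_id", "stage", "replicate", "value", "call")
  missing <- setdiff(required, names(expr))
  if (length(missing) > 0) {
    abort(paste0("expression table lacks column(s): ", toString(missing)))
  }
  if (!is.numeric(expr$value)) abort("`value` must be numeric (log2 scale)")
  if (!is.logical(expr$call)) abort("`call` must be logical")
  if (anyNA(expr$value) || anyNA(expr$call)) {
    abort("expression values and calls must not contain NA")
  }
  key <- paste(expr$gene_id, expr$stage, expr$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicate (gene_id, stage, replicate) rows in expression table")
  }
  invisible(expr)
}

#' @rdname expression-data
#' @export
validate_stages <- function(stages) {
  if (!all(c("stage", "hours") %in% names(stages))) {
    abort("stage table needs columns `stage` and `hours`")
  }
  if (anyDuplicated(stages$stage)) abort("duplicate stage labels")
  if (any(stages$hours <= 0)) abort("stage times must be positive (hours)")
  if (is.unsorted(stages$hours, strictly = TRUE)) {
    abort("stage times must be strictly increasing")
  }
  invisible(stages)
}

#' Collapse probe-level measurements to gene level
#'
#' Many-probes-to-one-gene designs are collapsed by taking, per
#' (stage, replicate), the arithmetic mean of a gene's probe values as its
#' expression value, and calling the gene present only when *strictly more
#' than half* of its probe calls are present. Probes mapping to multiple
#' genes must be resolved (removed) upstream; `probe_map` is rejected if a
#' probe appears more than once.
#'
#' @param probe_data Long tibble with columns `probe_id`, `stage`,
#'   `replicate`, `value`, `call`.
#' @param probe_map Tibble with columns `probe_id`, `gene_id`; every probe
#'   maps to exactly one gene.
#' @param on_missing_probe What to do when a probe listed in `probe_map` has
#'   no rows in `probe_data`: `"error"` (default) names the probe and stops;
#'   `"drop"` ignores it, and genes left with no probes at all are omitted
#'   with a warning.
#' @return A long expression tibble (see [expression-data]) keyed by
#'   `gene_id`.
#' @export
collapse_probes <- function(probe_data, probe_map,
                            on_missing_probe = c("error", "drop")) {
  on_missing_probe <- match.arg(on_missing_probe)
  if (anyDuplicated(probe_map$probe_id)) {
    dup <- unique(probe_map$probe_id[duplicated(probe_map$probe_id)])
    abort(paste0("ambiguous probe -> gene mapping for: ",
                 toString(head(dup, 5)),
                 "; multi-mapping probes must be removed upstream"))
  }
  unknown <- setdiff(unique(probe_data$probe_id), probe_map$probe_id)
  if (length(unknown) > 0) {
    abort(paste0("probe(s) absent from probe_map: ", toString(head(unknown, 5))))
  }
  absent <- setdiff(probe_map$probe_id, unique(probe_data$probe_id))
  if (length(absent) > 0) {
    if (on_missing_probe == "error") {
      abort(paste0("probe(s) in probe_map but absent from the matrix: ",
                   toString(head(absent, 5))))
    }
    lost <- setdiff(probe_map$gene_id,
                    probe_map$gene_id[!probe_map$probe_id %in% absent])
    if (length(lost) > 0) {
      warn(paste0("gene(s) with no measured probes omitted: ",
                  toString(head(lost, 5))))
    }
  }
  probe_data |>
    inner_join(probe_map, by = "probe_id") |>
    summarise(
      value = mean(.data$value),
      call = mean(.data$call) > 0.5,
      .by = c("gene_id", "stage", "replicate")
    ) |>
    arrange(.data$gene_id, .data$stage, .data$replicate)
}

#' Count expressed genes of a set per stage
#'
#' For a gene set, counts how many members carry a present call in each
#' replicate of each stage, and averages the per-replicate counts within the
#' stage (the per-stage summary used for trend fitting).
#'
#' @param expr Long expression tibble (see [expression-data]).
#' @param genes Character vector of member gene ids; must be non-empty and
#'   contained in the dataset.
#' @return Tibble with one row per (stage, replicate): `stage`, `replicate`,
#'   `count` (integer) and `mean_count` (mean over the stage's replicates,
#'   repeated within the stage).
#' @export
count_expressed <- function(expr, genes) {
  genes <- unique(genes)
  if (length(genes) == 0) abort("gene set is empty")
  outside <- setdiff(genes, unique(expr$gene_id))
  if (length(outside) > 0) {
    abort(paste0("gene set members absent from dataset: ",
                 toString(head(outside, 5))))
  }
  expr |>
    filter(.data$gene_id %in% genes) |>
    summarise(count = sum(.data$call), .by = c("stage", "replicate")) |>
    mutate(mean_count = mean(.data$count), .by = "stage") |>
    arrange(.data$stage, .data$replicate)
}

#' Average expression over replicates
#'
#' @param expr Long expression tibble (see [expression-data]).
#' @return Tibble `gene_id`, `stage`, `mean_value` with the arithmetic mean
#'   of the replicate values.
#' @export
mean_expression <- function(expr) {
  expr |>
    summarise(mean_value = mean(.data$value), .by = c("gene_id", "stage")) |>
    arrange(.data$gene_id, .data$stage)
}
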