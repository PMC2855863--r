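#' Gene presence per developmental metastage
#'
#' Collapses per-stage detection calls to broad developmental metastages
#' (zygote ... adult), the resolution at which stages of different species
#' can be compared: a gene counts as expressed in a metastage when it is
#' present (any replicate) at one or more stages mapping to that metastage.
#' A metastage listed in the map but containing no stage for this species is
#' reported as `NA`, not `FALSE`.
#'
#' @param expr Long expression tibble (see [expression-data]).
#' @param metastage_map Tibble with columns `stage`, `metastage` for one
#'   species; a row may have `stage = NA` to declare a metastage with no
#'   stages. Metastage order follows first appearance in the map.
#' @return Tibble `gene_id`, `metastage` (factor, ordered as in the map),
#'   `present` (logical, `NA` for empty metastages).
#' @export
metastage_presence <- function(expr, metastage_map) {
  levels <- unique(metastage_map$metastage)
  map <- filter(metastage_map, !is.na(.data$stage))
  unmapped <- setdiff(unique(expr$stage), map$stage)
  if (length(unmapped) > 0) {
    abort(paste0("stage(s) not mapped to a metastage: ", toString(unmapped)))
  }
  genes <- unique(expr$gene_id)
  observed <- expr |>
    inner_join(map, by = "stage") |>
    summarise(present = any(.data$call), .by = c("gene_id", "metastage"))
  tidyr::expand_grid(gene_id = genes, metastage = levels) |>
    left_join(observed, by = c("gene_id", "metastage")) |>
    mutate(
      present = ifelse(.data$metastage %in% observed$metastage,
                       tidyr::replace_na(.data$present, FALSE), NA),
      metastage = factor(.data$metastage, levels = levels)
    ) |>
    arrange(.data$gene_id, .data$metastage)
}

.presence_lookup <- function(presence, meta) {
  rows <- presence[as.character(presence$metastage) == meta, ]
  setNames(rows$present, rows$gene_id)
}

.rand_result_class <- function(x) {
  class(x) <- c("randomization_result", class(x))
  x
}

.perm_p_upper <- function(null, observed) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

# decode 1..choose(U,2) into (i, j), i < j, ordered by i then j
.decode_pairs <- function(codes, U) {
  cum <- cumsum((U - 1):1)
  i <- findInterval(codes - 0.5, c(0, cum))
  start <- c(0, cum)[i]
  j <- i + (codes - start)
  cbind(i, j)
}

#' Conservation of coexpression of interacting pairs across species
#'
#' For each metastage, counts the interacting pairs whose two genes are
#' expressed in species A *and* whose one-to-one orthologs are both
#' expressed in the corresponding metastage of species B, and compares this
#' with the same count for random distinct gene pairs drawn uniformly
#' (without self-pairs, resampled each repetition) from the eligible
#' universe — the ortholog-mapped genes with presence data in both species.
#' Reports the ratio of the observed count to the null mean, the 1st/99th
#' percentiles of the null counts, and an upper-tail permutation p-value
#' with the add-one convention.
#'
#' @param pairs Interaction tibble (`gene_a`, `gene_b`), ids in species A
#'   space. Pairs with an ineligible endpoint are dropped with a warning.
#' @param presence_a,presence_b Metastage presence tibbles from
#'   [metastage_presence()] for the two species.
#' @param orthologs One-to-one ortholog tibble (`gene_a` = species A id,
#'   `gene_b` = species B id); each id may appear only once.
#' @param n_rand Number of randomizations (10,000 in the motivating design).
#' @param seed Integer seed.
#' @param exclude_known_pairs Exclude the interacting pairs themselves from
#'   the random draws (default FALSE: random pairs may coincide with known
#'   interactions).
#' @return Tibble, one row per metastage: `metastage`, `observed`,
#'   `null_mean`, `null_p01`, `null_p99`, `ratio`, `p_value`, `n_pairs`,
#'   `n_rand`, `seed`, `defined`. Metastages with no stages in either
#'   species, or with a zero null mean, have `defined = FALSE` and `NA`
#'   statistics.
#' @export
ppi_conservation_ratio <- function(pairs, presence_a, presence_b, orthologs,
                                   n_rand = 10000, seed = 1,
                                   exclude_known_pairs = FALSE) {
  if (anyDuplicated(orthologs$gene_a) || anyDuplicated(orthologs$gene_b)) {
    abort("orthologs must be one-to-one: duplicated ids found")
  }
  orth <- setNames(orthologs$gene_b, orthologs$gene_a)
  eligible <- intersect(unique(presence_a$gene_id), names(orth))
  eligible <- eligible[orth[eligible] %in% unique(presence_b$gene_id)]
  eligible <- sort(eligible)
  U <- length(eligible)
  if (U < 4) abort("eligible gene universe has fewer than 4 genes")

  ok <- pairs$gene_a %in% eligible & pairs$gene_b %in% eligible
  if (any(!ok)) {
    warn(sprintf("dropped %d pair(s) with ineligible endpoints", sum(!ok)))
    pairs <- pairs[ok, ]
  }
  np <- nrow(pairs)
  if (np == 0) abort("no eligible interacting pairs")

  metas <- levels(presence_a$metastage) %||% unique(as.character(presence_a$metastage))
  idx <- setNames(seq_len(U), eligible)
  pa <- idx[pairs$gene_a]
  pb <- idx[pairs$gene_b]
  M <- U * (U - 1) / 2
  known_codes <- NULL
  if (exclude_known_pairs) {
    i <- pmin(pa, pb); j <- pmax(pa, pb)
    known_codes <- c(0, cumsum((U - 1):1))[i] + (j - i)
  }

  set.seed(seed)
  draws <- matrix(0L, np, n_rand)
  if (exclude_known_pairs) {
    allowed <- setdiff(seq_len(M), known_codes)
    for (r in seq_len(n_rand)) draws[, r] <- sample(allowed, np)
  } else {
    for (r in seq_len(n_rand)) draws[, r] <- sample.int(M, np)
  }
  ij <- .decode_pairs(as.vector(draws), U)

  purrr::map_dfr(metas, function(meta) {
    za <- .presence_lookup(presence_a, meta)[eligible]
    zb <- .presence_lookup(presence_b, meta)[orth[eligible]]
    if (all(is.na(za)) || all(is.na(zb))) {
      return(tibble(metastage = meta, observed = NA_integer_,
                    null_mean = NA_real_, null_p01 = NA_real_,
                    null_p99 = NA_real_, ratio = NA_real_,
                    p_value = NA_real_, n_pairs = np, n_rand = n_rand,
                    seed = seed, defined = FALSE))
    }
    z <- za & zb
    observed <- sum(z[pa] & z[pb])
    both <- z[ij[, 1]] & z[ij[, 2]]
    null <- colSums(matrix(both, np, n_rand))
    q <- quantile(null, c(0.01, 0.99), names = FALSE)
    nm <- mean(null)
    tibble(
      metastage = meta, observed = observed, null_mean = nm,
      null_p01 = q[1], null_p99 = q[2],
      ratio = if (nm > 0) observed / nm else NA_real_,
      p_value = .perm_p_upper(null, observed),
      n_pairs = np, n_rand = n_rand, seed = seed,
      defined = nm > 0
    )
  }) |>
    .rand_result_class()
}

#' Confidence band for conserved ortholog expression in a gene category
#'
#' For each metastage, counts the one-to-one ortholog pairs of a functional
#' category with both members expressed (species A gene in the metastage,
#' species B ortholog in the corresponding metastage), and builds a null by
#' randomly re-pairing the category's species-A genes with its species-B
#' genes (a fresh permutation of the B side each repetition). The 1st and
#' 99th percentiles of the null counts form the band; an observed count
#' above the upper band is flagged significant.
#'
#' @param category_pairs Ortholog pairs of one category (`gene_a`,
#'   `gene_b`); at least 3 pairs.
#' @inheritParams ppi_conservation_ratio
#' @return Tibble, one row per metastage, as in [ppi_conservation_ratio()]
#'   plus a `significant` flag (`observed > null_p99`).
#' @export
ortholog_conservation_band <- function(category_pairs, presence_a, presence_b,
                                       n_rand = 10000, seed = 1) {
  np <- nrow(category_pairs)
  if (np < 3) abort("category has fewer than 3 ortholog pairs")
  metas <- levels(presence_a$metastage) %||% unique(as.character(presence_a$metastage))
  set.seed(seed)
  perms <- replicate(n_rand, sample.int(np))
  purrr::map_dfr(metas, function(meta) {
    za <- unname(.presence_lookup(presence_a, meta)[category_pairs$gene_a])
    zb <- unname(.presence_lookup(presence_b, meta)[category_pairs$gene_b])
    if (all(is.na(za)) || all(is.na(zb))) {
      return(tibble(metastage = meta, observed = NA_integer_,
                    null_mean = NA_real_, null_p01 = NA_real_,
                    null_p99 = NA_real_, p_value = NA_real_,
                    significant = NA, n_pairs = np, n_rand = n_rand,
                    seed = seed, defined = FALSE))
    }
    observed <- sum(za & zb)
    null <- colSums(za & matrix(zb[perms], np, n_rand))
    q <- quantile(null, c(0.01, 0.99), names = FALSE)
    tibble(
      metastage = meta, observed = observed, null_mean = mean(null),
      null_p01 = q[1], null_p99 = q[2],
      p_value = .perm_p_upper(null, observed),
      significant = observed > q[2],
      n_pairs = np, n_rand = n_rand, seed = seed, defined = TRUE
    )
  }) |>
    .rand_result_class()
}

#' Pooled-resplit permutation test on the difference of medians
#'
#' Tests whether two gene groups differ in median expression: the observed
#' statistic is `median(values1) - median(values2)`; the null pools all
#' values and randomly re-forms two groups of the original sizes, with the
#' two-sided p-value
#' \deqn{p = \frac{1 + \#\{|null| \ge |obs|\}}{1 + n_{perm}}}
#' (add-one convention, so p is never exactly 0).
#'
#' @param values1,values2 Numeric value vectors of the two groups (each
#'   non-empty).
#' @param n_perm Number of random re-partitions.
#' @param seed Integer seed, or `NULL` to use the current RNG state (for
#'   callers that manage seeding across many tests).
#' @return One-row tibble: `observed`, `null_mean`, `null_p01`, `null_p99`,
#'   `p_value`, `n1`, `n2`, `n_perm`, `seed`.
#' @export
permutation_median_diff <- function(values1, values2, n_perm = 10000,
                                    seed = NULL) {
  n1 <- length(values1)
  n2 <- length(values2)
  if (n1 < 1 || n2 < 1) abort("both groups must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  observed <- median(values1) - median(values2)
  pooled <- c(values1, values2)
  n <- n1 + n2
  null <- vapply(seq_len(n_perm), function(r) {
    take <- sample.int(n, n1)
    median(pooled[take]) - median(pooled[-take])
  }, numeric(1))
  tol <- 1e-12 * (1 + abs(observed))
  q <- quantile(null, c(0.01, 0.99), names = FALSE)
  tibble(
    observed = observed, null_mean = mean(null),
    null_p01 = q[1], null_p99 = q[2],
    p_value = (1 + sum(abs(null) >= abs(observed) - tol)) / (1 + n_perm),
    n1 = n1, n2 = n2, n_perm = n_perm,
    seed = seed %||% NA_integer_
  ) |>
    .rand_result_class()
}

#' Genes targeted exclusively by one miRNA onset class
#'
#' Splits predicted miRNA targets into genes targeted only by early-onset
#' miRNAs and genes targeted only by late-onset miRNAs; genes targeted by
#' both classes, or by neither, are excluded.
#'
#' @param target_map Tibble `mirna`, `gene`.
#' @param early_mirnas,late_mirnas Disjoint character vectors of miRNA ids.
#' @return Tibble `gene_id`, `group` (`"early_only"` / `"late_only"`).
#' @export
classify_exclusive_targets <- function(target_map, early_mirnas, late_mirnas) {
  if (length(intersect(early_mirnas, late_mirnas)) > 0) {
    abort("early and late miRNA sets overlap")
  }
  hit <- target_map |>
    mutate(class = case_when(
      .data$mirna %in% early_mirnas ~ "early",
      .data$mirna %in% late_mirnas ~ "late",
      TRUE ~ NA_character_
    )) |>
    filter(!is.na(.data$class)) |>
    distinct(.data$gene, .data$class)
  tally <- hit |>
    summarise(
      early = any(.data$class == "early"),
      late = any(.data$class == "late"),
      .by = "gene"
    )
  tally |>
    filter(xor(.data$early, .data$late)) |>
    transmute(gene_id = .data$gene,
              group = ifelse(.data$early, "early_only", "late_only")) |>
    arrange(.data$gene_id)
}

#' Per-stage permutation test of miRNA target expression
#'
#' Runs [permutation_median_diff()] between the early-only and late-only
#' target groups independently for every (stage, replicate) of the dataset,
#' or once on per-gene medians across development (`pooled = TRUE`).
#'
#' @param expr Long expression tibble of the target genes' species.
#' @param target_groups Output of [classify_exclusive_targets()].
#' @param n_perm,seed Passed to the permutation engine; the seed is set once
#'   so the full table is reproducible.
#' @param pooled Test one across-development summary (per-gene median over
#'   all samples) instead of each time point.
#' @return Tibble of permutation results with `stage`/`replicate` columns
#'   (or a single `unit = "pooled"` row).
#' @export
target_expression_test <- function(expr, target_groups, n_perm = 10000,
                                   seed = 1, pooled = FALSE) {
  groups <- split(target_groups$gene_id, target_groups$group)
  if (length(intersect(groups$early_only, groups$late_only)) > 0) {
    abort("target groups overlap; exclusive-target contract violated")
  }
  g1 <- groups$early_only
  g2 <- groups$late_only
  if (length(g1) == 0 || length(g2) == 0) {
    abort("both exclusive target groups must be non-empty")
  }
  set.seed(seed)
  if (pooled) {
    med <- expr |>
      filter(.data$gene_id %in% c(g1, g2)) |>
      summarise(value = median(.data$value), .by = "gene_id")
    v <- setNames(med$value, med$gene_id)
    out <- permutation_median_diff(v[g1], v[g2], n_perm, seed = NULL) |>
      mutate(unit = "pooled", .before = 1)
    return(.rand_result_class(out))
  }
  cells <- distinct(expr, .data$stage, .data$replicate)
  purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    sub <- expr |>
      filter(.data$stage == cells$stage[i],
             .data$replicate == cells$replicate[i])
    v <- setNames(sub$value, sub$gene_id)
    permutation_median_diff(v[g1], v[g2], n_perm, seed = NULL) |>
      mutate(stage = cells$stage[i], replicate = cells$replicate[i],
             .before = 1)
  }) |>
    .rand_result_class()
}

#' Plot a randomization result
#'
#' Observed statistic per unit with the 1st-99th percentile null band.
#'
#' @param object A `randomization_result` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.randomization_result <- function(object, ...) {
  unit_col <- setdiff(names(object),
                      c("observed", "null_mean", "null_p01", "null_p99",
                        "ratio", "p_value", "significant", "n_pairs",
                        "n1", "n2", "n_perm", "n_rand", "seed", "defined"))[1]
  ggplot2::ggplot(object, ggplot2::aes(.data[[unit_col]])) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$null_p01,
                                        ymax = .data$null_p99),
                           width = 0.25, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = .data$null_mean),
                        colour = "grey50", shape = 1) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), colour = "red3") +
    ggplot2::labs(y = "statistic (observed vs null band)", x = unit_col)
}
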