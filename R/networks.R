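#' Presence-filtered interaction subgraph at one stage
#'
#' Restricts an undirected interaction set to the proteins detectably
#' expressed at a developmental stage: the node set is the genes (among
#' genes appearing in the interaction list) that satisfy the presence rule
#' at the stage, and an interaction is retained only when both endpoints are
#' nodes.
#'
#' @param interactions Tibble of distinct unordered pairs (`gene_a`,
#'   `gene_b`); see [normalize_interactions()].
#' @param expr Long expression tibble (see [expression-data]).
#' @param stage Stage label to filter on.
#' @param presence_rule `"any_replicate"` (present in at least one replicate
#'   of the stage; default) or `"all_replicates"`.
#' @return An [igraph::graph] (undirected) with graph attributes `stage` and
#'   `presence_rule`.
#' @export
build_stage_graph <- function(interactions, expr, stage,
                              presence_rule = c("any_replicate", "all_replicates")) {
  presence_rule <- match.arg(presence_rule)
  if (!stage %in% unique(expr$stage)) {
    abort(paste0("unknown stage label: ", stage))
  }
  agg <- if (presence_rule == "any_replicate") any else all
  present <- expr |>
    filter(.data$stage == !!stage) |>
    summarise(present = agg(.data$call), .by = "gene_id")
  network_genes <- unique(c(interactions$gene_a, interactions$gene_b))
  nodes <- intersect(network_genes, present$gene_id[present$present])
  edges <- interactions |>
    filter(.data$gene_a %in% nodes, .data$gene_b %in% nodes)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = tibble(name = nodes))
  g <- igraph::set_graph_attr(g, "stage", stage)
  igraph::set_graph_attr(g, "presence_rule", presence_rule)
}

#' Node centralities of a stage graph
#'
#' Computes, per node: degree (incident edge count), betweenness (raw
#' shortest-path counts over unordered node pairs, unnormalized — only rank
#' order enters downstream correlations), and closeness under the
#' reachable-set convention: \eqn{r_v / \sum_{u} d(v, u)} over the
#' \eqn{r_v} nodes reachable from \eqn{v} (excluding \eqn{v}). Stage graphs
#' are routinely disconnected, so this keeps closeness defined everywhere;
#' isolated nodes get closeness 0 and are flagged.
#'
#' @param graph An undirected [igraph::graph] (typically from
#'   [build_stage_graph()]).
#' @return Tibble `gene_id`, `degree`, `betweenness`, `closeness`,
#'   `isolated`.
#' @export
centrality_table <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) {
    return(tibble(gene_id = character(), degree = integer(),
                  betweenness = double(), closeness = double(),
                  isolated = logical()))
  }
  deg <- igraph::degree(graph)
  btw <- igraph::betweenness(graph, directed = FALSE, normalized = FALSE)
  dmat <- igraph::distances(graph)
  clo <- vapply(seq_len(n), function(i) {
    d <- dmat[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))
  tibble(
    gene_id = igraph::V(graph)$name,
    degree = as.integer(deg),
    betweenness = as.numeric(btw),
    closeness = clo,
    isolated = deg == 0
  )
}

#' Centrality-expression correlation at one stage
#'
#' Spearman rank correlation (average ranks for ties) between each
#' centrality measure of the stage graph and the genes' expression at that
#' stage (mean over the stage's replicates), with a two-sided p-value from
#' the t approximation. A constant centrality or constant expression vector
#' leaves rho undefined; such cases are returned as flagged `NA`, never as
#' zero.
#'
#' @param graph A stage graph from [build_stage_graph()].
#' @param expr Long expression tibble.
#' @param drop_isolated Exclude degree-0 nodes from the correlation
#'   (default FALSE: all stage-graph nodes enter).
#' @return Tibble with one row per measure: `stage`, `measure`, `rho`,
#'   `p_value`, `n`, `defined`.
#' @export
stage_centrality_correlation <- function(graph, expr, drop_isolated = FALSE) {
  stage <- igraph::graph_attr(graph, "stage")
  cent <- centrality_table(graph)
  if (drop_isolated) cent <- filter(cent, !.data$isolated)
  me <- mean_expression(filter(expr, .data$stage == !!stage))
  dat <- inner_join(cent, me, by = "gene_id")
  if (nrow(dat) < 3) {
    abort(sprintf("stage '%s': need >= 3 nodes with expression, got %d",
                  stage, nrow(dat)))
  }
  purrr::map_dfr(c("degree", "betweenness", "closeness"), function(measure) {
    x <- dat[[measure]]
    y <- dat$mean_value
    if (length(unique(x)) < 2 || length(unique(y)) < 2) {
      return(tibble(stage = stage, measure = measure, rho = NA_real_,
                    p_value = NA_real_, n = nrow(dat), defined = FALSE))
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    tibble(stage = stage, measure = measure,
           rho = unname(ct$estimate), p_value = ct$p.value,
           n = nrow(dat), defined = TRUE)
  })
}

#' Centrality-expression correlations across a time course
#'
#' Convenience wrapper running [build_stage_graph()] and
#' [stage_centrality_correlation()] for every stage of the dataset.
#'
#' @inheritParams build_stage_graph
#' @param stages Stage metadata tibble (`stage`, `hours`).
#' @param drop_isolated Passed to [stage_centrality_correlation()].
#' @return Tibble of per-stage correlations joined with `hours`.
#' @export
centrality_timecourse <- function(interactions, expr, stages,
                                  presence_rule = "any_replicate",
                                  drop_isolated = FALSE) {
  validate_stages(stages)
  purrr::map_dfr(stages$stage, function(s) {
    g <- build_stage_graph(interactions, expr, s, presence_rule)
    stage_centrality_correlation(g, expr, drop_isolated = drop_isolated)
  }) |>
    inner_join(stages, by = "stage") |>
    relocate("hours", .after = "stage")
}

#' Temporal trend of the centrality-expression correlation
#'
#' Spearman correlation of the per-stage centrality-expression rho against
#' developmental time, per measure — a declining trend means early
#' expression relates more strongly to network centrality than late
#' expression. Stages whose correlation is undefined are dropped.
#'
#' @param stage_cor Output of [centrality_timecourse()] (or of
#'   [stage_centrality_correlation()] row-bound over stages and joined with
#'   `hours`).
#' @return Tibble per measure: `measure`, `rho`, `p_value`, `n_stages`,
#'   `defined`.
#' @export
temporal_trend <- function(stage_cor) {
  if (!all(c("hours", "rho", "measure") %in% names(stage_cor))) {
    abort("stage_cor needs columns measure, hours, rho")
  }
  purrr::map_dfr(unique(stage_cor$measure), function(m) {
    dat <- stage_cor |>
      filter(.data$measure == m, !is.na(.data$rho))
    if (nrow(dat) < 3) {
      abort(sprintf("measure '%s': fewer than 3 stages with a defined correlation", m))
    }
    if (length(unique(dat$rho)) < 2) {
      return(tibble(measure = m, rho = NA_real_, p_value = NA_real_,
                    n_stages = nrow(dat), defined = FALSE))
    }
    ct <- suppressWarnings(cor.test(dat$hours, dat$rho, method = "spearman",
                                    exact = FALSE))
    tibble(measure = m, rho = unname(ct$estimate), p_value = ct$p.value,
           n_stages = nrow(dat), defined = TRUE)
  })
}

#' Plot the centrality-expression correlation over development
#'
#' @param stage_cor Output of [centrality_timecourse()].
#' @param alpha Significance level used to fill points whose per-stage
#'   correlation is significant.
#' @return A ggplot: per-stage rho against log-scaled developmental time,
#'   one curve per centrality measure.
#' @export
plot_centrality_trend <- function(stage_cor, alpha = 0.05) {
  dat <- filter(stage_cor, !is.na(.data$rho)) |>
    mutate(significant = .data$p_value < alpha)
  ggplot2::ggplot(dat, ggplot2::aes(.data$hours, .data$rho,
                                    colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$significant), size = 2.5) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hours post fertilization (log scale)",
                  y = "Spearman rho (centrality vs expression)")
}
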