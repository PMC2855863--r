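#' Configuration of the synthetic developmental study
#'
#' Bundles every knob of the synthetic-data generator, which emulates the
#' structure of a two-replicate developmental microarray time course with
#' detection calls, a protein-interaction network whose hubs can be coupled
#' to early expression, a second species with tunable expression
#' conservation, early/late-onset miRNAs repressing disjoint target sets,
#' and a DAG ontology with one planted enriched term. Defaults mirror the
#' motivating study design: 14 stages from 6 h to 90 days post
#' fertilization, two replicates, log2-scale intensities, and miRNA classes
#' switching on at 11.7 h (segmentation) and 28 h (pharyngula) with target
#' group sizes 119 and 253.
#'
#' @param n_genes Number of genes.
#' @param proportions Named proportions of the `early`, `organogenesis`,
#'   `late` and `background` groups; must sum to 1. Group sizes are
#'   allocated deterministically (`diff(round(cumsum(p) * n))`).
#' @param stage_hours Strictly increasing stage times in hours.
#' @param replicates Replicates per stage.
#' @param noise_sd Replicate noise standard deviation, log2 units.
#' @param detection_threshold Log2 intensity above which a measurement is
#'   called present.
#' @param expr_low,expr_high Low/high plateau levels of the dynamic
#'   profiles, log2 units.
#' @param background_level Constant level of background genes (close to the
#'   detection threshold, so their calls fluctuate like weakly expressed
#'   real genes).
#' @param gene_level_sd Per-gene baseline offset standard deviation.
#' @param phylotypic_hours Designated phylotypic time: organogenesis
#'   profiles rise here and early profiles have finished declining by here.
#' @param early_decline_hours,late_onset_hours,adult_decline_hours Logistic
#'   midpoints of the early decline, the late rise, and the adult-stage
#'   decline of organogenesis profiles.
#' @param profile_steepness Logistic steepness on the log10-hours axis.
#' @param n_edges Number of unique interaction edges.
#' @param pa_exponent Tail exponent of the preferential-attachment fitness
#'   (smaller = heavier-tailed degree distribution).
#' @param hub_coupling Strength of the tilt of hub fitness toward
#'   early-group genes (0 = no coupling).
#' @param conservation Named per-group probabilities that a gene's
#'   second-species metastage presence copies the first species' (otherwise
#'   it is an independent draw at the background marginal).
#' @param n_mirnas,mirna_onset_hours Named (`early`, `late`) miRNA class
#'   sizes and logistic onset midpoints.
#' @param n_targets Named sizes of the exclusive target groups.
#' @param repression Log2 reduction applied to a target's expression after
#'   its regulator class switches on (0 disables the planted effect).
#' @param n_terms,ontology_depth Size and depth of the synthetic DAG
#'   ontology.
#' @param annotations_per_gene Random direct annotations per gene.
#' @param planted_term_size,planted_effect,planted_group The planted
#'   enriched term: number of annotated genes, probability that each is
#'   drawn from `planted_group` (vs uniformly), and the group.
#' @param seed Master seed; per-component seeds are fanned out from it by a
#'   fixed scheme (see [derive_seeds()]).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 1200,
                         proportions = c(early = 0.1, organogenesis = 0.2,
                                         late = 0.2, background = 0.5),
                         stage_hours = c(6, 8, 9, 10, 11.7, 16, 24, 32, 48,
                                         96, 120, 336, 720, 2160),
                         replicates = 2,
                         noise_sd = 0.5,
                         detection_threshold = 6,
                         expr_low = 4.5,
                         expr_high = 9,
                         background_level = 5.8,
                         gene_level_sd = 0.3,
                         phylotypic_hours = 24,
                         early_decline_hours = 12,
                         late_onset_hours = 96,
                         adult_decline_hours = 1000,
                         profile_steepness = 8,
                         n_edges = 1000,
                         pa_exponent = 1,
                         hub_coupling = 1,
                         conservation = c(early = 0.7, organogenesis = 0.7,
                                          late = 0.7, background = 0.7),
                         n_mirnas = c(early = 65, late = 44),
                         mirna_onset_hours = c(early = 11.7, late = 28),
                         n_targets = c(early = 119, late = 253),
                         repression = 1,
                         n_terms = 60,
                         ontology_depth = 4,
                         annotations_per_gene = 2,
                         planted_term_size = 40,
                         planted_effect = 0.8,
                         planted_group = "organogenesis",
                         seed = 1) {
  groups <- c("early", "organogenesis", "late", "background")
  if (!setequal(names(proportions), groups)) {
    abort("proportions must be named early/organogenesis/late/background")
  }
  if (abs(sum(proportions) - 1) > 1e-8) abort("proportions must sum to 1")
  if (any(stage_hours <= 0) || is.unsorted(stage_hours, strictly = TRUE)) {
    abort("stage_hours must be positive and strictly increasing")
  }
  if (n_genes < 1 || n_edges < 0 || replicates < 1) {
    abort("sizes must be positive")
  }
  cfg <- as.list(environment())
  cfg$proportions <- proportions[groups]
  structure(cfg, class = "synth_config")
}

#' Fan out per-component seeds from the master seed
#'
#' A single master seed is expanded into one sub-seed per generator
#' component by a fixed scheme (seed the RNG with the master seed, then draw
#' five integers), so that regenerating one component — or changing a
#' config field that only affects later components — remains reproducible.
#'
#' @param seed Master seed.
#' @return Named integer vector with components `timecourse`, `mirna`,
#'   `network`, `orthology`, `ontology`.
#' @export
derive_seeds <- function(seed) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max, 5),
           c("timecourse", "mirna", "network", "orthology", "ontology"))
}

.logistic_time <- function(hours, midpoint_hours, steepness) {
  1 / (1 + exp(-steepness * (log10(hours) - log10(midpoint_hours))))
}

#' Noiseless archetype profiles of the temporal groups
#'
#' The designed mean log2 profile of each group over the configured stages:
#' early genes sit on a high plateau and decline logistically, completing
#' the decline by the phylotypic stage; organogenesis genes rise at the
#' phylotypic stage, stay high, and decline toward the adult stage; late
#' genes rise after the phylotypic period; background genes are constant
#' near the detection threshold.
#'
#' @param config A [synth_config()].
#' @return Tibble `group`, `stage`, `hours`, `level`.
#' @export
archetype_profiles <- function(config) {
  h <- config$stage_hours
  k <- config$profile_steepness
  lo <- config$expr_low
  span <- config$expr_high - config$expr_low
  levels <- list(
    early = lo + span * (1 - .logistic_time(h, config$early_decline_hours, k)),
    organogenesis = lo + span * .logistic_time(h, config$phylotypic_hours, k) *
      (1 - .logistic_time(h, config$adult_decline_hours, k)),
    late = lo + span * .logistic_time(h, config$late_onset_hours, k),
    background = rep(config$background_level, length(h))
  )
  purrr::imap_dfr(levels, function(lev, grp) {
    tibble(group = grp, stage = .stage_labels(h), hours = h, level = lev)
  })
}

.stage_labels <- function(hours) sprintf("s%02d", seq_along(hours))

.group_sizes <- function(config) {
  p <- config$proportions
  sizes <- diff(round(cumsum(c(0, p)) * config$n_genes))
  setNames(as.integer(sizes), names(p))
}

#' Generate the synthetic expression time course
#'
#' Draws a gene-level log2 expression dataset with detection calls: each
#' gene follows its group archetype (see [archetype_profiles()]) plus a
#' per-gene baseline offset, with independent Gaussian replicate noise; a
#' measurement is called present when its value exceeds the detection
#' threshold. Fully determined by the master seed.
#'
#' @param config A [synth_config()].
#' @return List with `expr` (long expression tibble), `stages` (`stage`,
#'   `hours`) and `truth` (tibble `gene_id`, `group`).
#' @export
generate_timecourse <- function(config) {
  seeds <- derive_seeds(config$seed)
  set.seed(seeds[["timecourse"]])
  sizes <- .group_sizes(config)
  truth <- tibble(
    gene_id = sprintf("g%05d", seq_len(config$n_genes)),
    group = rep(names(sizes), sizes)
  )
  arch <- archetype_profiles(config)
  prof <- matrix(0, config$n_genes, length(config$stage_hours))
  for (grp in names(sizes)) {
    rows <- which(truth$group == grp)
    prof[rows, ] <- matrix(arch$level[arch$group == grp], length(rows),
                           length(config$stage_hours), byrow = TRUE)
  }
  prof <- prof + rnorm(config$n_genes, 0, config$gene_level_sd)
  stages <- tibble(stage = .stage_labels(config$stage_hours),
                   hours = config$stage_hours)
  grid <- tidyr::expand_grid(
    gene_id = truth$gene_id,
    stage = stages$stage,
    replicate = sprintf("r%d", seq_len(config$replicates))
  )
  base <- as.vector(t(prof[, rep(seq_along(config$stage_hours),
                                 each = config$replicates), drop = FALSE]))
  noise <- rnorm(length(base), 0, config$noise_sd)
  expr <- grid |>
    mutate(value = base + noise,
           call = .data$value > config$detection_threshold)
  list(expr = expr, stages = stages, truth = truth)
}

#' Generate the synthetic interaction network
#'
#' Draws exactly `n_edges` distinct undirected edges by fitness-based
#' preferential attachment: each gene receives a heavy-tailed fitness
#' (Pareto tail with exponent `pa_exponent`, capped), multiplied by
#' `exp(hub_coupling)` for early-group genes, and edge endpoints are
#' sampled proportionally to fitness. With `hub_coupling = 0` hub status is
#' independent of the temporal group; with positive coupling the early
#' genes carry the hubs.
#'
#' @param config A [synth_config()].
#' @param truth Gene truth tibble from [generate_timecourse()].
#' @return List with `interactions` (tibble `gene_a`, `gene_b`) and `truth`
#'   augmented with `degree` and `hub` (top-decile degree among connected
#'   genes).
#' @export
generate_network <- function(config, truth) {
  seeds <- derive_seeds(config$seed)
  set.seed(seeds[["network"]])
  n <- nrow(truth)
  if (config$n_edges > n * (n - 1) / 2) {
    abort("n_edges exceeds the number of possible pairs")
  }
  fitness <- pmin(runif(n)^(-1 / (config$pa_exponent + 1)), 50)
  fitness <- fitness * exp(config$hub_coupling * (truth$group == "early"))
  codes <- integer(0)
  while (length(codes) < config$n_edges) {
    m <- 2 * (config$n_edges - length(codes)) + 10
    a <- sample.int(n, m, replace = TRUE, prob = fitness)
    b <- sample.int(n, m, replace = TRUE, prob = fitness)
    keep <- a != b
    i <- pmin(a[keep], b[keep])
    j <- pmax(a[keep], b[keep])
    codes <- unique(c(codes, (i - 1) * n + j))
  }
  codes <- codes[seq_len(config$n_edges)]
  i <- (codes - 1) %/% n + 1
  j <- (codes - 1) %% n + 1
  interactions <- tibble(gene_a = truth$gene_id[pmin(i, j)],
                         gene_b = truth$gene_id[pmax(i, j)]) |>
    arrange(.data$gene_a, .data$gene_b)
  deg <- table(factor(c(interactions$gene_a, interactions$gene_b),
                      levels = truth$gene_id))
  truth$degree <- as.integer(deg)
  connected <- truth$degree[truth$degree > 0]
  cut <- if (length(connected) > 0) quantile(connected, 0.9) else Inf
  truth$hub <- truth$degree > 0 & truth$degree >= cut
  list(interactions = interactions, truth = truth)
}

#' Generate the second species (orthology and conserved presence)
#'
#' Every gene gets a one-to-one ortholog. The second species' expression is
#' represented directly at metastage resolution: with the per-group
#' conservation probability a gene's ortholog copies the first species'
#' metastage presence; otherwise each metastage is an independent Bernoulli
#' draw at that metastage's marginal presence frequency. Stages are
#' partitioned into named metastages (early, organogenesis — containing the
#' phylotypic stage —, larval, juvenile, adult) by their time in hours.
#'
#' @param config A [synth_config()].
#' @param expr,stages,truth Outputs of [generate_timecourse()] (expression
#'   possibly already modified by [generate_mirna()]).
#' @return List with `orthologs` (`gene_a`, `gene_b`), `presence_a`,
#'   `presence_b` (metastage presence tibbles), `metastage_map`
#'   (`species`, `stage`, `metastage`) and `truth` augmented with
#'   `conserved`.
#' @export
generate_orthology <- function(config, expr, stages, truth) {
  seeds <- derive_seeds(config$seed)
  set.seed(seeds[["orthology"]])
  breaks <- c(0, 16, 72, 500, 1500, Inf)
  meta_names <- c("early", "organogenesis", "larval", "juvenile", "adult")
  map_a <- stages |>
    mutate(metastage = meta_names[findInterval(.data$hours, breaks)]) |>
    select("stage", "metastage")
  # keep all metastage levels even if a species has no stage in one
  map_full <- bind_rows(map_a,
                        tibble(stage = NA_character_,
                               metastage = setdiff(meta_names, map_a$metastage)))
  map_full <- map_full[order(match(map_full$metastage, meta_names)), ]
  presence_a <- metastage_presence(expr, map_full)

  conserved <- runif(nrow(truth)) < config$conservation[truth$group]
  truth$conserved <- unname(conserved)
  orthologs <- tibble(gene_a = truth$gene_id,
                      gene_b = paste0("orth_", truth$gene_id))

  wide <- presence_a |>
    tidyr::pivot_wider(names_from = "metastage", values_from = "present")
  wide <- wide[match(truth$gene_id, wide$gene_id), ]
  pa <- as.matrix(wide[-1])
  marginal <- colMeans(pa, na.rm = TRUE)
  pb <- pa
  for (m in seq_len(ncol(pb))) {
    if (all(is.na(pa[, m]))) next
    indep <- runif(nrow(pb)) < marginal[m]
    pb[!conserved, m] <- indep[!conserved]
  }
  presence_b <- as_tibble(pb) |>
    mutate(gene_id = paste0("orth_", truth$gene_id), .before = 1) |>
    tidyr::pivot_longer(-"gene_id", names_to = "metastage",
                        values_to = "present") |>
    mutate(metastage = factor(.data$metastage,
                              levels = levels(presence_a$metastage)))
  metastage_map <- bind_rows(
    mutate(map_full, species = "species_a", .before = 1),
    tibble(species = "species_b", stage = meta_names, metastage = meta_names)
  )
  list(orthologs = orthologs, presence_a = presence_a,
       presence_b = presence_b, metastage_map = metastage_map, truth = truth)
}

#' Generate miRNA expression and planted target repression
#'
#' miRNA profiles rise logistically from low to high at their class onset
#' (early onset before the phylotypic period, late onset after). Exclusive
#' target sets of the configured sizes are sampled disjointly; each
#' target's gene expression is reduced by `repression * onset(t)` log2
#' units once its regulator class switches on, and the gene's detection
#' calls are recomputed from the repressed values.
#'
#' @param config A [synth_config()].
#' @param expr,stages,truth Outputs of [generate_timecourse()].
#' @return List with `mirna_expr` (long expression tibble of the miRNAs),
#'   `mirna_classes` (tibble `mirna`, `class`), `targets`
#'   (tibble `mirna`, `gene`), `expr` (gene expression after repression)
#'   and `truth` augmented with `targeted_by`.
#' @export
generate_mirna <- function(config, expr, stages, truth) {
  seeds <- derive_seeds(config$seed)
  set.seed(seeds[["mirna"]])
  classes <- rep(c("early", "late"), config$n_mirnas[c("early", "late")])
  mirnas <- tibble(
    mirna = sprintf("mir%03d", seq_along(classes)),
    class = classes
  )
  lo <- config$expr_low
  span <- config$expr_high - config$expr_low
  grid <- tidyr::expand_grid(
    gene_id = mirnas$mirna,
    stage = stages$stage,
    replicate = sprintf("r%d", seq_len(config$replicates))
  )
  onset <- setNames(config$mirna_onset_hours[c("early", "late")],
                    c("early", "late"))
  hours <- stages$hours[match(grid$stage, stages$stage)]
  cls <- mirnas$class[match(grid$gene_id, mirnas$mirna)]
  level <- lo + span * .logistic_time(hours, onset[cls],
                                      config$profile_steepness)
  offsets <- rnorm(nrow(mirnas), 0, config$gene_level_sd)
  mirna_expr <- grid |>
    mutate(
      value = level + offsets[match(.data$gene_id, mirnas$mirna)] +
        rnorm(nrow(grid), 0, config$noise_sd),
      call = .data$value > config$detection_threshold
    )

  n_t <- config$n_targets[c("early", "late")]
  picked <- sample(truth$gene_id, sum(n_t))
  target_class <- rep(c("early", "late"), n_t)
  regulators <- purrr::map2_dfr(picked, target_class, function(g, cl) {
    pool <- mirnas$mirna[mirnas$class == cl]
    tibble(mirna = sample(pool, sample(1:3, 1)), gene = g)
  })
  truth$targeted_by <- NA_character_
  truth$targeted_by[match(picked, truth$gene_id)] <- target_class

  if (config$repression != 0) {
    tgt_cls <- setNames(target_class, picked)
    hit <- expr$gene_id %in% picked
    h <- stages$hours[match(expr$stage[hit], stages$stage)]
    drop <- config$repression *
      .logistic_time(h, onset[tgt_cls[expr$gene_id[hit]]],
                     config$profile_steepness)
    expr$value[hit] <- expr$value[hit] - drop
    expr$call <- expr$value > config$detection_threshold
  }
  list(mirna_expr = mirna_expr, mirna_classes = mirnas,
       targets = arrange(regulators, .data$mirna, .data$gene),
       expr = expr, truth = truth)
}

#' Generate the synthetic DAG ontology with one planted enriched term
#'
#' Builds a layered random DAG (each term has one or two parents in the
#' level above), annotates each gene to a few random terms, and plants one
#' deepest-level term whose `planted_term_size` annotated genes are drawn
#' from `planted_group` with probability `planted_effect` (uniformly from
#' all genes otherwise). With `planted_effect = 0` the planted term is
#' indistinguishable from the rest.
#'
#' @param config A [synth_config()].
#' @param truth Gene truth tibble.
#' @return List with `ontology` (an `ontology`), `annotations` (direct
#'   `gene_id`, `term_id`), `planted_term` (id) and `term_truth`
#'   (tibble `term_id`, `planted`).
#' @export
generate_ontology <- function(config, truth) {
  seeds <- derive_seeds(config$seed)
  set.seed(seeds[["ontology"]])
  D <- config$ontology_depth
  n_rest <- config$n_terms - 1
  sizes <- diff(round(seq(0, n_rest, length.out = D + 1)))
  sizes <- pmax(sizes, 1)
  ids <- sprintf("T%04d", seq_len(1 + sum(sizes)))
  level <- c(0, rep(seq_len(D), sizes))
  parents <- vector("list", length(ids))
  names(parents) <- ids
  for (i in seq_along(ids)[-1]) {
    pool <- ids[level == level[i] - 1]
    parents[[i]] <- sample(pool, min(length(pool), sample(1:2, 1)))
  }
  ont <- build_ontology(
    tibble(term_id = ids,
           name = ifelse(level == 0, "root",
                         sprintf("synthetic process %s", ids)),
           namespace = "biological_process"),
    parents
  )
  non_root <- ids[level > 0]
  random_ann <- tibble(
    gene_id = rep(truth$gene_id, each = config$annotations_per_gene),
    term_id = sample(non_root,
                     nrow(truth) * config$annotations_per_gene,
                     replace = TRUE)
  )
  planted <- sort(ids[level == D])[1]
  in_group <- truth$gene_id[truth$group == config$planted_group]
  take_group <- runif(config$planted_term_size) < config$planted_effect
  planted_genes <- character(config$planted_term_size)
  planted_genes[take_group] <- sample(in_group, sum(take_group))
  planted_genes[!take_group] <- sample(truth$gene_id, sum(!take_group))
  annotations <- bind_rows(
    random_ann,
    tibble(gene_id = unique(planted_genes), term_id = planted)
  ) |>
    distinct() |>
    arrange(.data$term_id, .data$gene_id)
  list(ontology = ont, annotations = annotations, planted_term = planted,
       term_truth = tibble(term_id = ids, planted = ids == planted))
}

#' Run the whole synthetic study generator
#'
#' Chains [generate_timecourse()], [generate_mirna()] (which plants target
#' repression into the expression values), [generate_network()],
#' [generate_orthology()] and [generate_ontology()] under one master seed.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_study` with all generated components and
#'   the consolidated `truth` record.
#' @export
simulate_study <- function(config = synth_config()) {
  tc <- generate_timecourse(config)
  mi <- generate_mirna(config, tc$expr, tc$stages, tc$truth)
  nw <- generate_network(config, mi$truth)
  orth <- generate_orthology(config, mi$expr, tc$stages, nw$truth)
  ont <- generate_ontology(config, orth$truth)
  structure(
    list(
      config = config,
      expr = mi$expr, stages = tc$stages,
      mirna_expr = mi$mirna_expr, mirna_classes = mi$mirna_classes,
      targets = mi$targets,
      interactions = nw$interactions,
      orthologs = orth$orthologs,
      presence_a = orth$presence_a, presence_b = orth$presence_b,
      metastage_map = orth$metastage_map,
      ontology = ont$ontology, annotations = ont$annotations,
      planted_term = ont$planted_term, term_truth = ont$term_truth,
      truth = orth$truth
    ),
    class = "synth_study"
  )
}

#' @export
print.synth_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic developmental study: %d genes x %d stages x %d replicates, %d edges, %d miRNAs, %d ontology terms (seed %d)\n",
    x$config$n_genes, length(x$config$stage_hours), x$config$replicates,
    nrow(x$interactions), nrow(x$mirna_classes), nrow(x$ontology$terms),
    x$config$seed
  ))
  invisible(x)
}

#' Map clusters to the generator's temporal groups
#'
#' Matches each fuzzy cluster center to the archetype profile (early,
#' organogenesis, late) it correlates with best; centers correlating with
#' no dynamic archetype above `min_cor` are labelled background. This is
#' how a clustering run over many clusters is condensed into the three
#' temporal gene groups without consulting per-gene truth.
#'
#' @param fit A [fuzzy_cmeans()] fit of the gene mean-expression profiles.
#' @param config The [synth_config()] that generated the data.
#' @param min_cor Minimum Pearson correlation with a dynamic archetype.
#' @return Tibble `cluster`, `group`, `cor`.
#' @export
map_clusters_to_groups <- function(fit, config, min_cor = 0.7) {
  arch <- archetype_profiles(config) |>
    filter(.data$group != "background") |>
    tidyr::pivot_wider(id_cols = "group", names_from = "stage",
                       values_from = "level")
  am <- as.matrix(arch[-1])
  rownames(am) <- arch$group
  purrr::map_dfr(seq_len(nrow(fit$centers)), function(cl) {
    cc <- suppressWarnings(apply(am, 1, cor, y = fit$centers[cl, ]))
    cc[is.na(cc)] <- -Inf
    best <- which.max(cc)
    tibble(cluster = cl,
           group = if (cc[best] >= min_cor) rownames(am)[best] else "background",
           cor = unname(cc[best]))
  })
}

#' Write a synthetic study to disk as plain-text files
#'
#' Emits the expression/call/stage TSVs for genes and miRNAs, the
#' interaction, ortholog, metastage, second-species presence and target
#' TSVs, the ontology as OBO, the annotation TSV, and the truth record as
#' JSON.
#'
#' @param sim A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression(sim$expr, p("expression.tsv"), p("calls.tsv"))
  write_stages(sim$stages, p("stages.tsv"))
  write_expression(sim$mirna_expr, p("mirna_expression.tsv"),
                   p("mirna_calls.tsv"))
  write_pairs(sim$interactions, p("interactions.tsv"))
  write_pairs(sim$orthologs, p("orthologs.tsv"))
  readr::write_tsv(sim$metastage_map, p("metastages.tsv"))
  readr::write_tsv(mutate(sim$presence_b,
                          metastage = as.character(.data$metastage)),
                   p("presence_species_b.tsv"))
  write_pairs(sim$targets, p("targets.tsv"))
  write_obo(sim$ontology, p("ontology.obo"))
  readr::write_tsv(sim$annotations, p("annotations.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(truth = sim$truth, planted_term = sim$planted_term,
           mirna_classes = sim$mirna_classes),
      p("truth.json")
    )
  } else {
    warn("jsonlite not available; truth.json not written")
  }
  invisible(dir)
}
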