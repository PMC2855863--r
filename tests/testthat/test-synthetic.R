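small_cfg <- function(seed = 1, ...) {
  synth_config(n_genes = 200, n_edges = 120,
               n_targets = c(early = 15, late = 30),
               n_mirnas = c(early = 10, late = 8),
               n_terms = 25, planted_term_size = 20, seed = seed, ...)
}

test_that("the generator is fully deterministic under the master seed", {
  s1 <- simulate_study(small_cfg(seed = 5))
  s2 <- simulate_study(small_cfg(seed = 5))
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$interactions, s2$interactions)
  expect_identical(s1$presence_b, s2$presence_b)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$truth, s2$truth)
  # emitted files are byte-identical across runs
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  s3 <- simulate_study(small_cfg(seed = 6))
  expect_false(identical(s1$expr$value, s3$expr$value))
})

test_that("group allocation is deterministic and proportional", {
  cfg <- synth_config(n_genes = 1000,
                      proportions = c(early = 0.1, organogenesis = 0.2,
                                      late = 0.2, background = 0.5))
  tc <- generate_timecourse(cfg)
  expect_equal(unname(table(tc$truth$group)[c("early", "organogenesis",
                                              "late", "background")]),
               c(100, 200, 200, 500), ignore_attr = TRUE)
  expect_error(synth_config(proportions = c(early = 0.5, organogenesis = 0.2,
                                            late = 0.2, background = 0.2)),
               "sum to 1")
})

test_that("noise-free profiles reproduce the designed ordering", {
  cfg <- small_cfg(noise_sd = 0, gene_level_sd = 0, repression = 0)
  tc <- generate_timecourse(cfg)
  med <- tc$expr |>
    dplyr::inner_join(tc$truth, by = "gene_id") |>
    dplyr::summarise(m = median(value), .by = c("group", "stage"))
  first <- dplyr::filter(med, stage == "s01")
  last <- dplyr::filter(med, stage == "s14")
  expect_gt(first$m[first$group == "early"], first$m[first$group == "late"])
  expect_gt(last$m[last$group == "late"], last$m[last$group == "early"])
  # organogenesis peaks in between
  org <- dplyr::filter(med, group == "organogenesis")
  expect_gt(max(org$m), org$m[org$stage == "s01"])
})

test_that("the network has exactly the requested unique edges and obeys the coupling", {
  tc <- generate_timecourse(small_cfg(seed = 2))
  nw <- generate_network(small_cfg(seed = 2), tc$truth)
  expect_equal(nrow(nw$interactions), 120)
  expect_equal(nrow(dplyr::distinct(nw$interactions)), 120)
  expect_true(all(nw$interactions$gene_a != nw$interactions$gene_b))
  expect_equal(sum(nw$truth$degree), 2 * 120)
  # strong coupling tilts degree toward early genes
  nw_strong <- generate_network(small_cfg(seed = 2, hub_coupling = 3),
                                tc$truth)
  md <- nw_strong$truth |>
    dplyr::summarise(d = mean(degree), .by = "group")
  expect_gt(md$d[md$group == "early"], md$d[md$group == "late"])
})

test_that("without coupling, hub status is independent of the temporal group", {
  tab <- matrix(0, 2, 4)
  for (seed in 1:200) {
    cfg <- small_cfg(seed = seed, hub_coupling = 0)
    tc <- generate_timecourse(cfg)
    nw <- generate_network(cfg, tc$truth)
    t0 <- table(factor(nw$truth$hub, levels = c(FALSE, TRUE)),
                factor(nw$truth$group,
                       levels = c("early", "organogenesis", "late",
                                  "background")))
    tab <- tab + t0
  }
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
})

test_that("full conservation copies presence exactly; planted conservation is recovered", {
  cfg <- small_cfg(seed = 3,
                   conservation = c(early = 1, organogenesis = 1,
                                    late = 1, background = 1))
  sim <- simulate_study(cfg)
  pa <- dplyr::arrange(sim$presence_a, gene_id, metastage)
  pb <- sim$presence_b |>
    dplyr::mutate(gene_id = sub("^orth_", "", gene_id)) |>
    dplyr::arrange(gene_id, metastage)
  expect_identical(pa$present, pb$present)

  # early-only conservation: the band flags where early presence is
  # informative (the organogenesis metastage, mid-decline), never for the
  # unconserved late category
  flags_early <- 0
  flags_late <- 0
  n_seeds <- 10
  for (seed in 1:n_seeds) {
    cfg2 <- synth_config(n_genes = 300, n_edges = 150, hub_coupling = 0,
                         conservation = c(early = 1, organogenesis = 0,
                                          late = 0, background = 0),
                         n_targets = c(early = 20, late = 40),
                         repression = 0, seed = seed)
    sim2 <- simulate_study(cfg2)
    pick <- function(grp) {
      sim2$orthologs |>
        dplyr::inner_join(sim2$truth, by = c(gene_a = "gene_id")) |>
        dplyr::filter(group == grp) |>
        dplyr::select(gene_a, gene_b) |>
        utils::head(25)
    }
    be <- ortholog_conservation_band(pick("early"), sim2$presence_a,
                                     sim2$presence_b, n_rand = 500,
                                     seed = seed)
    bl <- ortholog_conservation_band(pick("late"), sim2$presence_a,
                                     sim2$presence_b, n_rand = 500,
                                     seed = seed)
    flags_early <- flags_early +
      isTRUE(be$significant[be$metastage == "organogenesis"])
    flags_late <- flags_late + sum(bl$significant, na.rm = TRUE)
  }
  expect_gte(flags_early, 8)
  expect_lte(flags_late, 2)
})

test_that("with conservation at the background marginal the pair ratio is calibrated", {
  ratios <- vapply(1:500, function(seed) {
    cfg <- synth_config(n_genes = 250, n_edges = 150, hub_coupling = 0,
                        stage_hours = c(6, 10, 16, 24, 48, 96, 336, 2160),
                        conservation = c(early = 0, organogenesis = 0,
                                        late = 0, background = 0),
                        n_targets = c(early = 15, late = 30),
                        repression = 0, seed = seed)
    tc <- generate_timecourse(cfg)
    nw <- generate_network(cfg, tc$truth)
    orth <- generate_orthology(cfg, tc$expr, tc$stages, nw$truth)
    res <- ppi_conservation_ratio(nw$interactions, orth$presence_a,
                                  orth$presence_b, orth$orthologs,
                                  n_rand = 300, seed = seed)
    mean(res$ratio, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(ratios), 0.95)
  expect_lt(mean(ratios), 1.05)
})

test_that("miRNA onset classes are recoverable and repression is detectable", {
  cfg <- small_cfg(seed = 9)
  sim <- simulate_study(cfg)
  prof <- mean_expression(sim$mirna_expr) |>
    tidyr::pivot_wider(names_from = "stage", values_from = "mean_value")
  fit <- fuzzy_cmeans(prof, c = 2, m = 2, seed = 1)
  truth_class <- sim$mirna_classes$class[match(prof$gene_id,
                                               sim$mirna_classes$mirna)]
  expect_gte(ari(assign_clusters(fit)$cluster, truth_class), 0.95)

  # planted repression: between the two onsets the early-only targets are
  # pushed down by ~2 log2 units relative to late-only targets
  hits <- 0
  for (seed in 1:5) {
    cfg2 <- synth_config(n_genes = 400, n_edges = 150,
                         n_targets = c(early = 50, late = 50),
                         repression = 2, seed = seed)
    sim2 <- simulate_study(cfg2)
    tg <- classify_exclusive_targets(
      sim2$targets,
      sim2$mirna_classes$mirna[sim2$mirna_classes$class == "early"],
      sim2$mirna_classes$mirna[sim2$mirna_classes$class == "late"]
    )
    sub <- dplyr::filter(sim2$expr, stage == "s06", replicate == "r1")
    tt <- target_expression_test(sub, tg, n_perm = 10000, seed = seed)
    hits <- hits + (tt$p_value <= 0.001)
  }
  expect_gte(hits, 4)
  # exclusive targets in the truth record match the classifier
  tg2 <- classify_exclusive_targets(
    sim$targets,
    sim$mirna_classes$mirna[sim$mirna_classes$class == "early"],
    sim$mirna_classes$mirna[sim$mirna_classes$class == "late"]
  )
  tr <- sim$truth[!is.na(sim$truth$targeted_by), ]
  expect_setequal(tg2$gene_id, tr$gene_id)
})

test_that("with no repression the per-stage permutation p-values are uniform", {
  # group sizes large enough that median ties with null draws are negligible
  # (the add-one convention is conservative under heavy tying)
  ps <- vapply(1:400, function(seed) {
    cfg <- synth_config(n_genes = 250, n_edges = 60,
                        stage_hours = c(6, 16, 48, 336),
                        n_targets = c(early = 40, late = 60),
                        n_mirnas = c(early = 5, late = 5),
                        repression = 0, seed = seed)
    tc <- generate_timecourse(cfg)
    mi <- generate_mirna(cfg, tc$expr, tc$stages, tc$truth)
    tg <- classify_exclusive_targets(
      mi$targets,
      mi$mirna_classes$mirna[mi$mirna_classes$class == "early"],
      mi$mirna_classes$mirna[mi$mirna_classes$class == "late"]
    )
    sub <- dplyr::filter(mi$expr, stage == "s02", replicate == "r1")
    target_expression_test(sub, tg, n_perm = 149, seed = seed)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("the planted ontology term is calibrated at zero effect and recovered at full effect", {
  # effect 0: the planted term's elim p rejects at 5% no more often than 5%
  ps <- vapply(1:300, function(seed) {
    cfg <- synth_config(n_genes = 150, n_edges = 60, n_terms = 25,
                        n_targets = c(early = 10, late = 20),
                        planted_term_size = 20, planted_effect = 0,
                        seed = seed)
    tc <- generate_timecourse(cfg)
    ont <- generate_ontology(cfg, tc$truth)
    study <- tc$truth$gene_id[tc$truth$group == "organogenesis"]
    tab <- elim_enrichment(ont$ontology, ont$annotations, study,
                           tc$truth$gene_id)
    tab$p_elim[tab$term_id == ont$planted_term]
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.07)  # conservative discrete test

  # full effect: planted term is FDR-significant, its ancestors are not
  for (seed in 1:3) {
    cfg <- small_cfg(seed = seed, planted_effect = 1)
    sim <- simulate_study(cfg)
    study <- sim$truth$gene_id[sim$truth$group == sim$config$planted_group]
    tab <- elim_enrichment(sim$ontology, sim$annotations, study,
                           sim$truth$gene_id)
    expect_lt(tab$p_fdr[tab$term_id == sim$planted_term], 0.05)
    anc <- term_ancestors(sim$ontology, sim$planted_term)
    expect_true(all(tab$p_elim[tab$term_id %in% anc] > 0.05))
  }
})

test_that("generated inputs satisfy the pipeline's structural contracts", {
  sim <- simulate_study(small_cfg(seed = 12))
  expect_silent(validate_expression(sim$expr))
  expect_silent(validate_stages(sim$stages))
  norm <- suppressWarnings(normalize_interactions(sim$interactions))
  expect_equal(nrow(norm), nrow(sim$interactions))
  expect_false(any(duplicated(c(sim$orthologs$gene_a))))
  expect_false(any(duplicated(c(sim$orthologs$gene_b))))
  # every stage mapped; organogenesis metastage present
  expect_true(all(sim$stages$stage %in% sim$metastage_map$stage))
  expect_true("organogenesis" %in% sim$metastage_map$metastage)
  # ontology re-parses and depths survive the round trip
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(sim$ontology, path)
  expect_equal(parse_obo(path)$terms$depth, sim$ontology$terms$depth)
})
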