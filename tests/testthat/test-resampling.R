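# small presence-table builder: named logical matrices (gene x metastage)
presence_tbl <- function(mat) {
  tibble::as_tibble(mat, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "metastage",
                        values_to = "present") |>
    dplyr::mutate(metastage = factor(metastage, levels = colnames(mat)))
}

test_that("metastage presence is existential over stages, NA for empty metastages", {
  # 3 stages x 2 replicates; g1 present in one replicate of s02 (metastage A)
  # and one replicate of s03 (metastage B); g2 absent everywhere
  calls <- rbind(
    g1 = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    g2 = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  expr <- make_expr(matrix(8, 2, 6, dimnames = dimnames(calls)), calls)
  map <- tibble::tibble(stage = c("s01", "s02", "s03", NA),
                        metastage = c("A", "A", "B", "C"))
  mp <- metastage_presence(expr, map)
  expect_true(mp$present[mp$gene_id == "g1" & mp$metastage == "A"])
  expect_true(mp$present[mp$gene_id == "g1" & mp$metastage == "B"])
  expect_false(any(mp$present[mp$gene_id == "g2"], na.rm = TRUE))
  expect_true(all(is.na(mp$present[mp$metastage == "C"])))
  expect_equal(levels(mp$metastage), c("A", "B", "C"))
  expect_error(metastage_presence(expr, map[1:2, ]), "not mapped")
})

test_that("conservation ratio is exactly 1 under saturation and NA when nothing is expressed", {
  genes <- sprintf("g%d", 1:6)
  sat <- matrix(TRUE, 6, 1, dimnames = list(genes, "m1"))
  pa <- presence_tbl(sat)
  pb <- presence_tbl(`rownames<-`(sat, paste0("o_", genes)))
  orth <- tibble::tibble(gene_a = genes, gene_b = paste0("o_", genes))
  pairs <- tibble::tibble(gene_a = c("g1", "g2", "g3"),
                          gene_b = c("g2", "g3", "g4"))
  res <- ppi_conservation_ratio(pairs, pa, pb, orth, n_rand = 200, seed = 1)
  expect_equal(res$observed, 3L)
  expect_equal(res$ratio, 1)
  expect_equal(res$null_p01, 3)
  expect_equal(res$null_p99, 3)
  # no ortholog expressed -> observed 0, null 0, flagged NA
  none <- presence_tbl(`rownames<-`(matrix(FALSE, 6, 1,
                                           dimnames = list(genes, "m1")),
                                    paste0("o_", genes)))
  res0 <- ppi_conservation_ratio(pairs, pa, none, orth, n_rand = 100, seed = 1)
  expect_equal(res0$observed, 0L)
  expect_false(res0$defined)
  expect_true(is.na(res0$ratio))
  expect_error(
    ppi_conservation_ratio(pairs, pa[1:3, ], pb, orth[1:3, ], n_rand = 10),
    "fewer than 4"
  )
})

test_that("the sampled pair null matches exhaustive enumeration on a 6-gene universe", {
  genes <- sprintf("g%d", 1:6)
  set.seed(9)
  za <- setNames(c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE), genes)
  zb <- setNames(c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE), paste0("o_", genes))
  pa <- presence_tbl(matrix(za, 6, 1, dimnames = list(genes, "m1")))
  pb <- presence_tbl(matrix(zb, 6, 1,
                            dimnames = list(paste0("o_", genes), "m1")))
  orth <- tibble::tibble(gene_a = genes, gene_b = paste0("o_", genes))
  pairs <- tibble::tibble(gene_a = c("g1", "g2", "g5"),
                          gene_b = c("g3", "g4", "g6"))
  n_rand <- 10000
  res <- ppi_conservation_ratio(pairs, pa, pb, orth, n_rand = n_rand,
                                seed = 11)
  # exhaustive null: all C(15,3) = 455 sets of 3 distinct pairs
  z <- (za & zb[paste0("o_", genes)])
  all_pairs <- t(combn(genes, 2))
  coexp <- z[all_pairs[, 1]] & z[all_pairs[, 2]]
  triples <- combn(15, 3)
  exact_null <- colSums(matrix(coexp[triples], 3))
  expect_equal(res$observed, sum(z[pairs$gene_a] & z[pairs$gene_b]))
  # sampled mean within 3 Monte-Carlo SEs of the exact mean
  se_mean <- sd(exact_null) / sqrt(n_rand)
  expect_lt(abs(res$null_mean - mean(exact_null)), 3 * se_mean)
  # sampled p within 3 MC SEs of the exact (add-one-free) upper-tail p
  p_exact <- mean(exact_null >= res$observed)
  se_p <- sqrt(p_exact * (1 - p_exact) / n_rand)
  expect_lt(abs(res$p_value - p_exact), 3 * se_p + 2 / n_rand)
})

test_that("conservation results are seed-deterministic and seed-stable", {
  genes <- sprintf("g%d", 1:12)
  set.seed(2)
  mat_a <- matrix(runif(24) < 0.7, 12, 2, dimnames = list(genes, c("m1", "m2")))
  mat_b <- matrix(runif(24) < 0.7, 12, 2,
                  dimnames = list(paste0("o_", genes), c("m1", "m2")))
  orth <- tibble::tibble(gene_a = genes, gene_b = paste0("o_", genes))
  pairs <- tibble::tibble(gene_a = genes[1:5], gene_b = genes[8:12])
  r1 <- ppi_conservation_ratio(pairs, presence_tbl(mat_a), presence_tbl(mat_b),
                               orth, n_rand = 2000, seed = 7)
  r2 <- ppi_conservation_ratio(pairs, presence_tbl(mat_a), presence_tbl(mat_b),
                               orth, n_rand = 2000, seed = 7)
  expect_identical(r1, r2)
  r3 <- ppi_conservation_ratio(pairs, presence_tbl(mat_a), presence_tbl(mat_b),
                               orth, n_rand = 2000, seed = 8)
  expect_lt(max(abs(r1$p_value - r3$p_value)), 3 * 0.5 / sqrt(2000))
})

test_that("ortholog re-pairing matches the exhaustive 4! permutation null", {
  pairs4 <- tibble::tibble(gene_a = sprintf("a%d", 1:4),
                           gene_b = sprintf("b%d", 1:4))
  za <- c(TRUE, TRUE, FALSE, TRUE)
  zb <- c(TRUE, FALSE, TRUE, TRUE)
  pa <- presence_tbl(matrix(za, 4, 1, dimnames = list(pairs4$gene_a, "m1")))
  pb <- presence_tbl(matrix(zb, 4, 1, dimnames = list(pairs4$gene_b, "m1")))
  expect_error(ortholog_conservation_band(pairs4[1:2, ], pa, pb), "fewer than 3")
  n_rand <- 10000
  res <- ortholog_conservation_band(pairs4, pa, pb, n_rand = n_rand, seed = 3)
  perms <- all_perms(4)
  exact_null <- apply(perms, 1, function(p) sum(za & zb[p]))
  expect_equal(res$observed, sum(za & zb))
  se_mean <- sd(exact_null) / sqrt(n_rand)
  expect_lt(abs(res$null_mean - mean(exact_null)), 3 * se_mean + 1e-12)
  p_exact <- mean(exact_null >= res$observed)
  se_p <- sqrt(p_exact * (1 - p_exact) / n_rand)
  expect_lt(abs(res$p_value - p_exact), 3 * se_p + 2 / n_rand)
})

test_that("a saturated category yields a degenerate band and no flag", {
  pairs4 <- tibble::tibble(gene_a = sprintf("a%d", 1:4),
                           gene_b = sprintf("b%d", 1:4))
  pa <- presence_tbl(matrix(TRUE, 4, 1, dimnames = list(pairs4$gene_a, "m1")))
  pb <- presence_tbl(matrix(TRUE, 4, 1, dimnames = list(pairs4$gene_b, "m1")))
  res <- ortholog_conservation_band(pairs4, pa, pb, n_rand = 500, seed = 1)
  expect_equal(res$observed, 4L)
  expect_equal(res$null_p99, 4)
  expect_false(res$significant)
})

test_that("the median permutation test matches exhaustive splits and its conventions", {
  # identical groups: every |null| >= 0 = |obs|, so p = 1
  same <- permutation_median_diff(c(1, 2, 3), c(1, 2, 3), n_perm = 500,
                                  seed = 2)
  expect_equal(same$observed, 0)
  expect_equal(same$p_value, 1)
  # n1 = 1, n2 = 2: three possible splits, enumerate them
  ex <- oracle_median_perm_exact(10, c(1, 2))
  expect_equal(ex$p_two_sided, 1 / 3)
  res <- permutation_median_diff(10, c(1, 2), n_perm = 9999, seed = 4)
  se <- sqrt(ex$p_two_sided * (1 - ex$p_two_sided) / 9999)
  expect_lt(abs(res$p_value - ex$p_two_sided), 3 * se + 2 / 9999)
  # a shift no re-split can reach: p attains the add-one floor
  v1 <- rnorm(50) + 100
  v2 <- rnorm(50)
  res2 <- permutation_median_diff(v1, v2, n_perm = 999, seed = 5)
  expect_equal(res2$p_value, 1 / 1000)
})

test_that("sampled two-sided p stays within 3 MC SEs of exhaustive enumeration", {
  set.seed(6)
  for (rep in 1:4) {
    n1 <- sample(2:4, 1)
    n2 <- sample(2:4, 1)
    v1 <- round(rnorm(n1, 1), 2)
    v2 <- round(rnorm(n2), 2)
    ex <- oracle_median_perm_exact(v1, v2)
    res <- permutation_median_diff(v1, v2, n_perm = 10000, seed = rep)
    se <- sqrt(ex$p_two_sided * (1 - ex$p_two_sided) / 10000)
    expect_lt(abs(res$p_value - ex$p_two_sided), 3 * se + 2 / 10000)
  }
})

test_that("exclusive target classification follows the only-one-class rule", {
  tm <- tibble::tibble(
    mirna = c("mE1", "mE1", "mE2", "mL1", "mL1"),
    gene = c("gA", "gB", "gB", "gB", "gC")
  )
  out <- classify_exclusive_targets(tm, c("mE1", "mE2"), "mL1")
  expect_equal(out$group[out$gene_id == "gA"], "early_only")
  expect_equal(out$group[out$gene_id == "gC"], "late_only")
  expect_false("gB" %in% out$gene_id)   # both classes -> excluded
  empty <- classify_exclusive_targets(tm[0, ], "mE1", "mL1")
  expect_equal(nrow(empty), 0)
  expect_error(classify_exclusive_targets(tm, "mE1", c("mE1", "mL1")),
               "overlap")
})

test_that("the per-stage target test is deterministic and rejects overlapping groups", {
  set.seed(8)
  values <- matrix(rnorm(40, 7), 10, 4,
                   dimnames = list(sprintf("g%02d", 1:10), NULL))
  expr <- make_expr(values, matrix(TRUE, 10, 4))
  groups <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:9),
    group = rep(c("early_only", "late_only", "late_only"), 3)
  )
  t1 <- target_expression_test(expr, groups, n_perm = 300, seed = 12)
  t2 <- target_expression_test(expr, groups, n_perm = 300, seed = 12)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 4)  # 2 stages x 2 replicates
  tp <- target_expression_test(expr, groups, n_perm = 300, seed = 12,
                               pooled = TRUE)
  expect_equal(tp$unit, "pooled")
  bad <- dplyr::bind_rows(groups,
                          tibble::tibble(gene_id = "g01",
                                         group = "late_only"))
  expect_error(target_expression_test(expr, bad, n_perm = 10), "overlap")
})
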