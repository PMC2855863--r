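#' Kruskal-Wallis comparison of per-gene values between groups
#'
#' Rank-based omnibus test of whether several gene groups (e.g. the
#' temporal expression groups) differ in a per-gene quantity such as the
#' number of abnormal phenotypes of a mutant or the number of anatomical
#' structures with expression. Uses the average-rank tie correction and a
#' chi-square reference distribution with `groups - 1` degrees of freedom.
#' When every value is identical the statistic is 0 and p = 1.
#'
#' @param data Data frame with one row per gene.
#' @param value,group Column names of the value and the group label.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_groups`, `n`.
#' @export
kruskal_wallis <- function(data, value = "value", group = "group") {
  v <- data[[value]]
  g <- as.character(data[[group]])
  .check_groups(v, g)
  if (length(unique(v)) == 1) {
    return(tibble(statistic = 0, df = length(unique(g)) - 1, p_value = 1,
                  n_groups = length(unique(g)), n = length(v)))
  }
  kt <- kruskal.test(v, factor(g))
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, n_groups = length(unique(g)), n = length(v))
}

.check_groups <- function(v, g) {
  if (anyNA(v) || anyNA(g)) abort("values and groups must not contain NA")
  sizes <- table(g)
  if (length(sizes) < 2) abort("need at least 2 groups")
  if (any(sizes == 0)) abort("empty group(s)")
  if (length(v) < 3) abort("need at least 3 values in total")
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' Two-sided rank-sum test for every unordered pair of groups; the exact
#' distribution is used when the combined sample size is at most 20 and
#' there are no ties, otherwise the normal approximation with tie and
#' continuity correction. P-values are Bonferroni-adjusted with `k` tests
#' (default: the number of pairs).
#'
#' @inheritParams kruskal_wallis
#' @param k Bonferroni multiplicity; defaults to the number of group pairs.
#' @param exact_max Combined-size threshold below which the exact
#'   distribution is used (default 20).
#' @param correct Apply the continuity correction in the normal
#'   approximation (default TRUE; FALSE gives the plain normal
#'   approximation, whose two-group decision is identical to the
#'   Kruskal-Wallis chi-square).
#' @return Tibble, one row per pair: `group1`, `group2`, `n1`, `n2`,
#'   `statistic`, `p_value`, `p_adjusted`, `exact`.
#' @export
pairwise_wilcoxon <- function(data, value = "value", group = "group",
                              k = NULL, exact_max = 20, correct = TRUE) {
  v <- data[[value]]
  g <- as.character(data[[group]])
  .check_groups(v, g)
  labs <- sort(unique(g))
  pairs <- combn(labs, 2)
  k <- k %||% ncol(pairs)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- v[g == pairs[1, j]]
    b <- v[g == pairs[2, j]]
    use_exact <- (length(a) + length(b)) <= exact_max &&
      !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                  correct = correct)
    )
    tibble(group1 = pairs[1, j], group2 = pairs[2, j],
           n1 = length(a), n2 = length(b),
           statistic = unname(wt$statistic), p_value = wt$p.value,
           exact = use_exact)
  })
  mutate(out, p_adjusted = bonferroni(.data$p_value, k), .after = "p_value")
}

#' Two-proportion comparison
#'
#' Compares the proportions `x1/n1` and `x2/n2` of expressed genes between
#' two stages, by default with the two-proportion chi-square test with
#' continuity correction (`method = "chisq"`); Fisher's exact test on the
#' 2x2 table is available as a fallback since no single canonical test is
#' implied by "comparison of proportions". Multiplicity correction is the
#' caller's business (see [bonferroni()]).
#'
#' @param x1,n1,x2,n2 Successes and trials of the two samples.
#' @param method `"chisq"` or `"fisher"`.
#' @return One-row tibble: `estimate1`, `estimate2`, `p_value`, `method`.
#' @export
compare_proportions <- function(x1, n1, x2, n2,
                                method = c("chisq", "fisher")) {
  method <- match.arg(method)
  if (n1 <= 0 || n2 <= 0) abort("sample sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    abort("counts must satisfy 0 <= x <= n")
  }
  p <- if (method == "chisq") {
    suppressWarnings(prop.test(c(x1, x2), c(n1, n2), correct = TRUE))$p.value
  } else {
    fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2))$p.value
  }
  tibble(estimate1 = x1 / n1, estimate2 = x2 / n2, p_value = p,
         method = method)
}
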