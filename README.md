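# devoscope

Stage-resolved analysis of developmental transcriptome time courses with
detection calls — built for asking how molecular interaction signatures
(protein–protein networks, signaling-gene expression, miRNA–target
regulation) change across embryonic development, and in particular whether
anything singles out the mid-developmental *phylotypic period*, the window
where vertebrate embryo morphology is most conserved between species.

The package is aimed at computational biologists working with
multi-stage, replicated expression matrices (log2 values plus
present/absent calls), an interaction pair list, one-to-one ortholog maps,
miRNA target predictions and OBO ontologies. Everything is tidyverse-native:
long tibbles in, tibbles out, S3 fits with `tidy()` / `glance()` /
`autoplot()`.

## What it computes

* **Expression core** — probe→gene collapsing (mean value; present iff a
  strict majority of probe calls is present), per-stage expressed-gene
  counts with replicate averaging, TSV round-trip I/O.
* **Soft clustering** — seeded fuzzy c-means of standardized temporal
  profiles (membership `u_ij = 1/Σ_k (d_ij/d_kj)^(2/(m−1))`, centers
  `Σ u^m x / Σ u^m`), hard assignment and analyst-driven group selection.
* **Stage networks** — presence-filtered interaction subgraph per stage;
  degree, raw betweenness, reachable-set closeness; Spearman correlation of
  centrality with expression per stage and the temporal trend of that
  correlation.
* **Hourglass test** — nested OLS comparison of a parabola against a line
  for expressed-gene counts over log10 developmental time:
  `F = (RSS1 − RSS2)/(RSS2/(n−3))` on (1, n−3) df, Bonferroni over the
  category regressions.
* **Randomization nulls** — cross-species conservation of interacting-pair
  coexpression per developmental metastage against random gene pairs
  (observed/null-mean ratio with a 1%/99% null band); ortholog re-pairing
  confidence bands per functional category; pooled-resplit permutation test
  of the median expression difference between exclusive miRNA target
  groups, `p = (1 + #{|null| ≥ |obs|})/(1 + n_perm)`.
* **Enrichment** — OBO 1.2 parsing, true-path annotation propagation,
  exact hypergeometric tests, the *elim* decorrelation algorithm
  (deepest-first, significant descendants' genes removed from ancestors'
  annotation), BH-FDR per namespace.
* **Group statistics** — Kruskal–Wallis, exact/approximate pairwise
  Wilcoxon with Bonferroni, two-proportion comparisons (chi-square with
  continuity correction, or Fisher).
* **Synthetic study generator** — every input above with planted structure
  (temporal groups, hub–early-expression coupling, per-group cross-species
  conservation, miRNA repression, an enriched ontology term) and full truth
  records, deterministic under one master seed.

## Worked example

```r
library(devoscope)
library(dplyr)

sim <- simulate_study(synth_config(seed = 1))

# declining centrality-expression correlation over development
ct <- centrality_timecourse(sim$interactions, sim$expr, sim$stages)
temporal_trend(ct)
#> # A tibble: 3 × 5
#>   measure        rho  p_value n_stages defined
#>   <chr>        <dbl>    <dbl>    <int> <lgl>
#> 1 degree      -0.609  0.0209        14 TRUE
#> 2 betweenness -0.591  0.0260        14 TRUE
#> 3 closeness    0.112  0.703        14 TRUE

# hourglass signature of the organogenesis group
org <- sim$truth$gene_id[sim$truth$group == "organogenesis"]
counts <- count_expressed(sim$expr, org) |> inner_join(sim$stages, by = "stage")
fit_hourglass(counts, k_tests = 2)
#> Hourglass fit (n = 28, log10 time): F(1, 25) = 133.8, p = 1.57e-11, adjusted p = 3.15e-11
#>   vertex at 148 hours
```

The trend table says expression relates to network centrality much more
strongly at early stages than late ones for the local and path-based
measures (rho declines with time; closeness, dominated by component
structure on sparse stage graphs, shows no stable trend). The hourglass fit
says the organogenesis group's expressed-gene count is far better described
by a parabola peaking at ~148 h (larval) than by a line — the planted
mid-developmental signature, recovered.

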