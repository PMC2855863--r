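# Small expression fixtures built in code.

# expr tibble from a genes x (stage x replicate) value matrix and call matrix
make_expr <- function(values, calls, stages = NULL, replicates = 2) {
  genes <- rownames(values)
  if (is.null(genes)) genes <- rownames(calls)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  n_stage <- ncol(values) / replicates
  stage <- rep(sprintf("s%02d", seq_len(n_stage)), each = replicates)
  repl <- rep(sprintf("r%d", seq_len(replicates)), n_stage)
  out <- tidyr::expand_grid(gene_id = genes, col = seq_len(ncol(values)))
  out$stage <- stage[out$col]
  out$replicate <- repl[out$col]
  out$value <- as.vector(t(values))
  out$call <- as.vector(t(calls))
  out$col <- NULL
  out
}

make_stages <- function(hours) {
  tibble::tibble(stage = sprintf("s%02d", seq_along(hours)), hours = hours)
}

# two well-separated spherical profile groups (for clustering recovery)
separated_profiles <- function(n_per_group = 100, p = 8, sep_sds = 5,
                               seed = 42) {
  set.seed(seed)
  base1 <- rnorm(p)
  dirv <- rnorm(p)
  dirv <- dirv / sqrt(sum(dirv^2))
  # centers sep_sds within-group sds apart per coordinate (on average)
  base2 <- base1 + sep_sds * sqrt(p) * dirv
  x <- rbind(
    matrix(rnorm(n_per_group * p, 0, 1), n_per_group, p, byrow = TRUE) +
      matrix(base1, n_per_group, p, byrow = TRUE),
    matrix(rnorm(n_per_group * p, 0, 1), n_per_group, p, byrow = TRUE) +
      matrix(base2, n_per_group, p, byrow = TRUE)
  )
  rownames(x) <- sprintf("it%03d", seq_len(2 * n_per_group))
  list(x = x, labels = rep(1:2, each = n_per_group))
}

# n_pairs distinct unordered non-self index pairs among 1..n_items
random_pairs <- function(n_items, n_pairs) {
  codes <- integer(0)
  while (length(codes) < n_pairs) {
    a <- sample.int(n_items, 2 * n_pairs, replace = TRUE)
    b <- sample.int(n_items, 2 * n_pairs, replace = TRUE)
    k <- a != b
    i <- pmin(a[k], b[k])
    j <- pmax(a[k], b[k])
    codes <- unique(c(codes, (i - 1) * n_items + j))
  }
  codes <- codes[seq_len(n_pairs)]
  cbind((codes - 1) %/% n_items + 1, (codes - 1) %% n_items + 1)
}

# tiny chain/diamond OBO files written to a temp path
write_obo_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

obo_chain3 <- function() c(
  "format-version: 1.2", "",
  "[Term]", "id: T3", "name: leaf", "namespace: bp", "is_a: T2 ! mid", "",
  "[Term]", "id: T2", "name: mid", "namespace: bp", "is_a: T1 ! root", "",
  "[Term]", "id: T1", "name: root", "namespace: bp", ""
)

obo_diamond <- function() c(
  "format-version: 1.2", "",
  "[Term]", "id: R", "name: root", "namespace: bp", "",
  "[Term]", "id: A", "name: left", "namespace: bp", "is_a: R", "",
  "[Term]", "id: B", "name: right", "namespace: bp", "is_a: R", "",
  "[Term]", "id: L", "name: leaf", "namespace: bp", "is_a: A", "is_a: B", ""
)
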