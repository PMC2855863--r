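# Independent oracles: deliberately naive re-derivations (enumeration,
# closed forms) that never share code with the package implementation.

# --- graph centralities by exhaustive simple-path enumeration (n <= ~8) ---

oracle_centrality <- function(nodes, edges) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      adj[edges$gene_a[r], edges$gene_b[r]] <- TRUE
      adj[edges$gene_b[r], edges$gene_a[r]] <- TRUE
    }
  }
  # all simple paths s -> t by depth-first enumeration
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        paths[[length(paths) + 1]] <<- path
        return()
      }
      for (w in nodes[adj[v, ]]) if (!w %in% path) walk(c(path, w))
    }
    walk(s)
    paths
  }
  betw <- setNames(rep(0, n), nodes)
  dmat <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(dmat) <- 0
  if (n >= 2) {
    for (si in seq_len(n - 1)) for (ti in (si + 1):n) {
      s <- nodes[si]; t <- nodes[ti]
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, 0L) - 1L
      d <- min(lens)
      dmat[s, t] <- dmat[t, s] <- d
      shortest <- paths[lens == d]
      sigma <- length(shortest)
      inner <- unlist(lapply(shortest, function(p) p[-c(1, length(p))]))
      if (length(inner) > 0) {
        tab <- table(inner)
        betw[names(tab)] <- betw[names(tab)] + as.numeric(tab) / sigma
      }
    }
  }
  clo <- vapply(nodes, function(v) {
    d <- dmat[v, setdiff(nodes, v)]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))
  deg <- rowSums(adj)
  tibble::tibble(gene_id = nodes, degree = as.integer(deg),
                 betweenness = unname(betw), closeness = unname(clo))
}

random_small_graph <- function(seed, max_nodes = 8, p_edge = 0.4) {
  set.seed(seed)
  n <- sample(2:max_nodes, 1)
  nodes <- sprintf("n%d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  tibble::tibble(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2])
}

# --- ordinary least squares by normal equations; nested F ---

oracle_hourglass_f <- function(t, y) {
  X1 <- cbind(1, t)
  X2 <- cbind(1, t, t^2)
  b1 <- solve(crossprod(X1), crossprod(X1, y))
  b2 <- solve(crossprod(X2), crossprod(X2, y))
  rss1 <- sum((y - X1 %*% b1)^2)
  rss2 <- sum((y - X2 %*% b2)^2)
  n <- length(y)
  f <- (rss1 - rss2) / (rss2 / (n - 3))
  list(rss1 = rss1, rss2 = rss2, f = f,
       p = stats::pf(f, 1, n - 3, lower.tail = FALSE))
}

# --- Spearman rho by the no-ties rank-difference formula ---

oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# --- hypergeometric upper tail by direct summation of choose() products ---

oracle_hyper_upper <- function(k, K, N, n) {
  support <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  sum(probs[support >= k])
}

# --- exhaustive pooled-resplit null for the median-difference test ---

oracle_median_perm_exact <- function(v1, v2) {
  pooled <- c(v1, v2)
  n1 <- length(v1)
  splits <- combn(length(pooled), n1)
  null <- apply(splits, 2, function(ix) {
    median(pooled[ix]) - median(pooled[-ix])
  })
  obs <- median(v1) - median(v2)
  list(observed = obs, null = null,
       p_two_sided = mean(abs(null) >= abs(obs) - 1e-12))
}

# --- all permutations of 1..n (n <= 6) ---

all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
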