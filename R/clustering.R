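#' Standardize temporal profiles
#'
#' Centers and scales each row (profile) to mean 0 and standard deviation 1
#' (n - 1 denominator), the conventional preprocessing before fuzzy c-means
#' clustering of expression time courses so that profile *shape*, not
#' amplitude, drives the distances.
#'
#' @param x A tibble whose first column is an item identifier and whose
#'   remaining columns are the numeric profile, or a plain numeric matrix
#'   with rownames.
#' @return Same shape as the input with each row standardized.
#' @export
standardize_rows <- function(x) {
  mat <- .profile_matrix(x)
  s <- apply(mat, 1, sd)
  if (any(s == 0)) {
    abort(paste0("constant profile(s) cannot be standardized: ",
                 toString(head(rownames(mat)[s == 0], 5))))
  }
  out <- (mat - rowMeans(mat)) / s
  .profile_like(x, out)
}

.profile_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
    return(x)
  }
  mat <- as.matrix(x[-1])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(x[[1]])
  mat
}

.profile_like <- function(x, mat) {
  if (is.matrix(x)) return(mat)
  out <- as_tibble(mat)
  out <- bind_cols(x[1], out)
  names(out) <- names(x)
  out
}

#' Fuzzy c-means soft clustering
#'
#' Soft-clusters standardized temporal profiles into `c` clusters by the
#' fuzzy c-means alternating scheme: memberships
#' \eqn{u_{ij} = 1 / \sum_k (d_{ij}/d_{kj})^{2/(m-1)}} for Euclidean
#' distances \eqn{d} to the current centers, then centers
#' \eqn{c_i = \sum_j u_{ij}^m x_j / \sum_j u_{ij}^m}, iterated until the
#' largest center displacement falls below `tol` or `max_iter` is reached.
#' Centers are initialized as `c` distinct data rows drawn by seeded
#' sampling, so a run is fully determined by its seed. An item coincident
#' with one or more centers splits its membership equally among the
#' coincident centers (zero-distance tie rule).
#'
#' @param x Profiles: tibble with an id column first, or matrix with
#'   rownames. One row per item (gene or miRNA), one column per stage.
#' @param c Number of clusters (the gene analysis of the motivating design
#'   uses 25; the miRNA onset analysis uses 2).
#' @param m Fuzzifier, > 1; default 2 (the canonical choice).
#' @param tol Convergence threshold on the maximum absolute center
#'   displacement between iterations.
#' @param max_iter Iteration cap.
#' @param seed Integer seed controlling center initialization.
#' @param standardize Standardize rows first (default TRUE, matching the
#'   usual soft-clustering workflow); set FALSE to cluster raw profiles.
#' @return An object of class `fcm_fit` with elements `membership`
#'   (items x clusters matrix, rows summing to 1), `centers` (clusters x
#'   stages matrix), `objective` (per-iteration trace of
#'   \eqn{\sum u^m d^2}, non-increasing), `n_iter`, `converged`, and the
#'   call parameters. Use [tidy()], [glance()], [autoplot()] and
#'   [assign_clusters()] to work with it.
#' @export
fuzzy_cmeans <- function(x, c, m = 2, tol = 1e-6, max_iter = 200, seed = 1,
                         standardize = TRUE) {
  if (c < 1) abort("c must be >= 1")
  if (m <= 1) abort("fuzzifier m must be > 1")
  if (standardize) x <- standardize_rows(x)
  mat <- .profile_matrix(x)
  n <- nrow(mat)
  if (c > n) abort(sprintf("c = %d exceeds the number of items (%d)", c, n))

  set.seed(seed)
  centers <- mat[sample.int(n, c), , drop = FALSE]
  rownames(centers) <- as.character(seq_len(c))

  expo <- 2 / (m - 1)
  objective <- numeric(0)
  converged <- FALSE
  u <- NULL
  for (iter in seq_len(max_iter)) {
    d2 <- .sq_dist(mat, centers)                     # n x c
    u <- .fcm_membership(d2, expo)
    um <- u^m
    objective <- c(objective, sum(um * d2))
    new_centers <- crossprod(um, mat) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  # memberships consistent with the final centers
  u <- .fcm_membership(.sq_dist(mat, centers), expo)
  dimnames(u) <- list(rownames(mat), seq_len(c))

  structure(
    list(
      membership = u,
      centers = centers,
      objective = objective,
      n_iter = length(objective),
      converged = converged,
      c = c, m = m, tol = tol, seed = seed,
      standardized = standardize,
      profiles = mat,
      stage_cols = colnames(mat)
    ),
    class = "fcm_fit"
  )
}

# squared Euclidean distances between rows of x and rows of centers
.sq_dist <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) -
    2 * tcrossprod(x, centers)
  pmax(d2, 0)
}

.fcm_membership <- function(d2, expo) {
  u <- matrix(0, nrow(d2), ncol(d2))
  zero <- d2 < .Machine$double.eps
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    u[hit, ] <- zero[hit, , drop = FALSE] /
      rowSums(zero[hit, , drop = FALSE])
  }
  if (any(!hit)) {
    w <- d2[!hit, , drop = FALSE]^(-expo / 2)
    u[!hit, ] <- w / rowSums(w)
  }
  u
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf(
    "Fuzzy c-means fit: %d items, c = %d, m = %g, %d iterations%s\n",
    nrow(x$membership), x$c, x$m, x$n_iter,
    if (x$converged) " (converged)" else " (iteration cap reached)"
  ))
  invisible(x)
}

#' @describeIn fuzzy_cmeans Long tibble of memberships: `item_id`,
#'   `cluster`, `membership`.
#' @param x,object An `fcm_fit`.
#' @param ... Unused.
#' @export
tidy.fcm_fit <- function(x, ...) {
  as_tibble(x$membership, rownames = "item_id") |>
    tidyr::pivot_longer(-"item_id", names_to = "cluster",
                        values_to = "membership") |>
    mutate(cluster = as.integer(.data$cluster))
}

#' @describeIn fuzzy_cmeans One-row summary (clusters, fuzzifier,
#'   iterations, final objective, convergence).
#' @export
glance.fcm_fit <- function(x, ...) {
  tibble(
    n_items = nrow(x$membership), c = x$c, m = x$m,
    n_iter = x$n_iter, objective = x$objective[x$n_iter],
    converged = x$converged
  )
}

#' Hard cluster assignment from a soft fit
#'
#' Assigns each item to its argmax-membership cluster; exact ties go to the
#' lowest cluster index (documented tie-break).
#'
#' @param fit An [fuzzy_cmeans()] fit.
#' @return Tibble `item_id`, `cluster`, `membership` (the winning score).
#' @export
assign_clusters <- function(fit) {
  idx <- max.col(fit$membership, ties.method = "first")
  tibble(
    item_id = rownames(fit$membership),
    cluster = idx,
    membership = fit$membership[cbind(seq_along(idx), idx)]
  )
}

#' Select a gene group from chosen clusters
#'
#' Forms a labelled gene set from the union of the argmax-assignment classes
#' of the requested cluster ids, carrying each member's membership score.
#' Cluster ids are properties of a particular clustering run, so they are
#' always supplied by the analyst.
#'
#' @param fit An [fuzzy_cmeans()] fit.
#' @param cluster_ids Integer cluster ids to pool.
#' @param label Group label (e.g. `"early"`, `"organogenesis"`, `"late"`).
#' @return Tibble `label`, `item_id`, `cluster`, `membership`.
#' @export
select_clusters <- function(fit, cluster_ids, label = "selected") {
  bad <- setdiff(cluster_ids, seq_len(fit$c))
  if (length(bad) > 0) abort(paste0("unknown cluster id(s): ", toString(bad)))
  out <- assign_clusters(fit) |>
    filter(.data$cluster %in% cluster_ids) |>
    mutate(label = label, .before = 1)
  if (nrow(out) == 0) abort("selection is empty: no item assigned to the requested clusters")
  out
}

#' @describeIn fuzzy_cmeans Profile plot per cluster, each line a member
#'   colored by membership score (the classic soft-clustering display).
#' @export
autoplot.fcm_fit <- function(object, ...) {
  prof <- as_tibble(.fcm_profiles(object), rownames = "item_id") |>
    tidyr::pivot_longer(-"item_id", names_to = "stage", values_to = "value")
  hard <- assign_clusters(object)
  dat <- inner_join(prof, hard, by = "item_id") |>
    mutate(stage = factor(.data$stage, levels = object$stage_cols))
  ggplot2::ggplot(dat, ggplot2::aes(.data$stage, .data$value,
                                    group = .data$item_id,
                                    colour = .data$membership)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "stage", y = "standardized expression",
                  colour = "membership")
}

.fcm_profiles <- function(fit) {
  fit$profiles %||% fit$centers
}
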