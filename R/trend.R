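#' Hourglass test: quadratic versus linear trend in expressed-gene counts
#'
#' Fits an ordinary least-squares linear model and a nested quadratic model
#' (parabola) of a per-stage expressed-gene count against developmental
#' time, and tests whether the quadratic term significantly improves the fit
#' with the extra-sum-of-squares F test:
#' \deqn{F = \frac{RSS_1 - RSS_2}{RSS_2 / (n - 3)}}
#' on (1, n - 3) degrees of freedom. A significant parabola with an interior
#' vertex is the operational signature of hourglass-like behavior (a
#' mid-developmental extremum). Time enters as log10(hours) by default,
#' matching the log-scaled axes on which developmental time courses are
#' normally examined; set `log_time = FALSE` for linear hours. Counts are
#' supplied per replicate (two points per stage in a two-replicate design);
#' pass per-stage means instead if preferred.
#'
#' Degenerate cases: a perfectly linear response (`RSS1` ~ 0) makes the test
#' meaningless — the fit is flagged `degenerate` and p = 1. An exactly
#' parabolic response with linear lack of fit (`RSS2` ~ 0, `RSS1` > 0) is
#' flagged `perfect_fit` and p is reported as the lower bound 0.
#'
#' @param counts Data frame with a time column and a count column; rows are
#'   (stage, replicate) points.
#' @param k_tests Bonferroni multiplicity for the adjusted p-value (e.g. 7
#'   when seven category regressions are examined together). Default 1.
#' @param log_time Regress on log10(hours) (default) or raw hours.
#' @param time_col,count_col Column names (defaults `"hours"`, `"count"`).
#' @return An object of class `hourglass_fit`; see [tidy()] / [glance()] /
#'   [autoplot()] methods.
#' @export
fit_hourglass <- function(counts, k_tests = 1, log_time = TRUE,
                          time_col = "hours", count_col = "count") {
  if (!all(c(time_col, count_col) %in% names(counts))) {
    abort(paste0("counts must have columns '", time_col, "' and '",
                 count_col, "'"))
  }
  hours <- counts[[time_col]]
  y <- counts[[count_col]]
  n <- length(y)
  if (n < 4) abort("need at least 4 points to compare linear and quadratic fits")
  if (any(hours <= 0)) abort("times must be positive hours")
  t <- if (log_time) log10(hours) else hours

  fit1 <- lm(y ~ t)
  fit2 <- lm(y ~ t + I(t^2))
  rss1 <- sum(fit1$residuals^2)
  rss2 <- sum(fit2$residuals^2)
  tss <- sum((y - mean(y))^2)
  eps <- 1e-12 * max(tss, 1)

  degenerate <- rss1 <= eps
  perfect_fit <- !degenerate && rss2 <= eps
  if (degenerate) {
    f <- 0
    p <- 1
  } else if (perfect_fit) {
    f <- Inf
    p <- 0
  } else {
    f <- (rss1 - rss2) / (rss2 / (n - 3))
    p <- pf(f, 1, n - 3, lower.tail = FALSE)
  }
  b <- coef(fit2)
  vertex_t <- if (!is.na(b[3]) && b[3] != 0) unname(-b[2] / (2 * b[3])) else NA_real_
  vertex_hours <- if (is.na(vertex_t)) NA_real_ else if (log_time) 10^vertex_t else vertex_t

  structure(
    list(
      n = n,
      linear_coef = unname(coef(fit1)),
      quadratic_coef = unname(b),
      rss1 = rss1, rss2 = rss2,
      statistic = f, df = c(1, n - 3),
      p_value = p,
      p_adjusted = min(1, k_tests * p),
      k_tests = k_tests,
      vertex_hours = vertex_hours,
      degenerate = degenerate, perfect_fit = perfect_fit,
      log_time = log_time,
      data = tibble(hours = hours, t = t, count = y)
    ),
    class = "hourglass_fit"
  )
}

#' @export
print.hourglass_fit <- function(x, ...) {
  cat(sprintf(
    "Hourglass fit (n = %d, %s time): F(1, %d) = %.4g, p = %.3g, adjusted p = %.3g\n",
    x$n, if (x$log_time) "log10" else "linear", x$df[2],
    x$statistic, x$p_value, x$p_adjusted
  ))
  if (x$degenerate) cat("  flag: degenerate (linear fit is already exact)\n")
  if (x$perfect_fit) cat("  flag: perfect quadratic fit (p reported as lower bound 0)\n")
  if (!is.na(x$vertex_hours)) {
    cat(sprintf("  vertex at %.3g hours\n", x$vertex_hours))
  }
  invisible(x)
}

#' @describeIn fit_hourglass Coefficients of both nested models as a long
#'   tibble (`model`, `term`, `estimate`).
#' @param x,object An `hourglass_fit`.
#' @param ... Unused.
#' @export
tidy.hourglass_fit <- function(x, ...) {
  bind_rows(
    tibble(model = "linear", term = c("(Intercept)", "t"),
           estimate = x$linear_coef),
    tibble(model = "quadratic", term = c("(Intercept)", "t", "I(t^2)"),
           estimate = x$quadratic_coef)
  )
}

#' @describeIn fit_hourglass One-row model comparison summary.
#' @export
glance.hourglass_fit <- function(x, ...) {
  tibble(
    n = x$n, rss_linear = x$rss1, rss_quadratic = x$rss2,
    statistic = x$statistic, df1 = x$df[1], df2 = x$df[2],
    p_value = x$p_value, p_adjusted = x$p_adjusted,
    vertex_hours = x$vertex_hours,
    degenerate = x$degenerate, perfect_fit = x$perfect_fit
  )
}

#' @describeIn fit_hourglass Scatter of counts over time with the fitted
#'   line and parabola.
#' @export
autoplot.hourglass_fit <- function(object, ...) {
  grid <- tibble(t = seq(min(object$data$t), max(object$data$t),
                         length.out = 200))
  grid$linear <- object$linear_coef[1] + object$linear_coef[2] * grid$t
  grid$quadratic <- object$quadratic_coef[1] +
    object$quadratic_coef[2] * grid$t + object$quadratic_coef[3] * grid$t^2
  long <- tidyr::pivot_longer(grid, -"t", names_to = "model",
                              values_to = "fit")
  ggplot2::ggplot(object$data, ggplot2::aes(.data$t, .data$count)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = long,
                       ggplot2::aes(y = .data$fit, linetype = .data$model)) +
    ggplot2::labs(
      x = if (object$log_time) "log10 hours post fertilization" else "hours",
      y = "expressed genes"
    )
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of tests in the family and caps at
#' 1.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param k Family size; must be at least `length(p)`.
#' @return Adjusted p-values, same order as the input.
#' @export
bonferroni <- function(p, k) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  if (k < length(p)) abort("k must be at least the number of p-values")
  pmin(1, k * p)
}
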