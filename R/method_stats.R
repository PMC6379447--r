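#' Paired sample of infarct ratios from two methods
#'
#' The method-comparison design: each section (animal) is analyzed by
#' two methods — e.g. supervised thresholding versus manual tracing —
#' giving paired ratios aligned by label.
#'
#' @param x,y ratios (percent) from method A and method B.
#' @param labels section/animal identifiers; default `1..n`.
#' @return an object of class `paired_sample`.
#' @export
paired_sample <- function(x, y, labels = as.character(seq_along(x))) {
  if (length(x) != length(y) || length(x) != length(labels))
    stop("paired_sample: x, y and labels must have equal length",
         call. = FALSE)
  if (length(x) < 2L)
    stop("paired_sample: need n >= 2 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("paired_sample: missing values are not allowed", call. = FALSE)
  structure(list(labels = as.character(labels),
                 x = as.numeric(x), y = as.numeric(y)),
            class = "paired_sample")
}

test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dfs <- if (length(x$df) == 2L) sprintf("df = (%g, %g)", x$df[1], x$df[2])
         else if (!is.null(x$df) && !is.na(x$df)) sprintf("df = %g", x$df)
         else ""
  cat(sprintf("%s: statistic = %.4f%s, p = %.4g\n", x$method, x$statistic,
              if (nzchar(dfs)) paste0(", ", dfs) else "", x$p_value))
  invisible(x)
}

#' Two-tailed paired Student's t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences
#' `d = x - y`, with the n-1 sample standard deviation, `df = n - 1`,
#' and a two-tailed p-value. Constant differences (zero variance,
#' including `x == y` exactly) make `t` undefined and raise a
#' degenerate-sample error — the caller decides how to interpret
#' "the two methods agreed on every section" (see
#' [compare_methods()]).
#'
#' @param s a [paired_sample].
#' @return a `test_result` with `statistic`, `df`, `p_value`.
#' @export
paired_t_test <- function(s) {
  stopifnot(inherits(s, "paired_sample"))
  d <- s$x - s$y
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0)
    stop("paired_t_test: differences have zero variance (degenerate sample)",
         call. = FALSE)
  t <- mean(d) / (sd_d / sqrt(n))
  test_result(t, n - 1L, 2 * stats::pt(-abs(t), n - 1L), "paired t-test")
}

#' Pearson correlation with two-tailed p-value
#'
#' `r = cov(x, y) / (sd(x) sd(y))`; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' two-tailed. Perfect correlation (`|r| = 1`) gives `p = 0`.
#'
#' @param s a [paired_sample] with `n >= 3` and both variables
#'   nonconstant.
#' @return a `test_result` with `statistic` = r, `df` = n - 2.
#' @export
pearson_r <- function(s) {
  stopifnot(inherits(s, "paired_sample"))
  n <- length(s$x)
  if (n < 3L)
    stop("pearson_r: need n >= 3", call. = FALSE)
  if (stats::sd(s$x) == 0 || stats::sd(s$y) == 0)
    stop("pearson_r: constant variable (degenerate sample)", call. = FALSE)
  dx <- s$x - mean(s$x); dy <- s$y - mean(s$y)
  r <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2L)
  }
  test_result(r, n - 2L, p, "Pearson correlation")
}

#' Ordinary least-squares regression of y on x
#'
#' Simple linear regression by the closed-form normal equations:
#' `slope = cov(x, y) / var(x)`, `intercept = mean(y) - slope *
#' mean(x)`. For simple OLS `r_squared` equals the squared Pearson
#' correlation (0 when `y` is constant).
#'
#' @param s a [paired_sample] with nonconstant `x`.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
linear_regression <- function(s) {
  stopifnot(inherits(s, "paired_sample"))
  dx <- s$x - mean(s$x); dy <- s$y - mean(s$y)
  sxx <- sum(dx^2)
  if (sxx == 0)
    stop("linear_regression: constant x (degenerate design)", call. = FALSE)
  slope <- sum(dx * dy) / sxx
  syy <- sum(dy^2)
  list(slope = slope,
       intercept = mean(s$y) - slope * mean(s$x),
       r_squared = if (syy == 0) 0 else slope^2 * sxx / syy)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic `D = sup |F_n - Phi_(mean, sd)|` against a
#' normal with the sample's own mean and n-1 SD, with the classical
#' asymptotic KS p-value `Q(sqrt(n) * D)`. Because the null parameters
#' are estimated from the same sample, this p-value is conservative
#' (the Lilliefors situation); it is documented as an approximation and
#' used only as a screening check, mirroring common practice in
#' method-comparison reports.
#'
#' @param values numeric sample, `n >= 3`, nonconstant.
#' @return a `test_result` with `statistic` = D (in `[0, 1]`).
#' @export
ks_normality <- function(values) {
  n <- length(values)
  if (n < 3L)
    stop("ks_normality: need n >= 3", call. = FALSE)
  if (anyNA(values)) stop("ks_normality: missing values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("ks_normality: constant sample (degenerate)", call. = FALSE)
  xs <- sort(values)
  fn <- stats::pnorm(xs, mean(values), stats::sd(values))
  d <- max(pmax(seq_len(n) / n - fn, fn - (seq_len(n) - 1) / n))
  test_result(d, NA_real_, ks_p_asymptotic(sqrt(n) * d),
              "Kolmogorov-Smirnov normality check")
}

# Asymptotic two-sided KS tail probability
# Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2).
# For small lambda the alternating series converges poorly, so the
# Jacobi-theta transform of the same function is used there (the same
# split classical implementations make).
# Truncation follows the classical implementation (term cut-off at
# tol = 1e-6) so results are bit-comparable with standard references.
ks_p_asymptotic <- function(lambda, tol = 1e-6) {
  if (lambda <= 0) return(1)
  if (lambda < 1) {
    k_max <- floor(sqrt(2 - log(tol)))
    i <- seq.int(1L, by = 2L, length.out = ceiling((k_max - 1) / 2))
    s <- sum(exp(-i^2 * pi^2 / (8 * lambda^2)) / lambda)
    p <- 1 - sqrt(2 * pi) * s
  } else {
    s <- 1; k <- 1; term <- Inf
    while (abs(term) > tol) {
      term <- 2 * (-1)^k * exp(-2 * k^2 * lambda^2)
      s <- s + term
      k <- k + 1
    }
    p <- 1 - s
  }
  min(max(p, 0), 1)
}

#' F-test for equality of two variances
#'
#' `F = s^2_larger / s^2_smaller` (so `F >= 1` by construction), with
#' degrees of freedom ordered to match, and a two-tailed p-value
#' `2 * P(F_(df1, df2) >= F)` capped at 1. Reported in the CLI as the
#' "variance F-test". Method-comparison write-ups sometimes label a
#' variance-similarity check "Fisher's exact test"; an exact
#' contingency-table test cannot assess variances, so the F-test of
#' variance equality is what this function provides under its correct
#' name.
#'
#' @param x,y numeric samples, each `n >= 2` and nonconstant.
#' @return a `test_result` with `statistic` = F and `df` a pair.
#' @export
variance_ratio_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("variance_ratio_test: need n >= 2 in each sample", call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0)
    stop("variance_ratio_test: zero variance (degenerate sample)",
         call. = FALSE)
  if (vx >= vy) {
    f <- vx / vy; df <- c(length(x) - 1L, length(y) - 1L)
  } else {
    f <- vy / vx; df <- c(length(y) - 1L, length(x) - 1L)
  }
  p <- min(1, 2 * stats::pf(f, df[1], df[2], lower.tail = FALSE))
  test_result(f, df, p, "variance F-test")
}

#' Full method-comparison report
#'
#' Bundles the standard agreement analysis for paired ratios from two
#' methods: KS normality check on the paired differences, two-tailed
#' paired t-test, Pearson correlation, and the OLS fit of method B on
#' method A. When the two methods agree exactly on every section the
#' paired t is undefined (zero-variance differences); the report
#' records this as a note instead of failing, since exact agreement is
#' the strongest possible "no difference" outcome.
#'
#' @param s a [paired_sample].
#' @return an object of class `method_comparison`.
#' @export
compare_methods <- function(s) {
  stopifnot(inherits(s, "paired_sample"))
  d <- s$x - s$y
  normality <- if (stats::sd(d) == 0 || length(d) < 3L) NULL
               else ks_normality(d)
  if (stats::sd(d) == 0) {
    t_res <- NULL
    note <- "methods identical on every section; paired t undefined (treated as no difference)"
  } else {
    t_res <- paired_t_test(s)
    note <- NULL
  }
  structure(list(n = length(s$x),
                 normality = normality,
                 paired_t = t_res,
                 correlation = pearson_r(s),
                 regression = linear_regression(s),
                 note = note),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Method comparison, n = %d paired sections\n", x$n))
  if (!is.null(x$normality)) {
    cat("  differences: "); print(x$normality)
  }
  if (!is.null(x$paired_t)) {
    cat("  "); print(x$paired_t)
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  cat("  "); print(x$correlation)
  cat(sprintf("  OLS fit: slope = %.4f, intercept = %.4f, r^2 = %.4f\n",
              x$regression$slope, x$regression$intercept,
              x$regression$r_squared))
  invisible(x)
}
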