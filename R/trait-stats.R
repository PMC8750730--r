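# Descriptive statistics for line-by-trait panels: Pearson correlation with
# a t-based significance threshold, PCA on the correlation matrix, simple
# linear regression, and one-way ANOVA with least significant difference.

#' Critical Pearson correlation for a two-tailed test
#'
#' The smallest |r| significant at level `alpha` for a sample of `n` pairs:
#' `r_crit = t / sqrt(t^2 + df)` with `df = n - 2` and `t` the two-tailed
#' `1 - alpha/2` quantile of the t-distribution on `df` degrees of freedom.
#'
#' @param n Number of paired observations (>= 3).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return The critical correlation in (0, 1).
#' @examples
#' critical_r(40, 0.05)  # 0.312 to 3 decimal places
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (n < 3) stop("need n >= 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  df <- n - 2
  t <- stats::qt(1 - alpha / 2, df)
  t / sqrt(t^2 + df)
}

#' Between-trait Pearson correlation matrix with significance flags
#'
#' @param table A [trait_table()] with at least 3 complete lines and no
#'   constant trait column. Missing values are refused; use
#'   [drop_incomplete_lines()] first to opt in to dropping.
#' @param alpha Significance level for the critical-r threshold.
#' @return An object of class `correlation_result` with `traits`, `r_matrix`,
#'   `n`, `df`, `critical_r` and the logical `significant` matrix
#'   (`|r| > critical_r`, diagonal `FALSE`).
#' @export
correlation_matrix <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "trait_table"))
  x <- table$values
  if (anyNA(x))
    stop("table contains missing values; use drop_incomplete_lines() first")
  if (nrow(x) < 3L) stop("need at least 3 lines")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant trait column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  r <- stats::cor(x)
  n <- nrow(x)
  rc <- critical_r(n, alpha)
  sig <- abs(r) > rc
  diag(sig) <- FALSE
  structure(list(traits = colnames(x), r_matrix = r, n = n, df = n - 2L,
                 critical_r = rc, alpha = alpha, significant = sig),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, digits = 2, ...) {
  cat("Pearson correlation of", length(x$traits), "traits over", x$n,
      "lines\n")
  cat(sprintf("critical |r| = %.3f at alpha = %g (df = %d)\n",
              x$critical_r, x$alpha, x$df))
  print(round(x$r_matrix, digits))
  invisible(x)
}

#' Principal component analysis on the correlation matrix
#'
#' Eigendecomposition of the between-trait correlation matrix. Component k
#' explains `lambda_k / p` of the total standardized variance (`p` traits);
#' loadings are eigenvectors scaled by `sqrt(lambda)`. For determinism the
#' largest-magnitude element of each eigenvector is made positive.
#'
#' @param table A [trait_table()], passed to [correlation_matrix()].
#' @return An object of class `pca_result` with `loadings` (trait x
#'   component), `variance_fraction` (sums to 1), `eigenvalues` and
#'   `n_components`.
#' @export
pca_on_correlation <- function(table) {
  cr <- correlation_matrix(table)
  eg <- eigen(cr$r_matrix, symmetric = TRUE)
  p <- length(cr$traits)
  vec <- eg$vectors
  for (k in seq_len(p)) {
    j <- which.max(abs(vec[, k]))
    if (vec[j, k] < 0) vec[, k] <- -vec[, k]
  }
  lam <- pmax(eg$values, 0)
  loadings <- vec %*% diag(sqrt(lam), p)
  dimnames(loadings) <- list(cr$traits, paste0("PC", seq_len(p)))
  structure(list(loadings = loadings,
                 variance_fraction = lam / p,
                 eigenvalues = lam,
                 n_components = p),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, n = 2, ...) {
  cat("PCA on correlation matrix:", x$n_components, "components\n")
  pct <- 100 * x$variance_fraction
  for (k in seq_len(min(n, x$n_components)))
    cat(sprintf("  PC%d: %.1f%% of variation\n", k, pct[k]))
  invisible(x)
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x`, reporting the squared Pearson
#' correlation as the fit statistic.
#'
#' @param x,y Numeric vectors of equal length (>= 3); `x` must not be
#'   constant.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("x is constant: regression undefined")
  fit <- stats::lm(y ~ x)
  # exact fits are legitimate here; silence the perfect-fit note
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2,
       n = length(x))
}

#' One-way ANOVA with least significant difference
#'
#' Standard one-way analysis of variance over replicate groups, with the LSD
#' at level `alpha` for a balanced replicate count:
#' `LSD = t(1 - alpha/2, df_error) * sqrt(2 MSE / r)`.
#'
#' @param groups List of numeric replicate vectors, one per group (>= 2
#'   groups, >= 2 replicates each).
#' @param alpha Significance level (default 0.05).
#' @return List with `f_statistic`, `p_value`, `mse`, `lsd`, `df_between`,
#'   `df_error`. With zero within-group variance and non-zero between-group
#'   variance, `f_statistic` is `Inf` and `p_value` 0 (degenerate case
#'   flagged by `lsd = 0`).
#' @export
one_way_anova_lsd <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1L)) < 2L))
    stop("need at least 2 replicates per group")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups),
                    vapply(groups, length, integer(1L))))
  fit <- stats::aov(value ~ grp)
  tab <- summary(fit)[[1L]]  # row 1 = between groups, row 2 = residuals
  mse <- tab[2L, "Mean Sq"]
  f <- tab[1L, "F value"]
  p <- tab[1L, "Pr(>F)"]
  df_err <- tab[2L, "Df"]
  between <- tab[1L, "Mean Sq"]
  # zero within-group variance (up to floating-point noise): flag the limit
  if (is.na(f) || mse <= 1e-12 * max(between, .Machine$double.xmin)) {
    mse <- 0
    f <- if (between > 0) Inf else 0
    p <- if (between > 0) 0 else 1
  }
  r <- length(groups[[1L]])
  lsd <- stats::qt(1 - alpha / 2, df_err) * sqrt(2 * mse / r)
  list(f_statistic = f, p_value = p, mse = mse, lsd = lsd,
       df_between = tab[1L, "Df"], df_error = df_err)
}
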