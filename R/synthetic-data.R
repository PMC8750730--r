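# Seeded generators for every input the pipeline consumes: correlated
# line-by-trait matrices, replicated GxE trials with known variance
# components, and chained parent-offspring generations with known
# heritability.

# Run `expr` under a purpose-specific seed, restoring the caller's RNG state.
# Deriving a sub-seed from (seed, purpose) keeps generator outputs stable when
# new generators are added: each draws from its own stream.
with_stream <- function(seed, purpose, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  sub <- (abs(as.numeric(seed)) * 48271 + h * 69621) %% 2147483629
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(sub))
  expr
}

#' Specify per-trait distributions and their correlation structure
#'
#' @param means Named numeric vector of trait means (trait units).
#' @param sds Named numeric vector of strictly positive trait standard
#'   deviations, same names and order as `means`.
#' @param correlation Symmetric target correlation matrix with unit diagonal
#'   and entries in [-1, 1]; defaults to the identity (independent traits).
#' @param bounds Optional two-column matrix (low, high) of admissible ranges
#'   per trait; rows of the simulated table violating any bound are redrawn.
#' @return An object of class `trait_distribution_spec`.
#' @export
trait_distribution_spec <- function(means, sds,
                                    correlation = diag(length(means)),
                                    bounds = NULL) {
  p <- length(means)
  stopifnot(length(sds) == p, all(is.finite(means)), all(is.finite(sds)))
  if (any(sds <= 0)) stop("trait standard deviations must be > 0")
  correlation <- as.matrix(correlation)
  if (!all(dim(correlation) == p))
    stop("correlation matrix dimension must match trait count")
  if (max(abs(correlation - t(correlation))) > 1e-8)
    stop("correlation matrix must be symmetric")
  if (any(abs(diag(correlation) - 1) > 1e-12))
    stop("correlation diagonal must be exactly 1")
  if (any(correlation < -1 | correlation > 1))
    stop("correlation entries must lie in [-1, 1]")
  if (is.null(names(means))) names(means) <- paste0("trait", seq_len(p))
  names(sds) <- names(means)
  dimnames(correlation) <- list(names(means), names(means))
  if (!is.null(bounds)) {
    bounds <- as.matrix(bounds)
    stopifnot(nrow(bounds) == p, ncol(bounds) == 2L)
    rownames(bounds) <- names(means)
  }
  structure(list(means = means, sds = sds, correlation = correlation,
                 bounds = bounds),
            class = "trait_distribution_spec")
}

#' Default distribution spec for the selection-index trait panel
#'
#' Twelve traits (five yield, seven seed-composition) with means and standard
#' deviations placed inside the ranges observed for the bambara groundnut
#' gene pool, and the published between-trait correlation structure of the
#' 40-line selection-index panel as the target correlation. Percentage-typed
#' traits are bounded to [0, 100], weights and counts to non-negative values.
#'
#' @return A [trait_distribution_spec()] for the 12-trait panel.
#' @export
default_trait_spec <- function() {
  nm <- c("Seed number", "Dry pod weight", "Dry seed weight",
          "Single seed size", "Shelling percentage", "Protein", "Lipid",
          "Total carbohydrate", "Oleic acid", "Lignoceric acid",
          "Linoleic acid", "Linolenic acid")
  means <- c(60, 45, 30, 0.55, 55, 21, 6.4, 64, 22, 2, 39, 2.5)
  sds <- c(20, 15, 10, 0.15, 12, 3.2, 1.1, 2.7, 3.5, 0.5, 3, 0.7)
  names(means) <- names(sds) <- nm
  # published 40-line between-trait correlations, lower triangle by row
  lt <- c(
    0.88,
    0.94, 0.97,
    0.42, 0.65, 0.62,
    -0.30, -0.49, -0.37, -0.32,
    -0.11, 0.08, 0.02, 0.25, -0.15,
    0.44, 0.38, 0.41, 0.31, -0.20, 0.09,
    0.00, -0.10, -0.07, -0.22, 0.14, -0.91, -0.40,
    0.43, 0.42, 0.43, 0.35, -0.28, 0.30, 0.62, -0.43,
    0.48, 0.47, 0.51, 0.32, -0.26, 0.18, 0.38, -0.21, 0.55,
    -0.15, -0.16, -0.18, -0.16, 0.04, 0.07, -0.19, -0.04, -0.35, -0.28,
    -0.46, -0.43, -0.43, -0.30, 0.36, -0.16, -0.78, 0.37, -0.63, -0.38, 0.05
  )
  r <- diag(12)
  k <- 1L
  for (i in 2:12) for (j in 1:(i - 1)) {
    r[i, j] <- r[j, i] <- lt[k]
    k <- k + 1L
  }
  bounds <- cbind(low = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                  high = c(Inf, Inf, Inf, Inf, 100, 100, 100, 100,
                           100, 100, 100, 100))
  trait_distribution_spec(means, sds, r, bounds)
}

#' Repair a correlation matrix to positive semidefiniteness
#'
#' Published correlation tables carry rounded entries and need not be
#' positive semidefinite. This clips eigenvalues at a small floor,
#' reassembles the matrix, and rescales the diagonal back to 1. Already-PSD
#' inputs are returned unchanged, making the repair idempotent.
#'
#' @param matrix Symmetric matrix with unit diagonal.
#' @param floor Eigenvalue floor (default `1e-8`).
#' @return The repaired correlation matrix, with attribute `max_change`
#'   giving the largest entry-wise modification.
#' @export
repair_correlation <- function(matrix, floor = 1e-8) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("input must be a symmetric square matrix")
  if (any(abs(diag(m) - 1) > 1e-8)) stop("input diagonal must be 1")
  eg <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(eg$values) >= floor) {
    attr(m, "max_change") <- 0
    return(m)
  }
  lam <- pmax(eg$values, floor)
  out <- eg$vectors %*% diag(lam, length(lam)) %*% t(eg$vectors)
  d <- 1 / sqrt(diag(out))
  out <- out * tcrossprod(d)
  diag(out) <- 1
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(m)
  attr(out, "max_change") <- max(abs(out - m))
  out
}

#' Simulate a correlated line-by-trait matrix
#'
#' Draws line rows from a multivariate normal distribution with the
#' requested means, standard deviations and (PSD-repaired) target
#' correlation. When bounds are given, rows violating any bound are redrawn
#' (rejection resampling), which preserves the correlation structure better
#' than clipping.
#'
#' @param spec A [trait_distribution_spec()].
#' @param n_lines Number of lines to simulate.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param max_retries Redraw passes allowed before giving up (default 100).
#' @return A [trait_table()] of simulated lines.
#' @export
generate_trait_matrix <- function(spec, n_lines, seed, max_retries = 100L) {
  stopifnot(inherits(spec, "trait_distribution_spec"), n_lines >= 1L)
  r <- repair_correlation(spec$correlation)
  sigma <- r * tcrossprod(spec$sds)
  p <- length(spec$means)
  with_stream(seed, "trait_matrix", {
    x <- MASS::mvrnorm(n_lines, mu = spec$means, Sigma = sigma)
    if (n_lines == 1L) x <- matrix(x, nrow = 1L)
    colnames(x) <- names(spec$means)
    if (!is.null(spec$bounds)) {
      lo <- spec$bounds[, 1L]
      hi <- spec$bounds[, 2L]
      bad_row <- function(m)
        which(rowSums(sweep(m, 2L, lo, "<") | sweep(m, 2L, hi, ">")) > 0L)
      bad <- bad_row(x)
      tries <- 0L
      n_drawn <- n_lines
      while (length(bad)) {
        tries <- tries + 1L
        if (tries > max_retries)
          stop("bound rejection retry cap exceeded; acceptance rate ",
               signif(1 - n_lines / n_drawn, 3L))
        redraw <- MASS::mvrnorm(length(bad), mu = spec$means, Sigma = sigma)
        if (length(bad) == 1L) redraw <- matrix(redraw, nrow = 1L)
        n_drawn <- n_drawn + length(bad)
        x[bad, ] <- redraw
        bad <- bad_row(x)
      }
    }
    # simulated traits need not exist in the registry; skip the lookup warning
    suppressWarnings(
      trait_table(x, lines = sprintf("L%03d", seq_len(n_lines)),
                  metadata = list(source = "simulated", seed = seed))
    )
  })
}

#' Specify variance components of a two-way random GxE model
#'
#' @param mu Grand mean (trait units).
#' @param var_g,var_e,var_gxe,var_resid Non-negative variances of the
#'   genotype, environment, interaction and residual effects (trait units
#'   squared).
#' @return An object of class `variance_components_spec`.
#' @export
variance_components_spec <- function(mu = 0, var_g = 1, var_e = 1,
                                     var_gxe = 1, var_resid = 1) {
  v <- c(var_g = var_g, var_e = var_e, var_gxe = var_gxe,
         var_resid = var_resid)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all variance components must be finite and non-negative")
  structure(list(mu = mu, var_g = var_g, var_e = var_e, var_gxe = var_gxe,
                 var_resid = var_resid),
            class = "variance_components_spec")
}

#' Specify a replicated multi-environment trial design
#'
#' Defaults mirror a pilot GxE study: 6 genotypes grown in 2 environments in
#' a randomised complete block design with 4 blocks.
#'
#' @param n_genotypes Number of genotypes (>= 2).
#' @param n_environments Number of environments (>= 1).
#' @param n_blocks Replicate blocks per environment (>= 1).
#' @param seed Integer seed.
#' @return An object of class `trial_design_spec`.
#' @export
trial_design_spec <- function(n_genotypes = 6L, n_environments = 2L,
                              n_blocks = 4L, seed = 1L) {
  stopifnot(n_genotypes >= 2L, n_environments >= 1L, n_blocks >= 1L)
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_environments = as.integer(n_environments),
                 n_blocks = as.integer(n_blocks),
                 seed = seed),
            class = "trial_design_spec")
}

#' Simulate a balanced GxE trial with known variance components
#'
#' Each observation is `mu + g_i + e_j + (ge)_ij + eps_ijk` with every effect
#' drawn independently from a zero-mean normal with the specified variance.
#'
#' @param vc A [variance_components_spec()].
#' @param design A [trial_design_spec()]; its `seed` drives the draw.
#' @param trait Trait name to stamp on the records.
#' @return A balanced [gxe_dataset()].
#' @export
generate_gxe_dataset <- function(vc, design, trait = "trait") {
  stopifnot(inherits(vc, "variance_components_spec"),
            inherits(design, "trial_design_spec"))
  ng <- design$n_genotypes
  ne <- design$n_environments
  nb <- design$n_blocks
  with_stream(design$seed, "gxe_dataset", {
    g <- stats::rnorm(ng, 0, sqrt(vc$var_g))
    e <- stats::rnorm(ne, 0, sqrt(vc$var_e))
    ge <- matrix(stats::rnorm(ng * ne, 0, sqrt(vc$var_gxe)), ng, ne)
    grid <- expand.grid(block = seq_len(nb), genotype = seq_len(ng),
                        environment = seq_len(ne))
    eps <- stats::rnorm(nrow(grid), 0, sqrt(vc$var_resid))
    value <- vc$mu + g[grid$genotype] + e[grid$environment] +
      ge[cbind(grid$genotype, grid$environment)] + eps
    gxe_dataset(genotype = sprintf("G%02d", grid$genotype),
                environment = sprintf("E%02d", grid$environment),
                block = sprintf("B%d", grid$block),
                trait = trait, value = value)
  })
}

#' Simulate chained parent-offspring generations with known heritability
#'
#' Offspring values follow `mu + b (parent - mu) + eps` with `b = sqrt(h2)`
#' and `var(eps) = (1 - h2) sigma^2`, so the squared parent-offspring
#' correlation equals `h2_target` in expectation and the trait variance is
#' stationary across generations. Offspring of one transition become parents
#' of the next.
#'
#' @param h2_target Target broad-sense heritability on the [0, 1] scale.
#' @param n_lines Lines per generation.
#' @param n_generations Number of generations (>= 2 gives
#'   `n_generations - 1` transitions; default 3).
#' @param seed Integer seed.
#' @param mu,sigma Mean and standard deviation of the founding generation.
#' @param trait Trait name to stamp on the records.
#' @return A [pedigree_table()] with one record per line per transition.
#' @export
generate_parent_offspring <- function(h2_target, n_lines,
                                      n_generations = 3L, seed = 1L,
                                      mu = 50, sigma = 10,
                                      trait = "trait") {
  if (!is.finite(h2_target) || h2_target < 0 || h2_target > 1)
    stop("h2_target must lie in [0, 1]")
  stopifnot(n_lines >= 2L, n_generations >= 2L)
  b <- sqrt(h2_target)
  se <- sigma * sqrt(1 - h2_target)
  with_stream(seed, "parent_offspring", {
    parent <- stats::rnorm(n_lines, mu, sigma)
    recs <- vector("list", n_generations - 1L)
    for (gen in seq_len(n_generations - 1L)) {
      offspring <- mu + b * (parent - mu) + stats::rnorm(n_lines, 0, se)
      recs[[gen]] <- pedigree_table(line = sprintf("L%05d", seq_len(n_lines)),
                                    generation_from = gen,
                                    parent_value = parent,
                                    offspring_value = offspring,
                                    trait = trait)
      parent <- offspring
    }
    out <- do.call(rbind, recs)
    class(out) <- c("pedigree_table", "data.frame")
    out
  })
}
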