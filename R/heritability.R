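# Broad-sense heritability by two routes: parent-offspring regression
# (R-squared convention) and variance components of the two-way random
# genotype x environment model, combined by a three-slot averaging rule.

round_half_up <- function(x) floor(x + 0.5)

#' Heritability from parent-offspring regression
#'
#' Regresses offspring trait values on parent values for one generation
#' transition and reports 100 times the coefficient of determination as the
#' broad-sense heritability estimate. The regression slope (the textbook
#' estimator) and intercept are reported alongside.
#'
#' @param pairs A [pedigree_table()].
#' @param trait Trait to analyse; defaults to the only trait present.
#' @param transition Generation transition as the starting generation
#'   (e.g. `1` for generation 1 to 2).
#' @return An object of class `po_h2` with components `h2` (percent),
#'   `slope`, `intercept`, `r_squared`, `n`, `trait`, `transition`.
#' @export
parent_offspring_h2 <- function(pairs, trait = unique(pairs$trait),
                                transition = 1L) {
  stopifnot(inherits(pairs, "pedigree_table"), length(trait) == 1L)
  d <- pairs[pairs$trait == trait & pairs$generation_from == transition, ]
  if (nrow(d) < 3L)
    stop("need at least 3 parent-offspring pairs for transition ", transition)
  if (stats::var(d$parent_value) == 0)
    stop("parent values are constant: regression undefined")
  fit <- stats::lm(offspring_value ~ parent_value, data = d)
  # exact heredity (offspring identical to parent) is a legitimate input
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(h2 = 100 * r2,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 n = nrow(d), trait = trait,
                 transition = c(transition, transition + 1L)),
            class = "po_h2")
}

#' @export
print.po_h2 <- function(x, ...) {
  cat("Parent-offspring regression heritability (", x$trait, ")\n", sep = "")
  cat(sprintf("  generation %d -> %d, n = %d\n", x$transition[1L],
              x$transition[2L], x$n))
  cat(sprintf("  H = %.1f%%  (R^2 = %.4f; slope = %.4f, intercept = %.4f)\n",
              x$h2, x$r_squared, x$slope, x$intercept))
  invisible(x)
}

#' Estimate variance components of the two-way random GxE model
#'
#' Fits `value = mu + g + e + (ge) + eps` with genotype, environment and
#' interaction all random. Two estimators are available: the closed-form
#' expected-mean-squares (EMS) solution for balanced designs, and an EM
#' algorithm for the REML criterion that also handles unbalanced data. On
#' balanced data with interior estimates the two coincide. Negative EMS
#' solutions are truncated to zero and flagged.
#'
#' @param data A [gxe_dataset()].
#' @param trait Trait to analyse; defaults to the only trait present.
#' @param method `"ems_anova"` (balanced designs only) or `"em_reml"`.
#' @param use_line_means If `TRUE`, collapse to genotype x environment cell
#'   means first; the residual variance is then confounded with the
#'   interaction and forced to zero.
#' @param tol,max_iter EM convergence tolerance on the relative change of
#'   every component (default `1e-8`) and iteration cap (default 1000).
#' @return An object of class `variance_components` with components `var_g`,
#'   `var_e`, `var_gxe`, `var_resid`, `method`, `converged`, `n_iterations`,
#'   `truncated`.
#' @export
estimate_variance_components <- function(data, trait = unique(data$trait),
                                         method = c("ems_anova", "em_reml"),
                                         use_line_means = FALSE,
                                         tol = 1e-8, max_iter = 1000L) {
  method <- match.arg(method)
  stopifnot(inherits(data, "gxe_dataset"), length(trait) == 1L)
  d <- data[data$trait == trait, ]
  if (length(unique(d$genotype)) < 2L || length(unique(d$environment)) < 2L)
    stop("need at least 2 genotypes and 2 environments")
  if (use_line_means) {
    agg <- stats::aggregate(value ~ genotype + environment, data = d, FUN = mean)
    agg$block <- "B1"
    agg$trait <- trait
    d <- gxe_dataset(agg$genotype, agg$environment, agg$block, agg$trait,
                     agg$value)
  }
  out <- switch(method,
                ems_anova = vc_ems(d),
                em_reml = vc_em_reml(d, tol = tol, max_iter = max_iter))
  if (use_line_means) {
    # residual is confounded with the interaction at one record per cell
    out$var_resid <- 0
  }
  out$trait <- trait
  out
}

# Closed-form expected-mean-squares solution for the balanced design.
vc_ems <- function(d) {
  g <- factor(d$genotype)
  e <- factor(d$environment)
  counts <- table(g, e)
  if (length(unique(as.vector(counts))) != 1L || any(counts == 0L))
    stop("design is unbalanced; use method = \"em_reml\"")
  r <- unname(counts[1L, 1L])
  ng <- nlevels(g)
  ne <- nlevels(e)
  y <- d$value
  grand <- mean(y)
  gm <- tapply(y, g, mean)
  em <- tapply(y, e, mean)
  cm <- tapply(y, list(g, e), mean)
  ms_g <- ne * r * sum((gm - grand)^2) / (ng - 1L)
  ms_e <- ng * r * sum((em - grand)^2) / (ne - 1L)
  ms_ge <- r * sum((cm - outer(gm, em, "+") + grand)^2) /
    ((ng - 1L) * (ne - 1L))
  if (r > 1L) {
    ss_res <- sum((y - cm[cbind(g, e)])^2)
    ms_res <- ss_res / (ng * ne * (r - 1L))
    raw <- c(var_g = (ms_g - ms_ge) / (r * ne),
             var_e = (ms_e - ms_ge) / (r * ng),
             var_gxe = (ms_ge - ms_res) / r,
             var_resid = ms_res)
  } else {
    # no within-cell replication: interaction and residual are confounded
    raw <- c(var_g = (ms_g - ms_ge) / ne,
             var_e = (ms_e - ms_ge) / ng,
             var_gxe = ms_ge,
             var_resid = 0)
  }
  truncated <- names(raw)[raw < 0]
  est <- pmax(raw, 0)
  structure(list(var_g = est[["var_g"]], var_e = est[["var_e"]],
                 var_gxe = est[["var_gxe"]], var_resid = est[["var_resid"]],
                 method = "ems_anova", converged = TRUE, n_iterations = 0L,
                 truncated = truncated),
            class = "variance_components")
}

# EM iterations for the REML criterion of the three-random-effect model.
# Each update is
#   sigma2_i <- sigma2_i + sigma2_i^2 / q_i * (y'P Zi Zi' P y - tr(Zi' P Zi))
# whose fixed point solves the REML score equations; non-negativity is
# automatic because estimates approach zero from above.
vc_em_reml <- function(d, tol = 1e-8, max_iter = 1000L) {
  g <- factor(d$genotype)
  e <- factor(d$environment)
  ge <- factor(paste(d$genotype, d$environment, sep = ":"))
  y <- d$value
  n <- length(y)
  Zs <- list(g = stats::model.matrix(~ g - 1),
             e = stats::model.matrix(~ e - 1),
             ge = stats::model.matrix(~ ge - 1))
  q <- vapply(Zs, ncol, integer(1L))
  ZZt <- lapply(Zs, tcrossprod)
  X <- matrix(1, n, 1L)
  vy <- stats::var(y)
  s2 <- c(g = vy / 4, e = vy / 4, ge = vy / 4, resid = vy / 4)
  s2[s2 <= 0] <- 1e-6
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    V <- s2[["resid"]] * diag(n)
    for (k in names(Zs)) V <- V + s2[[k]] * ZZt[[k]]
    Vi <- chol2inv(chol(V))
    ViX <- Vi %*% X
    P <- Vi - ViX %*% solve(crossprod(X, ViX), t(ViX))
    Py <- P %*% y
    new <- s2
    for (k in names(Zs)) {
      zpy <- crossprod(Zs[[k]], Py)
      trv <- sum(P * ZZt[[k]])
      new[[k]] <- s2[[k]] + s2[[k]]^2 / q[[k]] * (sum(zpy^2) - trv)
    }
    new[["resid"]] <- s2[["resid"]] +
      s2[["resid"]]^2 / n * (sum(Py^2) - sum(diag(P)))
    new <- pmax(new, 0)
    delta <- max(abs(new - s2) / (abs(s2) + 1e-12))
    s2 <- new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(var_g = s2[["g"]], var_e = s2[["e"]],
                 var_gxe = s2[["ge"]], var_resid = s2[["resid"]],
                 method = "em_reml", converged = converged,
                 n_iterations = it, truncated = character()),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (", x$method, ")\n", sep = "")
  cat(sprintf("  genotype    %.6g\n  environment %.6g\n  GxE         %.6g\n  residual    %.6g\n",
              x$var_g, x$var_e, x$var_gxe, x$var_resid))
  if (x$method == "em_reml")
    cat(sprintf("  %s after %d iterations\n",
                if (x$converged) "converged" else "NOT converged",
                x$n_iterations))
  if (length(x$truncated))
    cat("  truncated at zero:", paste(x$truncated, collapse = ", "), "\n")
  invisible(x)
}

#' Broad-sense heritability from GxE variance components
#'
#' `H = 100 var_g / (var_g + var_gxe + var_resid)`. The environment main
#' effect is deliberately excluded from the denominator: heritability here
#' measures the repeatability of genotype differences within environments.
#'
#' @param vc A `variance_components` object (or any list with `var_g`,
#'   `var_gxe`, `var_resid`).
#' @return Heritability as a percentage in [0, 100].
#' @export
gxe_heritability <- function(vc) {
  denom <- vc$var_g + vc$var_gxe + vc$var_resid
  if (!is.finite(denom) || denom <= 0)
    stop("heritability undefined: var_g + var_gxe + var_resid must be > 0")
  100 * vc$var_g / denom
}

#' Combine heritability estimates across methods
#'
#' Averages the two parent-offspring transition estimates and the GxE
#' estimate by summing the three slots (missing slots contribute zero) and
#' dividing by three. The combined value is also rounded half-up to an
#' integer percentage for reporting.
#'
#' @param gen1_to_2,gen2_to_3,gxe_h2 Heritability percentages, each possibly
#'   `NA` when the method was not available for the trait.
#' @return List with `combined` (unrounded percent) and `reported` (integer
#'   percent, rounded half-up).
#' @export
combine_heritability <- function(gen1_to_2, gen2_to_3, gxe_h2) {
  slots <- c(gen1_to_2, gen2_to_3, gxe_h2)
  if (all(is.na(slots))) stop("all three heritability estimates are missing")
  combined <- sum(slots, na.rm = TRUE) / 3
  list(combined = combined, reported = round_half_up(combined))
}

#' Proportion of total variation per variance source
#'
#' @param vc A `variance_components` object.
#' @return Named vector of fractions (`G`, `E`, `GxE`, `residual`) of the
#'   total variance, summing to 1.
#' @export
variance_proportions <- function(vc) {
  v <- c(G = vc$var_g, E = vc$var_e, GxE = vc$var_gxe,
         residual = vc$var_resid)
  tot <- sum(v)
  if (!is.finite(tot) || tot <= 0) stop("total variance must be > 0")
  v / tot
}

#' Per-trait heritability summary table
#'
#' Assembles, for each trait, the two parent-offspring transition estimates,
#' the GxE variance-component estimate and their three-slot average into one
#' report table.
#'
#' @param pedigree A [pedigree_table()] covering transitions 1->2 and 2->3,
#'   or `NULL`.
#' @param gxe_data A [gxe_dataset()], or `NULL`.
#' @param traits Traits to include; defaults to all traits present in either
#'   input.
#' @param method Variance-component estimator passed to
#'   [estimate_variance_components()].
#' @return A data frame with one row per trait and columns `gen1_to_2`,
#'   `gen2_to_3`, `gxe_h2`, `combined`, `reported` (percent scales).
#' @export
heritability_table <- function(pedigree = NULL, gxe_data = NULL,
                               traits = NULL,
                               method = c("em_reml", "ems_anova")) {
  method <- match.arg(method)
  if (is.null(traits))
    traits <- unique(c(if (!is.null(pedigree)) pedigree$trait,
                       if (!is.null(gxe_data)) gxe_data$trait))
  if (!length(traits)) stop("no traits to summarise")
  rows <- lapply(traits, function(tr) {
    g12 <- g23 <- gh <- NA_real_
    if (!is.null(pedigree) && tr %in% pedigree$trait) {
      g12 <- parent_offspring_h2(pedigree, tr, transition = 1L)$h2
      if (any(pedigree$trait == tr & pedigree$generation_from == 2L))
        g23 <- parent_offspring_h2(pedigree, tr, transition = 2L)$h2
    }
    if (!is.null(gxe_data) && tr %in% gxe_data$trait) {
      vc <- estimate_variance_components(gxe_data, tr, method = method)
      gh <- gxe_heritability(vc)
    }
    comb <- combine_heritability(g12, g23, gh)
    data.frame(trait = tr, gen1_to_2 = g12, gen2_to_3 = g23, gxe_h2 = gh,
               combined = comb$combined, reported = comb$reported,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
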