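test_that("parent-offspring regression heritability is R-squared based", {
  p <- pedigree_table(line = letters[1:6], generation_from = 1L,
                      parent_value = 1:6, offspring_value = 1:6,
                      trait = "Lipid")
  fit <- parent_offspring_h2(p)
  expect_equal(fit$h2, 100)
  expect_equal(fit$slope, 1)

  # R-squared is blind to the sign of the relationship
  neg <- pedigree_table(line = letters[1:6], generation_from = 1L,
                        parent_value = 1:6,
                        offspring_value = -2 * (1:6) + 7, trait = "Lipid")
  expect_equal(parent_offspring_h2(neg)$h2, 100)
  expect_equal(parent_offspring_h2(neg)$slope, -2)

  const <- pedigree_table(line = letters[1:4], generation_from = 1L,
                          parent_value = rep(5, 4),
                          offspring_value = rnorm(4), trait = "Lipid")
  expect_error(parent_offspring_h2(const), "constant")
  expect_error(parent_offspring_h2(p[1:2, ]), "at least 3")
})

test_that("regression heritability is invariant to affine transforms", {
  ped <- generate_parent_offspring(0.4, 200, seed = 21)
  base <- parent_offspring_h2(ped, transition = 1)$h2
  shifted <- ped
  shifted$parent_value <- 3 * shifted$parent_value - 40
  shifted$offspring_value <- -0.5 * shifted$offspring_value + 11
  expect_equal(parent_offspring_h2(shifted, transition = 1)$h2, base,
               tolerance = 1e-10)
})

test_that("EMS estimator recovers a pure-noise null and truncates negatives", {
  vc <- variance_components_spec(mu = 5, var_g = 0, var_e = 0,
                                 var_gxe = 0, var_resid = 1)
  d <- generate_gxe_dataset(vc, trial_design_spec(30, 8, 4, seed = 31))
  est <- estimate_variance_components(d, method = "ems_anova")
  expect_lt(est$var_g, 0.05)
  expect_equal(est$var_resid, 1, tolerance = 0.1)
  expect_true(all(c(est$var_g, est$var_e, est$var_gxe, est$var_resid) >= 0))
})

test_that("EMS and EM-REML coincide on balanced data away from the boundary", {
  vc <- variance_components_spec(mu = 10, var_g = 1, var_e = 2,
                                 var_gxe = 0.5, var_resid = 0.5)
  d <- generate_gxe_dataset(vc, trial_design_spec(6, 4, 4, seed = 3))
  a <- estimate_variance_components(d, method = "ems_anova")
  b <- estimate_variance_components(d, method = "em_reml")
  expect_true(b$converged)
  expect_lt(max(abs(c(a$var_g - b$var_g, a$var_e - b$var_e,
                      a$var_gxe - b$var_gxe, a$var_resid - b$var_resid))),
            1e-6)
})

test_that("EM-REML agrees with an independent mixed-model fit", {
  vc <- variance_components_spec(mu = 10, var_g = 1, var_e = 2,
                                 var_gxe = 0.5, var_resid = 0.5)
  d <- generate_gxe_dataset(vc, trial_design_spec(6, 4, 4, seed = 3))
  mine <- estimate_variance_components(d, method = "em_reml")
  fit <- lme4::lmer(value ~ (1 | genotype) + (1 | environment) +
                      (1 | genotype:environment),
                    data = d, REML = TRUE)
  ref <- as.data.frame(lme4::VarCorr(fit))
  ref <- setNames(ref$vcov, ref$grp)
  expect_equal(mine$var_g, unname(ref["genotype"]), tolerance = 1e-4)
  expect_equal(mine$var_e, unname(ref["environment"]), tolerance = 1e-4)
  expect_equal(mine$var_gxe, unname(ref["genotype:environment"]),
               tolerance = 1e-4)
  expect_equal(mine$var_resid, unname(ref["Residual"]), tolerance = 1e-4)
})

test_that("unbalanced designs are routed to EM-REML", {
  vc <- variance_components_spec(mu = 0, var_g = 1, var_e = 1,
                                 var_gxe = 0.5, var_resid = 0.5)
  d <- generate_gxe_dataset(vc, trial_design_spec(5, 3, 3, seed = 7))
  d <- d[-1, ]  # drop one plot
  class(d) <- c("gxe_dataset", "data.frame")
  expect_error(estimate_variance_components(d, method = "ems_anova"),
               "em_reml")
  est <- estimate_variance_components(d, method = "em_reml")
  expect_true(all(c(est$var_g, est$var_e, est$var_gxe, est$var_resid) >= 0))
})

test_that("line-mean collapse forces the residual component to zero", {
  vc <- variance_components_spec(mu = 0, var_g = 2, var_e = 1,
                                 var_gxe = 0.5, var_resid = 0.5)
  d <- generate_gxe_dataset(vc, trial_design_spec(8, 4, 4, seed = 13))
  est <- estimate_variance_components(d, method = "ems_anova",
                                      use_line_means = TRUE)
  expect_equal(est$var_resid, 0)
  expect_gt(est$var_g, 0)
})

test_that("GxE heritability excludes the environment main effect", {
  expect_equal(gxe_heritability(list(var_g = 1, var_gxe = 0, var_resid = 0)),
               100)
  # a huge var_e does not enter the denominator
  expect_equal(gxe_heritability(list(var_g = 1, var_e = 100, var_gxe = 0.5,
                                     var_resid = 0.5)), 50)
  expect_equal(gxe_heritability(list(var_g = 0, var_gxe = 1, var_resid = 1)),
               0)
  expect_error(gxe_heritability(list(var_g = 0, var_gxe = 0, var_resid = 0)),
               "> 0")
})

test_that("GxE heritability is bounded and monotone in its components", {
  withr::with_seed(17, {
    for (i in 1:50) {
      v <- runif(3, 0, 5)
      h <- gxe_heritability(list(var_g = v[1], var_gxe = v[2],
                                 var_resid = v[3]))
      expect_gte(h, 0)
      expect_lte(h, 100)
      up <- gxe_heritability(list(var_g = v[1] + 1, var_gxe = v[2],
                                  var_resid = v[3]))
      dn <- gxe_heritability(list(var_g = v[1], var_gxe = v[2] + 1,
                                  var_resid = v[3]))
      expect_gt(up, h)
      expect_lt(dn, h)
    }
  })
})

test_that("the three-slot average reproduces the published summaries", {
  triples <- published_heritability_triples()
  reported <- vapply(triples, function(t)
    combine_heritability(t[[1]][1], t[[1]][2], t[[1]][3])$reported,
    numeric(1))
  printed <- vapply(triples, `[[`, numeric(1), 2)
  agree <- reported == printed
  # pod dry weight is the documented discrepancy; all others must match
  expect_false(agree[["Pod DW"]])
  expect_true(all(agree[names(agree) != "Pod DW"]))
  expect_equal(sum(agree), 11L)

  expect_equal(combine_heritability(27, 72, 77)$combined, 58 + 2 / 3)
  expect_equal(combine_heritability(0, 0, 0)$reported, 0)
  expect_error(combine_heritability(NA, NA, NA), "missing")
})

test_that("variance proportions partition the total variance", {
  eq <- variance_proportions(list(var_g = 2, var_e = 2, var_gxe = 2,
                                  var_resid = 2))
  expect_equal(unname(eq), rep(0.25, 4))
  solo <- variance_proportions(list(var_g = 3, var_e = 0, var_gxe = 0,
                                    var_resid = 0))
  expect_equal(unname(solo["G"]), 1)
  expect_error(variance_proportions(list(var_g = 0, var_e = 0, var_gxe = 0,
                                         var_resid = 0)), "> 0")
})

test_that("a genotype-dominant simulation yields a genotype-dominant share", {
  # lipid-like conditions: 55% of total variance planted in genotype
  vc <- variance_components_spec(mu = 6.4, var_g = 0.55, var_e = 0.20,
                                 var_gxe = 0.10, var_resid = 0.15)
  d <- generate_gxe_dataset(vc, trial_design_spec(30, 6, 4, seed = 19))
  est <- estimate_variance_components(d, method = "ems_anova")
  expect_gt(variance_proportions(est)[["G"]], 0.5)
})

test_that("heritability summary table combines both methods per trait", {
  ped <- generate_parent_offspring(0.6, 50, n_generations = 3, seed = 23,
                                   trait = "Lipid")
  vc <- variance_components_spec(mu = 6, var_g = 1, var_e = 0.5,
                                 var_gxe = 0.3, var_resid = 0.3)
  gxe <- generate_gxe_dataset(vc, trial_design_spec(seed = 23),
                              trait = "Lipid")
  tab <- heritability_table(ped, gxe)
  expect_equal(nrow(tab), 1L)
  expect_false(anyNA(tab[, c("gen1_to_2", "gen2_to_3", "gxe_h2")]))
  expect_equal(tab$combined,
               (tab$gen1_to_2 + tab$gen2_to_3 + tab$gxe_h2) / 3)
  expect_equal(tab$reported, floor(tab$combined + 0.5))
})
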