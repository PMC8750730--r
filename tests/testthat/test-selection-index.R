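test_that("standardization yields exact zero-mean unit-sd columns", {
  col <- trait_table(cbind("Seed number" = c(1, 2, 3)))
  z <- standardize(col)
  expect_equal(unname(z$values[, 1]), c(-1, 0, 1))

  tab <- random_base_table(40, seed = 61, with_lignoceric = TRUE)
  snd <- standardize(tab)
  expect_true(all(abs(colMeans(snd$values)) < 1e-10))
  expect_true(all(abs(apply(snd$values, 2, sd) - 1) < 1e-10))

  # any affine transform of a column maps to the identical SND column
  shifted <- tab
  shifted$values[, 4] <- 250 * shifted$values[, 4] + 13
  expect_equal(standardize(shifted)$values[, 4], snd$values[, 4],
               tolerance = 1e-10)

  flat <- tab
  flat$values[, 2] <- 1
  expect_error(standardize(flat), flat$traits$name[2])
})

test_that("the default scenario registry matches the published design", {
  sc <- default_scenarios()
  expect_length(sc, 15L)
  idx <- vapply(sc, `[[`, character(1), "index_id")
  expect_equal(unname(table(idx)[paste0("SI-", 1:5)]),
               c(1L, 1L, 4L, 4L, 5L), ignore_attr = TRUE)

  w3d <- sc[["3d"]]$selected_weights
  expect_equal(sort(names(w3d)),
               sort(c("Oleic acid", "Seed number", "Dry seed weight")))
  expect_equal(unname(w3d[c("Oleic acid", "Seed number",
                            "Dry seed weight")]), c(3, 2, 2))
  expect_equal(sc[["1a"]]$selected_weights, c("Oleic acid" = 3))
  expect_equal(sc[["2a"]]$selected_weights,
               c("Linoleic acid" = 3, "Linolenic acid" = 3))
  expect_equal(sc[["5e"]]$selected_weights,
               c("Seed number" = 2, "Dry seed weight" = 2,
                 "Single seed size" = 2))

  # fatty acids weigh 3, yield traits 2, everything else 1
  for (s in sc) {
    w <- scenario_weights(s)
    expect_true(all(w %in% c(1, 2, 3)))
    expect_equal(sum(names(w) %in% index_base_traits()), 11L)
  }
  expect_false(anyDuplicated(names(sc)) > 0)
})

test_that("scenario scores equal a brute-force weighted sum", {
  tab <- random_base_table(5, seed = 62)
  snd <- standardize(tab)
  sc <- default_scenarios()
  for (id in c("1a", "3d", "5e")) {
    w <- scenario_weights(sc[[id]])
    manual <- sapply(seq_along(snd$lines), function(i) {
      sum(w * snd$values[i, match(names(w), snd$traits$name)])
    })
    expect_equal(unname(score_scenario(snd, sc[[id]])), manual,
                 tolerance = 1e-12)
  }

  # population-mean line scores zero; scores always sum to zero
  scores <- score_all_scenarios(snd, sc)
  expect_true(all(abs(colSums(scores)) < 1e-8))

  # antisymmetric two-line fixture: equal magnitude, opposite sign
  two <- tab
  two$values <- tab$values[1:2, , drop = FALSE]
  two$values[2, ] <- 2 * colMeans(tab$values[1:2, ]) - two$values[1, ]
  two$lines <- tab$lines[1:2]
  s2 <- score_scenario(standardize(trait_table(two$values,
                                               lines = two$lines)),
                       sc[["1a"]])
  expect_equal(s2[1], -s2[2], ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("scores are invariant to per-trait affine rescaling", {
  tab <- random_base_table(12, seed = 63)
  snd1 <- standardize(tab)
  rescaled <- tab
  for (j in seq_len(ncol(tab$values)))
    rescaled$values[, j] <- rescaled$values[, j] * (j + 0.5) + j
  snd2 <- standardize(rescaled)
  s1 <- score_all_scenarios(snd1)
  s2 <- score_all_scenarios(snd2)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("selected-only scoring drops the base-weight traits", {
  tab <- random_base_table(8, seed = 64)
  snd <- standardize(tab)
  sc <- default_scenarios()[["1a"]]
  sel <- score_scenario(snd, sc, score_traits = "selected_only")
  j <- match("Oleic acid", snd$traits$name)
  expect_equal(unname(sel), unname(3 * snd$values[, j]), tolerance = 1e-12)
})

test_that("culling eliminates strictly-below-threshold lines only", {
  vals <- cbind("Protein" = c(14.9, 15.0, 20, 16),
                "Shelling percentage" = c(60, 50.0, 49.9, 70))
  tab <- trait_table(vals, lines = c("low_protein", "boundary",
                                     "low_shelling", "fine"))
  kept <- apply_culling(tab, default_culling_rules())
  expect_equal(kept, c("boundary", "fine"))
  expect_equal(apply_culling(tab, list()), tab$lines)
  expect_error(apply_culling(tab, list(culling_rule("Lipid", 5))),
               "missing")
})

test_that("positive-score compilation is an intersection over scenarios", {
  scores <- cbind(a = c(1, 1, -1, 1), b = c(1, -1, 1, 1), c = c(1, 1, 1, 0))
  rownames(scores) <- sprintf("L%d", 1:4)
  attr(scores, "index_id") <- c("SI-9", "SI-9", "SI-9")
  expect_equal(compile_positive(scores, "SI-9"), "L1")

  single <- scores[, 1, drop = FALSE]
  attr(single, "index_id") <- "SI-8"
  expect_equal(compile_positive(single, "SI-8"), c("L1", "L2", "L4"))

  # adding scenarios can only shrink the compiled set
  tab <- random_base_table(20, seed = 65)
  snd <- standardize(tab)
  sc <- default_scenarios()
  all_sc <- score_all_scenarios(snd, sc)
  for (n_sc in 1:4) {
    part <- all_sc[, 1:n_sc, drop = FALSE]
    attr(part, "index_id") <- rep("X", n_sc)
    if (n_sc == 1) prev <- compile_positive(part, "X")
    cur <- compile_positive(part, "X")
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("top-k selection respects culling, positivity and the tie rule", {
  scores <- c(L1 = 3, L2 = 2, L3 = 2, L4 = -1, L5 = 0.5, L6 = 10)
  sel <- select_top_k(scores, culled = c("L1", "L2", "L3", "L4", "L5"),
                      k = 3)
  expect_equal(sel, c("L1", "L2", "L3"))  # L6 culled out, tie L2 < L3 by id

  expect_warning(sel2 <- select_top_k(scores, culled = c("L1", "L5"), k = 15),
                 "qualifying")
  expect_equal(sel2, c("L1", "L5"))
  expect_warning(expect_equal(select_top_k(c(L1 = -2), k = 5), character()),
                 "no lines")
})

test_that("expected gain matches direct arithmetic and the zero identity", {
  two <- trait_table(cbind("Lipid" = c(10, 30)), lines = c("a", "b"))
  g <- expected_gain(two, "b")
  expect_equal(g$percent_change, 50)

  tab <- random_base_table(10, seed = 66)
  sel <- tab$lines[c(2, 5, 7)]
  rep <- expected_gain(tab, sel)
  for (j in seq_len(ncol(tab$values))) {
    oracle <- 100 * (mean(tab$values[c(2, 5, 7), j]) -
                       mean(tab$values[, j])) / mean(tab$values[, j])
    expect_equal(rep$percent_change[j], oracle, tolerance = 1e-12)
  }

  full <- expected_gain(tab, tab$lines)
  expect_true(all(abs(full$percent_change) < 1e-12))

  expect_error(expected_gain(tab, character()), "empty")
  expect_error(expected_gain(tab, "nope"), "not in table")
  zero <- trait_table(cbind("Seed number" = c(-1, 1)), lines = c("a", "b"))
  expect_error(expected_gain(zero, "a"), "zero")
})

test_that("the fitted selection index is deterministic end to end", {
  tab <- generate_trait_matrix(default_trait_spec(), 40, seed = 67)
  f1 <- suppressWarnings(selection_index(tab, "SI-3"))
  f2 <- suppressWarnings(selection_index(tab, "SI-3"))
  expect_identical(f1$selected, f2$selected)
  expect_identical(f1$gains$percent_change, f2$gains$percent_change)
  expect_identical(capture.output(print(f1)), capture.output(print(f2)))

  flat <- trait_table(matrix(5, 3, 11,
                             dimnames = list(NULL, index_base_traits())))
  expect_error(selection_index(flat, "SI-1"), "constant")
  expect_error(selection_index(tab, "SI-99"), "unknown index")
})

test_that("a planted high-lipid high-yield subpopulation is found by SI-3", {
  spec <- default_trait_spec()
  base <- generate_trait_matrix(spec, 40, seed = 68)
  vals <- base$values
  elite <- 1:8
  for (tr in c("Lipid", "Oleic acid", "Seed number", "Dry seed weight",
               "Dry pod weight"))
    vals[elite, tr] <- vals[elite, tr] + 2 * spec$sds[[tr]]
  # keep the planted lines clear of the culling thresholds
  vals[elite, "Protein"] <- pmax(vals[elite, "Protein"], 16)
  vals[elite, "Shelling percentage"] <-
    pmin(pmax(vals[elite, "Shelling percentage"], 55), 100)
  planted <- trait_table(vals, lines = base$lines)
  fit <- suppressWarnings(selection_index(planted, "SI-3"))
  expect_gt(sum(fit$selected %in% base$lines[elite]), 4)
  g <- fit$gains
  expect_gt(g$percent_change[g$trait == "Lipid"], 0)
  expect_gt(g$percent_change[g$trait == "Seed number"], 0)
})

test_that("fit methods expose weights, predictions and summaries", {
  tab <- generate_trait_matrix(default_trait_spec(), 40, seed = 69)
  fit <- suppressWarnings(selection_index(tab, "SI-1"))
  w <- coef(fit)
  expect_equal(dim(w), c(15L, 11L))
  expect_equal(unname(w["1a", "Oleic acid"]), 3)
  expect_equal(unname(w["1a", "Protein"]), 1)

  # in-sample predictions equal the stored aggregate scores
  expect_equal(predict(fit), fit$aggregate_score)
  expect_equal(predict(fit, tab), fit$aggregate_score, tolerance = 1e-12)

  s <- summary(fit)
  expect_s3_class(s, "summary.selection_index")
  out <- capture.output(print(s))
  expect_true(any(grepl("Selected lines", out)))

  # union aggregation selects a superset-or-equal line set
  fit_u <- suppressWarnings(selection_index(tab, "SI-3",
                                            aggregate = "union"))
  fit_m <- suppressWarnings(selection_index(tab, "SI-3"))
  expect_true(length(fit_u$selected) >= 1)
})

test_that("membership table covers all indices and drops all-negative lines", {
  tab <- generate_trait_matrix(default_trait_spec(), 40, seed = 70)
  m <- positive_score_membership(tab)
  expect_equal(colnames(m), paste0("SI-", 1:5))
  expect_true(all(rowSums(m) > 0))
  # consistent with compile_positive per index
  snd <- standardize(tab)
  scores <- score_all_scenarios(snd)
  for (id in colnames(m)) {
    expect_setequal(rownames(m)[m[, id]], compile_positive(scores, id))
  }
})
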