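#' Fit a phenotypic selection index to a line-by-trait table
#'
#' The central fitting function of the package. It standardizes the table to
#' standard-normal-deviate units, scores every scenario of the chosen index,
#' applies independent culling levels, compiles the lines with positive
#' scores in all of the index's scenarios, selects the top-`k` lines by
#' aggregate score, and reports the expected percent gain of the selection
#' for every trait.
#'
#' @param table A [trait_table()] containing all eleven base-set traits (see
#'   [index_base_traits()]) and any culling traits; no missing values.
#' @param index Index identifier, one of `"SI-1"` to `"SI-5"` under the
#'   default registry.
#' @param scenarios Scenario registry (default [default_scenarios()]); all
#'   scenarios are scored, those of `index` drive selection.
#' @param culling List of [culling_rule()]s (default
#'   [default_culling_rules()]); `list()` disables culling.
#' @param k Number of lines to select (default 15).
#' @param score_traits `"all"` or `"selected_only"`, see [score_scenario()].
#' @param aggregate How one aggregate score per line is formed from the
#'   index's scenario scores: `"mean"` (default) averages them; `"union"`
#'   selects the union of per-scenario top-`k` sets instead of ranking an
#'   aggregate.
#' @param sd_type Standard-deviation convention for [standardize()].
#' @return An object of class `selection_index` with components `snd`,
#'   `scores` (lines x all scenarios), `index`, `scenarios`,
#'   `positive_lines` (per index, the lines positive in every scenario),
#'   `culled` (retained lines), `aggregate_score`, `selected` and `gains`
#'   (a [expected_gain()] report).
#' @examples
#' spec <- default_trait_spec()
#' tab <- generate_trait_matrix(spec, n_lines = 40, seed = 1)
#' fit <- selection_index(tab, index = "SI-3")
#' print(fit)
#' coef(fit)["3d", ]
#' @export
selection_index <- function(table, index = "SI-3",
                            scenarios = default_scenarios(),
                            culling = default_culling_rules(),
                            k = 15L,
                            score_traits = c("all", "selected_only"),
                            aggregate = c("mean", "union"),
                            sd_type = c("sample", "population")) {
  score_traits <- match.arg(score_traits)
  aggregate <- match.arg(aggregate)
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(table, "trait_table"))
  index_ids <- unique(vapply(scenarios, `[[`, character(1L), "index_id"))
  if (!index %in% index_ids)
    stop("unknown index '", index, "'; registry defines: ",
         paste(index_ids, collapse = ", "))

  snd <- standardize(table, sd_type = sd_type)
  scores <- score_all_scenarios(snd, scenarios, score_traits = score_traits)
  positive <- lapply(stats::setNames(index_ids, index_ids),
                     function(id) compile_positive(scores, id))
  culled <- apply_culling(table, culling)

  cols <- which(attr(scores, "index_id") == index)
  agg <- rowMeans(scores[, cols, drop = FALSE])
  if (aggregate == "mean") {
    selected <- select_top_k(agg, culled, k)
  } else {
    per <- lapply(cols, function(j)
      select_top_k(scores[, j], culled, k))
    selected <- sort(unique(unlist(per)))
  }
  gains <- if (length(selected)) expected_gain(table, selected, index)
           else NULL

  structure(list(table = table, snd = snd, index = index,
                 scenarios = scenarios, scores = scores,
                 positive_lines = positive, culled = culled,
                 aggregate_score = agg, aggregate = aggregate,
                 score_traits = score_traits, k = k,
                 selected = selected, gains = gains,
                 call = match.call()),
            class = "selection_index")
}

#' @export
print.selection_index <- function(x, ...) {
  cols <- sum(attr(x$scores, "index_id") == x$index)
  cat("Phenotypic selection index fit: ", x$index, " (", cols,
      " scenario", if (cols > 1L) "s", ")\n", sep = "")
  cat("  population:", length(x$table$lines), "lines;",
      length(x$culled), "survive culling\n")
  cat("  positive in all", x$index, "scenarios:",
      length(x$positive_lines[[x$index]]), "lines\n")
  cat("  selected (top ", x$k, "): ", length(x$selected), " line",
      if (length(x$selected) != 1L) "s", "\n", sep = "")
  if (!is.null(x$gains)) {
    top <- x$gains[order(-abs(x$gains$percent_change)), ][1:3, ]
    cat("  largest expected changes:",
        paste(sprintf("%s %+.1f%%", top$trait, top$percent_change),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.selection_index <- function(object, ...) {
  structure(list(index = object$index,
                 n_lines = length(object$table$lines),
                 n_culled_out = length(object$table$lines) -
                   length(object$culled),
                 positive_counts = vapply(object$positive_lines, length,
                                          integer(1L)),
                 selected = object$selected,
                 gains = object$gains),
            class = "summary.selection_index")
}

#' @export
print.summary.selection_index <- function(x, ...) {
  cat("Selection index", x$index, "on", x$n_lines, "lines\n")
  cat("Eliminated by culling:", x$n_culled_out, "\n")
  cat("Lines positive in all scenarios, per index:\n")
  print(x$positive_counts)
  cat("Selected lines:", paste(x$selected, collapse = ", "), "\n")
  if (!is.null(x$gains)) print(x$gains)
  invisible(x)
}

#' Scenario weight matrix of a fitted selection index
#'
#' @param object A fitted [selection_index()].
#' @param ... Unused.
#' @return Numeric matrix (scenarios x base traits) of the trait weights each
#'   scenario applies.
#' @export
coef.selection_index <- function(object, ...) {
  w <- t(vapply(object$scenarios, scenario_weights,
                numeric(length(index_base_traits()))))
  rownames(w) <- names(object$scenarios)
  w
}

#' Score new lines with a fitted selection index
#'
#' New lines are standardized with the centre and scale learned from the
#' fitted population, then scored under the fitted index's scenarios; the
#' aggregate (mean) scenario score is returned.
#'
#' @param object A fitted [selection_index()].
#' @param newdata A [trait_table()] with the same traits; defaults to the
#'   training table.
#' @param ... Unused.
#' @return Named numeric vector of aggregate index scores for the new lines.
#' @export
predict.selection_index <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$aggregate_score)
  stopifnot(inherits(newdata, "trait_table"))
  idx <- match(normalize_trait_name(object$snd$traits$name),
               normalize_trait_name(newdata$traits$name))
  if (anyNA(idx))
    stop("newdata lacks trait(s): ",
         paste(object$snd$traits$name[is.na(idx)], collapse = ", "))
  x <- newdata$values[, idx, drop = FALSE]
  z <- sweep(sweep(x, 2L, object$snd$center), 2L, object$snd$scale, "/")
  snd <- object$snd
  snd$values <- z
  snd$lines <- newdata$lines
  scores <- score_all_scenarios(snd, object$scenarios,
                                score_traits = object$score_traits)
  cols <- which(attr(scores, "index_id") == object$index)
  rowMeans(scores[, cols, drop = FALSE])
}

#' Plot expected gains of a fitted selection index
#'
#' Horizontal bar chart of the expected percent change per trait.
#'
#' @param x A fitted [selection_index()].
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the gain report plotted.
#' @export
plot.selection_index <- function(x, ...) {
  if (is.null(x$gains)) stop("no selection: nothing to plot")
  g <- x$gains
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(g$percent_change), names.arg = rev(g$trait),
                    horiz = TRUE, las = 1,
                    xlab = "expected change (%)",
                    main = paste("Expected gain,", x$index), ...)
  graphics::abline(v = 0)
  invisible(g)
}

#' Positive-score membership across all indices
#'
#' Builds the membership matrix of lines scoring positively in every scenario
#' of each index.
#'
#' @param table A [trait_table()].
#' @param scenarios Scenario registry (default [default_scenarios()]).
#' @param score_traits Passed to [score_scenario()].
#' @return Logical matrix, lines x indices; `TRUE` where the line is positive
#'   in all of that index's scenarios. Lines positive nowhere are dropped.
#' @export
positive_score_membership <- function(table,
                                      scenarios = default_scenarios(),
                                      score_traits = "all") {
  snd <- standardize(table)
  scores <- score_all_scenarios(snd, scenarios, score_traits = score_traits)
  ids <- unique(attr(scores, "index_id"))
  m <- vapply(ids, function(id) table$lines %in% compile_positive(scores, id),
              logical(length(table$lines)))
  dimnames(m) <- list(table$lines, ids)
  m[rowSums(m) > 0, , drop = FALSE]
}
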