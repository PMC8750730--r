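# The base linear phenotypic selection-index engine: standard-normal-deviate
# scoring against a weighted scenario registry, independent culling levels,
# positive-score compilation, top-k selection and expected percent gain.

#' The eleven-trait base set of the selection indices
#'
#' @return Character vector of the trait names every scenario is scored over.
#' @export
index_base_traits <- function() {
  c("Lipid", "Protein", "Total carbohydrate", "Oleic acid", "Linoleic acid",
    "Linolenic acid", "Seed number", "Dry pod weight", "Dry seed weight",
    "Single seed size", "Shelling percentage")
}

#' Standardize a trait table to standard normal deviate units
#'
#' Centres each trait column by its mean and scales by its standard
#' deviation (sample, n-1, by default), so every column has mean 0 and
#' standard deviation 1. The per-trait centre and scale are retained for
#' standardizing new lines on the same basis.
#'
#' @param table A [trait_table()] with >= 2 lines, no missing values and no
#'   constant trait column.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`
#'   (n denominator).
#' @return An object of class `snd_table`: a `trait_table` whose values are
#'   in SND units, with components `center` and `scale`.
#' @export
standardize <- function(table, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(table, "trait_table"))
  x <- table$values
  if (anyNA(x))
    stop("table contains missing values; use drop_incomplete_lines() first")
  if (nrow(x) < 2L) stop("need at least 2 lines to standardize")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  if (sd_type == "population")
    scl <- scl * sqrt((nrow(x) - 1) / nrow(x))
  if (any(scl == 0))
    stop("constant trait column(s): ",
         paste(colnames(x)[scl == 0], collapse = ", "))
  z <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  out <- list(lines = table$lines, traits = table$traits, values = z,
              metadata = table$metadata, center = ctr, scale = scl,
              sd_type = sd_type)
  class(out) <- c("snd_table", "trait_table")
  out
}

#' @export
print.snd_table <- function(x, ...) {
  cat("Standard-normal-deviate table: ", length(x$lines), " lines x ",
      nrow(x$traits), " traits (", x$sd_type, " sd)\n", sep = "")
  invisible(x)
}

#' Define a selection-index scenario
#'
#' @param scenario_id Scenario label, e.g. `"3d"`.
#' @param index_id Index the scenario belongs to, e.g. `"SI-3"`.
#' @param selected_weights Named numeric vector of emphasised traits and
#'   their weights (2 or 3 in the default registry).
#' @param base_weight Weight applied to every other base-set trait
#'   (default 1).
#' @param base_traits The trait set the score is summed over
#'   (default [index_base_traits()]).
#' @return An object of class `scenario_definition`.
#' @export
scenario_definition <- function(scenario_id, index_id, selected_weights,
                                base_weight = 1,
                                base_traits = index_base_traits()) {
  stopifnot(is.numeric(selected_weights), !is.null(names(selected_weights)))
  missing <- setdiff(normalize_trait_name(names(selected_weights)),
                     normalize_trait_name(base_traits))
  if (length(missing))
    stop("selected trait(s) outside the base set: ",
         paste(missing, collapse = ", "))
  structure(list(scenario_id = scenario_id, index_id = index_id,
                 selected_weights = selected_weights,
                 base_weight = base_weight, base_traits = base_traits),
            class = "scenario_definition")
}

#' Full trait-weight vector of a scenario
#'
#' @param scenario A [scenario_definition()].
#' @return Named numeric vector over the scenario's base traits: the selected
#'   weights where emphasised, the base weight elsewhere.
#' @export
scenario_weights <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_definition"))
  w <- stats::setNames(rep(scenario$base_weight,
                           length(scenario$base_traits)),
                       scenario$base_traits)
  idx <- match(normalize_trait_name(names(scenario$selected_weights)),
               normalize_trait_name(scenario$base_traits))
  w[idx] <- scenario$selected_weights
  w
}

#' The default registry of fifteen selection scenarios
#'
#' Five indices targeting seed lipid (SI-1), omega 3 and 6 fatty acids
#' (SI-2), seed lipid and yield (SI-3), omega 3 and 6 fatty acids and yield
#' (SI-4) and yield alone (SI-5), tested through fifteen scenarios. Fatty
#' acids carry weight 3, yield traits weight 2, all other base-set traits
#' weight 1.
#'
#' @return Named list of 15 [scenario_definition()] objects (names are the
#'   scenario ids `1a`, `2a`, `3a`-`3d`, `4a`-`4d`, `5a`-`5e`).
#' @export
default_scenarios <- function() {
  defs <- list(
    list("1a", "SI-1", c("Oleic acid" = 3)),
    list("2a", "SI-2", c("Linoleic acid" = 3, "Linolenic acid" = 3)),
    list("3a", "SI-3", c("Oleic acid" = 3, "Dry seed weight" = 2)),
    list("3b", "SI-3", c("Oleic acid" = 3, "Single seed size" = 2)),
    list("3c", "SI-3", c("Oleic acid" = 3, "Seed number" = 2)),
    list("3d", "SI-3", c("Oleic acid" = 3, "Seed number" = 2,
                         "Dry seed weight" = 2)),
    list("4a", "SI-4", c("Linoleic acid" = 3, "Linolenic acid" = 3,
                         "Dry seed weight" = 2)),
    list("4b", "SI-4", c("Linoleic acid" = 3, "Linolenic acid" = 3,
                         "Single seed size" = 2)),
    list("4c", "SI-4", c("Linoleic acid" = 3, "Linolenic acid" = 3,
                         "Seed number" = 2)),
    list("4d", "SI-4", c("Linoleic acid" = 3, "Linolenic acid" = 3,
                         "Seed number" = 2, "Dry seed weight" = 2)),
    list("5a", "SI-5", c("Dry seed weight" = 2)),
    list("5b", "SI-5", c("Seed number" = 2)),
    list("5c", "SI-5", c("Single seed size" = 2)),
    list("5d", "SI-5", c("Seed number" = 2, "Dry seed weight" = 2)),
    list("5e", "SI-5", c("Seed number" = 2, "Dry seed weight" = 2,
                         "Single seed size" = 2))
  )
  out <- lapply(defs, function(d)
    scenario_definition(d[[1L]], d[[2L]], d[[3L]]))
  names(out) <- vapply(out, `[[`, character(1L), "scenario_id")
  out
}

#' Define an independent culling rule
#'
#' @param trait Trait the rule applies to.
#' @param threshold Elimination threshold in trait units.
#' @param comparison Only `"eliminate_if_below"` is defined: a line is
#'   eliminated iff its value is strictly below the threshold (a value
#'   exactly at the threshold is retained).
#' @return An object of class `culling_rule`.
#' @export
culling_rule <- function(trait, threshold,
                         comparison = "eliminate_if_below") {
  comparison <- match.arg(comparison)
  stopifnot(is.finite(threshold))
  structure(list(trait = trait, threshold = threshold,
                 comparison = comparison),
            class = "culling_rule")
}

#' Default culling levels
#'
#' Lines are eliminated when seed protein falls below 15 g/100 g seed dry
#' weight or shelling percentage falls below 50%.
#'
#' @return List of two [culling_rule()] objects.
#' @export
default_culling_rules <- function() {
  list(culling_rule("Protein", 15),
       culling_rule("Shelling percentage", 50))
}

#' Score lines under one scenario
#'
#' The scenario score of a line is the sum over the scenario's base traits of
#' the trait weight times the line's SND value.
#'
#' @param snd An [standardize()]d `snd_table` containing every base trait.
#' @param scenario A [scenario_definition()].
#' @param score_traits `"all"` (default; every base-set trait contributes,
#'   unselected ones at the base weight) or `"selected_only"` (only the
#'   emphasised traits contribute).
#' @return Named numeric vector of per-line scores.
#' @export
score_scenario <- function(snd, scenario,
                           score_traits = c("all", "selected_only")) {
  score_traits <- match.arg(score_traits)
  stopifnot(inherits(snd, "snd_table"),
            inherits(scenario, "scenario_definition"))
  w <- scenario_weights(scenario)
  if (score_traits == "selected_only")
    w <- w[normalize_trait_name(names(w)) %in%
             normalize_trait_name(names(scenario$selected_weights))]
  idx <- match(normalize_trait_name(names(w)),
               normalize_trait_name(snd$traits$name))
  if (anyNA(idx))
    stop("trait column(s) missing from table: ",
         paste(names(w)[is.na(idx)], collapse = ", "))
  drop(snd$values[, idx, drop = FALSE] %*% w)
}

#' Score lines under every scenario of a registry
#'
#' @param snd An `snd_table`.
#' @param scenarios List of [scenario_definition()] objects.
#' @param score_traits Passed to [score_scenario()].
#' @return Numeric matrix, lines x scenarios, with an `index_id` attribute
#'   mapping each column to its index.
#' @export
score_all_scenarios <- function(snd, scenarios = default_scenarios(),
                                score_traits = "all") {
  scores <- vapply(scenarios, score_scenario, numeric(length(snd$lines)),
                   snd = snd, score_traits = score_traits)
  if (length(snd$lines) == 1L) scores <- matrix(scores, nrow = 1L)
  dimnames(scores) <- list(snd$lines,
                           vapply(scenarios, `[[`, character(1L),
                                  "scenario_id"))
  attr(scores, "index_id") <- vapply(scenarios, `[[`, character(1L),
                                     "index_id")
  scores
}

#' Apply independent culling levels
#'
#' @param table A [trait_table()].
#' @param rules List of [culling_rule()] objects; with no rules every line is
#'   retained.
#' @return Character vector of retained line identifiers, in table order.
#' @export
apply_culling <- function(table, rules = default_culling_rules()) {
  stopifnot(inherits(table, "trait_table"))
  keep <- rep(TRUE, length(table$lines))
  for (rule in rules) {
    j <- match(normalize_trait_name(rule$trait),
               normalize_trait_name(table$traits$name))
    if (is.na(j)) stop("culling trait missing from table: ", rule$trait)
    v <- table$values[, j]
    keep <- keep & !(!is.na(v) & v < rule$threshold)
  }
  table$lines[keep]
}

#' Lines with positive scores in every scenario of an index
#'
#' @param scores Score matrix from [score_all_scenarios()].
#' @param index_id Index to compile, e.g. `"SI-3"`.
#' @return Character vector of line identifiers scoring strictly above zero
#'   in all of the index's scenarios.
#' @export
compile_positive <- function(scores, index_id) {
  map <- attr(scores, "index_id")
  cols <- which(map == index_id)
  if (!length(cols)) stop("no scenarios found for index ", index_id)
  pos <- rowSums(scores[, cols, drop = FALSE] > 0) == length(cols)
  rownames(scores)[pos]
}

#' Select the top-k positively scoring lines
#'
#' Among lines that survived culling and have a strictly positive aggregate
#' score, the `k` highest scorers are selected; ties are broken by line
#' identifier order. Fewer than `k` lines may qualify.
#'
#' @param index_scores Named numeric vector of aggregate per-line scores.
#' @param culled Character vector of line identifiers that survived culling.
#' @param k Number of lines to select (default 15).
#' @return Ordered character vector of selected line identifiers.
#' @export
select_top_k <- function(index_scores, culled = names(index_scores),
                         k = 15L) {
  stopifnot(k >= 1L, !is.null(names(index_scores)))
  eligible <- index_scores[names(index_scores) %in% culled]
  eligible <- eligible[eligible > 0]
  if (!length(eligible)) {
    warning("no lines with positive score survive culling")
    return(character())
  }
  ord <- order(-eligible, names(eligible))
  sel <- names(eligible)[ord]
  if (length(sel) < k)
    warning("only ", length(sel), " qualifying lines for k = ", k)
  utils::head(sel, k)
}

#' Expected percent gain of a selection
#'
#' For each trait, the relative difference between the selected lines' mean
#' and the whole population's mean, in original measurement units:
#' `100 (mean(selected) - mean(all)) / mean(all)`.
#'
#' @param table A [trait_table()].
#' @param selected Non-empty character vector of selected line identifiers,
#'   all present in the table.
#' @param index_id Optional index label stamped on the report.
#' @return An object of class `gain_report`: a data frame with columns
#'   `trait`, `population_mean`, `selected_mean`, `percent_change`, plus
#'   attributes `index_id` and `selected_lines`.
#' @export
expected_gain <- function(table, selected, index_id = NA_character_) {
  stopifnot(inherits(table, "trait_table"))
  if (!length(selected)) stop("empty selection")
  if (!all(selected %in% table$lines))
    stop("selected line(s) not in table: ",
         paste(setdiff(selected, table$lines), collapse = ", "))
  pop <- colMeans(table$values)
  if (any(pop == 0))
    stop("population mean is zero for trait(s): ",
         paste(table$traits$name[pop == 0], collapse = ", "),
         "; percent change undefined")
  sel <- colMeans(table$values[match(selected, table$lines), , drop = FALSE])
  out <- data.frame(trait = table$traits$name,
                    population_mean = unname(pop),
                    selected_mean = unname(sel),
                    percent_change = unname(100 * (sel - pop) / pop),
                    stringsAsFactors = FALSE)
  attr(out, "index_id") <- index_id
  attr(out, "selected_lines") <- selected
  class(out) <- c("gain_report", "data.frame")
  out
}

#' @export
print.gain_report <- function(x, digits = 2, ...) {
  id <- attr(x, "index_id")
  cat("Expected gain", if (!is.na(id)) paste0("(", id, ")"), "over",
      length(attr(x, "selected_lines")), "selected lines\n")
  df <- as.data.frame(x)
  df$percent_change <- round(df$percent_change, digits)
  df$population_mean <- signif(df$population_mean, 4)
  df$selected_mean <- signif(df$selected_mean, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
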