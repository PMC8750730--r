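# Deterministic formulas turning raw field and bench measurements into the
# analysis traits.

#' Composition and energy conversion constants
#'
#' @param nitrogen_to_protein Nitrogen-to-crude-protein conversion factor
#'   (default 6.25, the standard Dumas/Kjeldahl factor for legume seed).
#' @param energy_lipid,energy_protein,energy_carb Metabolizable energy per
#'   gram of lipid, protein and carbohydrate in kJ/g (defaults 35, 14.5, 17).
#' @return An object of class `composition_constants`.
#' @export
composition_constants <- function(nitrogen_to_protein = 6.25,
                                  energy_lipid = 35,
                                  energy_protein = 14.5,
                                  energy_carb = 17) {
  v <- c(nitrogen_to_protein, energy_lipid, energy_protein, energy_carb)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all composition constants must be strictly positive")
  structure(list(nitrogen_to_protein = nitrogen_to_protein,
                 energy_lipid = energy_lipid,
                 energy_protein = energy_protein,
                 energy_carb = energy_carb),
            class = "composition_constants")
}

#' Crude protein from total nitrogen
#'
#' @param nitrogen Total nitrogen in g/100 g.
#' @param constants A [composition_constants()].
#' @return Crude protein in g/100 g (`nitrogen * factor`).
#' @export
protein_from_nitrogen <- function(nitrogen,
                                  constants = composition_constants()) {
  if (any(nitrogen < 0, na.rm = TRUE)) stop("nitrogen must be >= 0")
  nitrogen * constants$nitrogen_to_protein
}

#' Total carbohydrate by difference
#'
#' Carbohydrate as the remainder after protein, lipid, ash and moisture are
#' subtracted from 100 g.
#'
#' @param protein,lipid,ash,moisture Component concentrations in
#'   g/100 g fresh weight, each >= 0.
#' @return Carbohydrate in g/100 g: `100 - (protein + lipid + ash + moisture)`.
#' @export
carbohydrate_by_difference <- function(protein, lipid, ash, moisture) {
  comp <- cbind(protein, lipid, ash, moisture)
  if (any(comp < 0, na.rm = TRUE)) stop("components must be >= 0")
  tot <- protein + lipid + ash + moisture
  if (any(tot > 100 + 1e-9, na.rm = TRUE))
    stop("components sum above 100 g/100 g")
  100 - tot
}

#' Convert a fresh-weight concentration to dry-weight basis
#'
#' Standard moisture correction: `value * 100 / (100 - moisture)`.
#'
#' @param value_fw Concentration in g/100 g fresh weight.
#' @param moisture Moisture in g/100 g fresh weight, in [0, 100).
#' @return Concentration in g/100 g dry weight.
#' @seealso [dry_to_fresh()] for the inverse map.
#' @export
fresh_to_dry <- function(value_fw, moisture) {
  if (any(moisture < 0 | moisture >= 100, na.rm = TRUE))
    stop("moisture must lie in [0, 100)")
  value_fw * 100 / (100 - moisture)
}

#' Convert a dry-weight concentration back to fresh-weight basis
#'
#' @param value_dw Concentration in g/100 g dry weight.
#' @param moisture Moisture in g/100 g fresh weight, in [0, 100).
#' @return Concentration in g/100 g fresh weight.
#' @export
dry_to_fresh <- function(value_dw, moisture) {
  if (any(moisture < 0 | moisture >= 100, na.rm = TRUE))
    stop("moisture must lie in [0, 100)")
  value_dw * (100 - moisture) / 100
}

#' Single seed size
#'
#' Mean weight per seed: total seed weight divided by seed count, in g/seed.
#'
#' @param total_seed_weight Weight of all seeds in g, >= 0.
#' @param seed_count Total number of seeds, >= 1.
#' @return Seed size in g/seed.
#' @export
single_seed_size <- function(total_seed_weight, seed_count) {
  if (any(seed_count < 1, na.rm = TRUE)) stop("seed_count must be >= 1")
  if (any(total_seed_weight < 0, na.rm = TRUE))
    stop("total_seed_weight must be >= 0")
  total_seed_weight / seed_count
}

#' Shelling percentage
#'
#' Seed weight as a percentage of total pod (seed + shell) weight; the
#' edible fraction of yield.
#'
#' @param total_seed_weight Total seed weight in g.
#' @param total_pod_weight Total pod weight in g, > 0 and >= seed weight.
#' @return Percentage in [0, 100].
#' @export
shelling_percentage <- function(total_seed_weight, total_pod_weight) {
  if (any(total_pod_weight <= 0, na.rm = TRUE))
    stop("total_pod_weight must be > 0")
  if (any(total_seed_weight > total_pod_weight, na.rm = TRUE))
    stop("seed weight cannot exceed pod weight")
  100 * total_seed_weight / total_pod_weight
}

#' Partition metabolizable energy across macronutrients
#'
#' Each component's share of total metabolizable energy, using per-gram
#' energy factors: `fraction_i = c_i E_i / sum_j c_j E_j`. Fractions sum to 1
#' and are invariant to uniform rescaling of the composition.
#'
#' @param lipid,protein,carb Concentrations in g/100 g dry weight, >= 0 and
#'   not all zero.
#' @param constants A [composition_constants()].
#' @return Named numeric vector `c(lipid =, protein =, carb =)` of energy
#'   fractions summing to 1.
#' @export
energy_fractions <- function(lipid, protein, carb,
                             constants = composition_constants()) {
  comp <- c(lipid = lipid, protein = protein, carb = carb)
  if (any(comp < 0)) stop("components must be >= 0")
  en <- c(lipid * constants$energy_lipid,
          protein * constants$energy_protein,
          carb * constants$energy_carb)
  tot <- sum(en)
  if (tot <= 0) stop("all-zero composition: energy fractions undefined")
  stats::setNames(en / tot, c("lipid", "protein", "carb"))
}
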