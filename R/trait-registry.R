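#' Normalise a trait name for matching
#'
#' Trait names are matched case-insensitively with internal whitespace
#' collapsed, because source tables capitalise inconsistently
#' ("Seed Lipid", "seed lipid", "Seed  lipid" all refer to the same trait).
#'
#' @param x Character vector of trait names.
#' @return Character vector of canonical lookup keys.
#' @export
normalize_trait_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

#' Construct a trait definition
#'
#' A trait definition records a trait's name, measurement units, optional
#' controlled-vocabulary accessions in the Crop Dietary Nutritional Ontology
#' (CDNO) and the bambara groundnut Crop Ontology (CO_366), and the direction
#' in which breeders ordinarily want the trait to move.
#'
#' @param name Trait name (unique within a registry).
#' @param units Measurement units, e.g. `"g/100 g seed dry weight"`.
#' @param cdno_id Optional CDNO accession, pattern `CDNO:NNNNNNN`, or `NA`.
#' @param co366_id Optional Crop Ontology accession, pattern `CO_366:NNNNNNN`,
#'   or `NA`.
#' @param direction One of `"higher_is_better"`, `"lower_is_better"`,
#'   `"neutral"`.
#' @return A one-row data frame with class `trait_definition` rows; registries
#'   are data frames of such rows.
#' @export
trait_definition <- function(name, units, cdno_id = NA_character_,
                             co366_id = NA_character_,
                             direction = c("neutral", "higher_is_better",
                                           "lower_is_better")) {
  direction <- match.arg(direction)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.na(cdno_id) && !grepl("^CDNO:\\d{7}$", cdno_id))
    stop("malformed CDNO accession: ", cdno_id)
  if (!is.na(co366_id) && !grepl("^CO_366:\\d{7}$", co366_id))
    stop("malformed CO_366 accession: ", co366_id)
  data.frame(name = name, units = units, cdno_id = cdno_id,
             co366_id = co366_id, direction = direction,
             stringsAsFactors = FALSE)
}

#' Default registry of seed-composition and agronomic traits
#'
#' Returns the registry of the fifteen seed-composition and agronomic traits
#' used throughout this package, with their CDNO and bambara groundnut Crop
#' Ontology (CO_366) accessions where such accessions exist. Proximate
#' components are recorded in g/100 g seed dry weight, individual fatty acids
#' as percentages of total fatty acid, and yield traits in their field units.
#'
#' @return A data frame with columns `name`, `units`, `cdno_id`, `co366_id`,
#'   `direction`; one row per trait.
#' @examples
#' reg <- default_trait_registry()
#' reg[reg$name == "Lipid", c("cdno_id", "co366_id")]
#' @export
default_trait_registry <- function() {
  rows <- list(
    trait_definition("Moisture", "g/100 g seed fresh weight",
                     "CDNO:0200002", "CO_366:0000185", "lower_is_better"),
    trait_definition("Ash", "g/100 g seed dry weight",
                     "CDNO:0200004", NA, "neutral"),
    trait_definition("Lipid", "g/100 g seed dry weight",
                     "CDNO:0200068", "CO_366:0000023", "higher_is_better"),
    trait_definition("Protein", "g/100 g seed dry weight",
                     "CDNO:0200040", "CO_366:0000026", "higher_is_better"),
    trait_definition("Total carbohydrate", "g/100 g seed dry weight",
                     "CDNO:0200005", "CO_366:0000309", "neutral"),
    trait_definition("Fatty acid composition", "% of total fatty acid",
                     "CDNO:0200465", NA, "neutral"),
    trait_definition("Oleic acid", "% of total fatty acid",
                     "CDNO:0200085", NA, "higher_is_better"),
    trait_definition("Lignoceric acid", "% of total fatty acid",
                     "CDNO:0200081", NA, "neutral"),
    trait_definition("Linoleic acid", "% of total fatty acid",
                     "CDNO:0200102", NA, "neutral"),
    trait_definition("Linolenic acid", "% of total fatty acid",
                     "CDNO:0200097", NA, "neutral"),
    trait_definition("Seed number", "count",
                     NA, "CO_366:0000340", "higher_is_better"),
    trait_definition("Dry seed weight", "g",
                     NA, "CO_366:0000337", "higher_is_better"),
    trait_definition("Dry pod weight", "g",
                     NA, "CO_366:0000325", "higher_is_better"),
    trait_definition("Single seed size", "g/seed",
                     NA, "CO_366:0000328", "higher_is_better"),
    trait_definition("Shelling percentage", "%",
                     NA, "CO_366:0000334", "higher_is_better")
  )
  reg <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(normalize_trait_name(reg$name)))
  reg
}

#' Look up a trait in a registry
#'
#' @param registry A registry data frame as from [default_trait_registry()].
#' @param name Trait name; matched case-insensitively with whitespace
#'   collapsed.
#' @return The matching registry row, or an error if absent.
#' @export
registry_lookup <- function(registry, name) {
  key <- normalize_trait_name(name)
  hit <- which(normalize_trait_name(registry$name) == key)
  if (length(hit) == 0L) stop("trait not found in registry: ", name)
  registry[hit, , drop = FALSE]
}

#' Export a trait registry as JSON
#'
#' @param registry A registry data frame.
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_trait_registry_json <- function(registry, path) {
  jsonlite::write_json(registry, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
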