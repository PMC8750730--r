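# Small in-code fixtures shared across tests.

# A random trait table over the 11-trait index base set (plus lignoceric acid
# when `with_lignoceric`), positive-valued so percentage invariants hold.
random_base_table <- function(n_lines = 10, seed = 42,
                              with_lignoceric = FALSE) {
  traits <- index_base_traits()
  if (with_lignoceric) traits <- c(traits, "Lignoceric acid")
  withr::with_seed(seed, {
    vals <- sapply(traits, function(tr) {
      base <- switch(tr,
                     "Shelling percentage" = runif(n_lines, 30, 80),
                     "Protein" = runif(n_lines, 14, 29),
                     "Lipid" = runif(n_lines, 4, 9),
                     "Total carbohydrate" = runif(n_lines, 58, 70),
                     "Oleic acid" = runif(n_lines, 15, 29),
                     "Linoleic acid" = runif(n_lines, 33, 45),
                     "Linolenic acid" = runif(n_lines, 1, 4),
                     "Lignoceric acid" = runif(n_lines, 1, 3),
                     "Single seed size" = runif(n_lines, 0.3, 0.9),
                     runif(n_lines, 10, 90))
      base
    })
    rownames(vals) <- sprintf("line%02d", seq_len(n_lines))
    trait_table(vals)
  })
}

# Printed per-trait heritability triples (generation 1->2, 2->3, GxE) and the
# printed integer averages, in trait order.
published_heritability_triples <- function() {
  list(
    "Seed number" = list(c(37, 41, NA), 26),
    "Pod DW" = list(c(20, 6, NA), 19),
    "Seed DW" = list(c(28, 12, NA), 13),
    "SSS" = list(c(67, 16, NA), 28),
    "Shelling %" = list(c(22, 7, NA), 10),
    "Protein" = list(c(27, 72, 77), 59),
    "Lipid" = list(c(34, 45, 63), 47),
    "Carb" = list(c(35, 58, 17), 37),
    "Linoleic acid" = list(c(9, 36, 0), 15),
    "Oleic acid" = list(c(67, 79, 0), 49),
    "Lignoceric acid" = list(c(77, 62, 69), 69),
    "Linolenic acid" = list(c(44, 32, 81), 52)
  )
}
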