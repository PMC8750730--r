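#' Construct a line-by-trait table
#'
#' The central rectangular container of the package: one row per breeding
#' line, one column per trait, real-valued measurements with missing values
#' allowed. Percentage-typed traits (units containing `%`) must lie in
#' [0, 100] where non-missing.
#'
#' @param values Numeric matrix (lines x traits). Row names supply line
#'   identifiers unless `lines` is given; column names supply trait names.
#' @param lines Optional character vector of line identifiers.
#' @param registry Optional trait registry; traits present in the registry
#'   contribute their units and accessions, unknown traits are kept with a
#'   warning.
#' @param metadata Optional named list of free-form metadata (growing season,
#'   location, source).
#' @return An object of class `trait_table` with components `lines`, `traits`
#'   (a registry-style data frame), `values` (the numeric matrix) and
#'   `metadata`.
#' @export
trait_table <- function(values, lines = rownames(values),
                        registry = default_trait_registry(),
                        metadata = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(lines)) lines <- paste0("line", seq_len(nrow(values)))
  lines <- as.character(lines)
  if (length(lines) != nrow(values))
    stop("length of 'lines' must equal nrow(values)")
  dup <- lines[duplicated(lines)]
  if (length(dup))
    stop("duplicate line identifier(s): ", paste(unique(dup), collapse = ", "))
  trait_names <- colnames(values)
  if (is.null(trait_names))
    stop("'values' must have column names giving trait names")
  rownames(values) <- lines

  keys <- normalize_trait_name(trait_names)
  reg_keys <- normalize_trait_name(registry$name)
  idx <- match(keys, reg_keys)
  unknown <- trait_names[is.na(idx)]
  if (length(unknown))
    warning("trait(s) not in registry: ", paste(unknown, collapse = ", "))
  traits <- data.frame(name = trait_names,
                       units = ifelse(is.na(idx), NA_character_,
                                      registry$units[idx]),
                       cdno_id = ifelse(is.na(idx), NA_character_,
                                        registry$cdno_id[idx]),
                       co366_id = ifelse(is.na(idx), NA_character_,
                                         registry$co366_id[idx]),
                       direction = ifelse(is.na(idx), "neutral",
                                          registry$direction[idx]),
                       stringsAsFactors = FALSE)

  pct <- !is.na(traits$units) & grepl("%", traits$units, fixed = TRUE)
  for (j in which(pct)) {
    v <- values[, j]
    bad <- !is.na(v) & (v < 0 | v > 100)
    if (any(bad))
      stop("percentage trait '", trait_names[j],
           "' outside [0, 100] for line(s): ",
           paste(lines[bad], collapse = ", "))
  }

  structure(list(lines = lines, traits = traits, values = values,
                 metadata = metadata),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Line-by-trait table: ", length(x$lines), " lines x ",
      nrow(x$traits), " traits\n", sep = "")
  n_miss <- sum(is.na(x$values))
  if (n_miss) cat("Missing cells:", n_miss, "\n")
  cat("Traits:", paste(x$traits$name, collapse = ", "), "\n")
  if (length(x$metadata))
    cat("Metadata:", paste(names(x$metadata), unlist(x$metadata),
                           sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' @export
dim.trait_table <- function(x) dim(x$values)

#' @export
as.matrix.trait_table <- function(x, ...) x$values

#' @export
as.data.frame.trait_table <- function(x, ...) {
  cbind(data.frame(line = x$lines, stringsAsFactors = FALSE),
        as.data.frame(x$values, row.names = NULL))
}

#' Drop lines containing missing values
#'
#' Most operations in the package refuse missing data; this is the explicit
#' opt-in that removes incomplete lines first.
#'
#' @param table A [trait_table()].
#' @return A `trait_table` restricted to complete lines.
#' @export
drop_incomplete_lines <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  keep <- stats::complete.cases(table$values)
  trait_table(table$values[keep, , drop = FALSE],
              lines = table$lines[keep], metadata = table$metadata)
}

#' Subset traits of a table
#'
#' @param table A [trait_table()].
#' @param traits Character vector of trait names (matched case-insensitively).
#' @return A `trait_table` with the requested trait columns, in the requested
#'   order.
#' @export
subset_traits <- function(table, traits) {
  stopifnot(inherits(table, "trait_table"))
  idx <- match(normalize_trait_name(traits),
               normalize_trait_name(table$traits$name))
  if (anyNA(idx))
    stop("trait(s) not present in table: ",
         paste(traits[is.na(idx)], collapse = ", "))
  trait_table(table$values[, idx, drop = FALSE], lines = table$lines,
              metadata = table$metadata)
}

#' Read a line-by-trait table from CSV
#'
#' Expects a comma-separated UTF-8 file whose header row names the traits and
#' whose first column (`line`) holds the line identifiers. Empty cells become
#' missing values; any other non-numeric cell is a hard error reporting its
#' position.
#'
#' @param path Path to the CSV file.
#' @param registry Trait registry used to attach units and accessions; traits
#'   absent from the registry are flagged with a warning.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path, registry = default_trait_registry()) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (ncol(raw) < 1L) stop("empty CSV: ", path)
  lines <- raw[[1L]]
  dup <- lines[duplicated(lines)]
  if (length(dup))
    stop("duplicate line identifier(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  cols <- raw[-1L]
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(cols),
                 dimnames = list(NULL, names(cols)))
  for (j in seq_along(cols)) {
    cell <- trimws(cols[[j]])
    empty <- !nzchar(cell)
    parsed <- suppressWarnings(as.numeric(cell))
    bad <- !empty & is.na(parsed)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("non-numeric cell at row ", i, " (line '", lines[i],
           "'), column '", names(cols)[j], "': '", cell[i], "'")
    }
    parsed[empty] <- NA_real_
    vals[, j] <- parsed
  }
  trait_table(vals, lines = lines, registry = registry)
}

#' Write a line-by-trait table to CSV
#'
#' Columns are written in the table's trait order, with the line identifier
#' first under the header `line`; missing values are written as empty cells.
#'
#' @param table A [trait_table()].
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_trait_table <- function(table, path) {
  stopifnot(inherits(table, "trait_table"))
  df <- as.data.frame(table)
  utils::write.csv(df, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a genotype-by-environment trial dataset
#'
#' Long-format records of a replicated multi-environment trial: one row per
#' genotype x environment x block observation of a single trait.
#'
#' @param genotype,environment,block Character or factor identifiers.
#' @param trait Trait name, recycled if scalar.
#' @param value Numeric trait measurements.
#' @return An object of class `gxe_dataset` (a validated data frame).
#' @export
gxe_dataset <- function(genotype, environment, block, trait, value) {
  df <- data.frame(genotype = as.character(genotype),
                   environment = as.character(environment),
                   block = as.character(block),
                   trait = as.character(trait),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  key <- paste(df$genotype, df$environment, df$block, df$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (genotype, environment, block, trait) record(s)")
  class(df) <- c("gxe_dataset", "data.frame")
  df
}

#' Check whether a trial dataset is balanced
#'
#' A design is balanced when every genotype x environment cell holds the same
#' number of replicate records for the trait.
#'
#' @param data A [gxe_dataset()].
#' @param trait Trait to check; defaults to the only trait present.
#' @return Logical scalar.
#' @export
is_balanced <- function(data, trait = unique(data$trait)) {
  stopifnot(inherits(data, "gxe_dataset"), length(trait) == 1L)
  d <- data[data$trait == trait, ]
  counts <- table(d$genotype, d$environment)
  length(unique(as.vector(counts))) == 1L && all(counts > 0L)
}

#' Construct a parent-offspring pedigree table
#'
#' Records trait-value pairs across successive generation transitions for a
#' set of lines, as used in parent-offspring regression heritability.
#'
#' @param line Line identifier per record.
#' @param generation_from Integer generation index of the parent.
#' @param parent_value,offspring_value Numeric trait values.
#' @param trait Trait name, recycled if scalar.
#' @return An object of class `pedigree_table` (a data frame whose
#'   `generation_to` is always `generation_from + 1`).
#' @export
pedigree_table <- function(line, generation_from, parent_value,
                           offspring_value, trait) {
  df <- data.frame(line = as.character(line),
                   generation_from = as.integer(generation_from),
                   generation_to = as.integer(generation_from) + 1L,
                   parent_value = as.numeric(parent_value),
                   offspring_value = as.numeric(offspring_value),
                   trait = as.character(trait),
                   stringsAsFactors = FALSE)
  class(df) <- c("pedigree_table", "data.frame")
  df
}
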