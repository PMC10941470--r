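# Reading, normalizing and reshaping folk-nomenclature tables.

#' Sentinel species id used by single-taxon (landrace) tables
#'
#' Landrace name lists record varieties of a single crop, so there is no real
#' species column; records carry this sentinel instead, letting one table type
#' serve both multi-species and single-crop data.
#' @export
SINGLE_TAXON <- ".single-taxon"

#' Normalize a vernacular name to a comparable token
#'
#' Applies Unicode compatibility (NFKC) normalization, strips straight and
#' typographic quote characters (the enclosed text is kept, so `"Oozu" nishiki`
#' and `Oozu nishiki` compare equal), trims, collapses internal whitespace to
#' single spaces, and case-folds. Matching downstream is exact token equality:
#' no cognate or edit-distance matching is attempted.
#'
#' @param raw character vector of raw names.
#' @return character vector of normalized tokens.
#' @examples
#' normalize_name("  Senbon ")
#' normalize_name("“Oozu” nishiki")
#' @export
normalize_name <- function(raw) {
  if (!is.character(raw)) raw <- as.character(raw)
  x <- stringi::stri_trans_nfkc(raw)
  x <- stringi::stri_replace_all_regex(x, "[\"'‘’‚‛“”„‟«»‹›]", "")
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  x <- stringi::stri_trim_both(x)
  x <- stringi::stri_trans_tolower(x)
  if (any(!nzchar(x) & !is.na(x))) {
    stop("normalize_name(): name(s) empty after normalization: raw value(s) ",
         paste(utils::head(sQuote(raw[!nzchar(x) & !is.na(x)]), 5), collapse = ", "),
         call. = FALSE)
  }
  x
}

new_folk_table <- function(records) {
  records <- records[order(records$unit_id, records$species_id, records$name), , drop = FALSE]
  rownames(records) <- NULL
  units <- sort(unique(records$unit_id))
  species <- sort(unique(records$species_id))
  coverage <- lapply(split(records$species_id, factor(records$unit_id, levels = units)),
                     function(s) sort(unique(s)))
  structure(
    list(records = records, units = units, species = species, coverage = coverage),
    class = "folk_table"
  )
}

#' Build a folk-nomenclature table from unit/species/name records
#'
#' @param unit_id,species_id,name character vectors of equal length; `name`
#'   is normalized with [normalize_name()] unless `normalize = FALSE`.
#'   `species_id` may be omitted for single-crop (landrace) data, in which
#'   case all records carry the [SINGLE_TAXON] sentinel.
#' @param normalize normalize names before deduplication?
#' @return a `folk_table`: records plus unit and species rosters and per-unit
#'   survey coverage (the set of species with at least one record).
#' @export
folk_table <- function(unit_id, species_id = NULL, name, normalize = TRUE) {
  if (is.null(species_id)) species_id <- rep(SINGLE_TAXON, length(unit_id))
  stopifnot(length(unit_id) == length(species_id), length(unit_id) == length(name))
  if (length(unit_id) == 0L) stop("folk_table(): no records", call. = FALSE)
  name <- if (normalize) normalize_name(name) else as.character(name)
  records <- data.frame(unit_id = as.character(unit_id),
                        species_id = as.character(species_id),
                        name = name, stringsAsFactors = FALSE)
  dup <- duplicated(records)
  if (any(dup)) {
    message("folk_table: collapsed ", sum(dup), " duplicate record(s)")
    records <- records[!dup, , drop = FALSE]
  }
  new_folk_table(records)
}

#' Read a folk-nomenclature table from CSV
#'
#' Expects a header row; the `schema` argument maps the required fields to the
#' file's column names. Duplicate (unit, species, name) triples are collapsed
#' with a message; empty-name rows are rejected.
#'
#' @param source path to a UTF-8, comma-delimited CSV file (or a connection).
#' @param schema named character vector mapping fields `unit_id`, `name` and
#'   optionally `species_id` to column names in the file.
#' @param normalize normalize names with [normalize_name()]?
#' @return a `folk_table`.
#' @export
read_name_table <- function(source,
                            schema = c(unit_id = "unit_id",
                                       species_id = "species_id",
                                       name = "name"),
                            normalize = TRUE) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  needed <- schema[intersect(c("unit_id", "species_id", "name"), names(schema))]
  missing_cols <- setdiff(unname(needed), names(df))
  if (length(missing_cols) > 0L) {
    stop("read_name_table(): missing column(s) in input: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  name_raw <- df[[schema[["name"]]]]
  keep <- !is.na(name_raw) & nzchar(trimws(name_raw))
  if (sum(keep) == 0L) stop("read_name_table(): no usable records in input", call. = FALSE)
  if (any(!keep)) message("read_name_table: dropped ", sum(!keep), " empty-name row(s)")
  df <- df[keep, , drop = FALSE]
  species <- if ("species_id" %in% names(schema) && schema[["species_id"]] %in% names(df)) {
    df[[schema[["species_id"]]]]
  } else NULL
  folk_table(df[[schema[["unit_id"]]]], species, df[[schema[["name"]]]],
             normalize = normalize)
}

#' Write a folk-nomenclature table to CSV
#'
#' Inverse of [read_name_table()]: writes columns `unit_id,species_id,name`,
#' one record per row, in the table's canonical sort order so that
#' read-write-read round-trips are exact.
#'
#' @param table a `folk_table`.
#' @param path output file path.
#' @export
write_name_table <- function(table, path) {
  stopifnot(inherits(table, "folk_table"))
  utils::write.csv(table$records, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.folk_table <- function(x, ...) {
  cat("Folk-nomenclature table:", nrow(x$records), "records,",
      length(x$units), "units,", length(x$species), "species,",
      length(unique(x$records$name)), "distinct names\n")
  invisible(x)
}

#' Merge survey units under a relabeling map
#'
#' Used when historically subdivided locations are folded back into a single
#' municipal framework: records are re-labeled, duplicates collapsed, and
#' survey coverage recomputed as the union of the merged units' coverage.
#'
#' @param table a `folk_table`.
#' @param mapping named character vector, `old unit -> new unit`. Units absent
#'   from the map keep their label.
#' @return a `folk_table` on the merged roster.
#' @export
merge_units <- function(table, mapping) {
  stopifnot(inherits(table, "folk_table"))
  if (length(mapping) > 0L) {
    if (is.null(names(mapping)) || any(!nzchar(names(mapping))))
      stop("merge_units(): mapping must be a named vector old -> new", call. = FALSE)
    if (anyDuplicated(names(mapping)))
      stop("merge_units(): unit(s) mapped to multiple new units: ",
           paste(unique(names(mapping)[duplicated(names(mapping))]), collapse = ", "),
           call. = FALSE)
  }
  rec <- table$records
  hit <- rec$unit_id %in% names(mapping)
  rec$unit_id[hit] <- unname(mapping[rec$unit_id[hit]])
  dup <- duplicated(rec)
  if (any(dup)) {
    message("merge_units: collapsed ", sum(dup), " duplicate record(s) after merging")
    rec <- rec[!dup, , drop = FALSE]
  }
  new_folk_table(rec)
}

#' Drop units with scarce survey coverage
#'
#' Units whose coverage contains fewer than `min_species` surveyed species are
#' removed; the drop list is reported. The default threshold of 5 surveyed
#' species marks a unit as too thinly surveyed to support pairwise comparison.
#'
#' @param table a `folk_table`.
#' @param min_species minimum number of surveyed species a unit must have.
#' @return a filtered `folk_table`; the dropped unit ids are attached as
#'   attribute `"dropped_units"`.
#' @export
filter_scarce_units <- function(table, min_species = 5L) {
  stopifnot(inherits(table, "folk_table"), min_species >= 1L)
  n_cov <- vapply(table$coverage, length, integer(1))
  drop <- names(n_cov)[n_cov < min_species]
  if (length(drop) == length(table$units)) {
    stop("filter_scarce_units(): all units fall below min_species = ",
         min_species, call. = FALSE)
  }
  if (length(drop) > 0L) {
    message("filter_scarce_units: dropped ", length(drop), " unit(s): ",
            paste(drop, collapse = ", "))
  }
  rec <- table$records[!(table$records$unit_id %in% drop), , drop = FALSE]
  out <- new_folk_table(rec)
  attr(out, "dropped_units") <- drop
  out
}

#' Convert a folk-nomenclature table to a binary occurrence matrix
#'
#' @param table a `folk_table`.
#' @return an `occurrence_table`: a binary unit-by-name matrix with
#'   `presence[u, n] = 1` iff unit `u` records name `n` for any species.
#' @export
to_occurrence <- function(table) {
  stopifnot(inherits(table, "folk_table"))
  units <- table$units
  names_ <- sort(unique(table$records$name))
  m <- matrix(0L, length(units), length(names_),
              dimnames = list(units, names_))
  m[cbind(match(table$records$unit_id, units),
          match(table$records$name, names_))] <- 1L
  structure(m, class = c("occurrence_table", class(m)))
}

#' Construct an occurrence table from a plain binary matrix
#'
#' @param m binary matrix with unit rownames and name colnames.
#' @export
occurrence_table <- function(m) {
  stopifnot(is.matrix(m), all(m %in% c(0L, 1L)),
            !is.null(rownames(m)), !is.null(colnames(m)))
  storage.mode(m) <- "integer"
  structure(m, class = c("occurrence_table", "matrix", "array"))
}

#' Write an occurrence matrix as wide CSV (unit rows, name columns)
#' @param occ an `occurrence_table`.
#' @param path output path.
#' @export
write_occurrence <- function(occ, path) {
  df <- data.frame(unit_id = rownames(occ), unclass(occ), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an occurrence matrix written by [write_occurrence()]
#' @param path input path.
#' @export
read_occurrence <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, encoding = "UTF-8")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  occurrence_table(m)
}

# per-unit set of names recorded for one species (internal)
names_for <- function(table, unit, species) {
  rec <- table$records
  rec$name[rec$unit_id == unit & rec$species_id == species]
}
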