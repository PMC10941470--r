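# Flora-corrected shared-name distance and Jaccard distance.

new_dissimilarity_matrix <- function(values, defined, units) {
  dimnames(values) <- dimnames(defined) <- list(units, units)
  structure(list(units = units, values = values, defined = defined),
            class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  n <- length(x$units)
  n_undef <- sum(!x$defined[upper.tri(x$defined)])
  cat("Dissimilarity matrix:", n, "units;",
      n_undef, "undefined pair(s)\n")
  invisible(x)
}

#' Flora-corrected shared-name distance between two units
#'
#' The index \eqn{D = 1 - a/A} compares only the `A` species commonly included
#' in the folk-nomenclature survey of both units, and credits a species
#' (counted in `a`) when the two units share at least one vernacular name for
#' it. Restricting to commonly surveyed species cancels innate differences in
#' regional flora; the at-least-one-shared rule caps each species'
#' contribution at one regardless of how many synonyms were recorded.
#' When no species is commonly surveyed (`A = 0`) the pair is undefined.
#'
#' @param table a `folk_table`.
#' @param u1,u2 unit ids.
#' @return list with elements `D` (NA if undefined), `a`, `A`, `defined`.
#' @export
shared_name_distance <- function(table, u1, u2) {
  stopifnot(inherits(table, "folk_table"))
  for (u in c(u1, u2)) {
    if (!u %in% table$units) stop("shared_name_distance(): unknown unit ", u, call. = FALSE)
  }
  common <- intersect(table$coverage[[u1]], table$coverage[[u2]])
  A <- length(common)
  if (A == 0L) return(list(D = NA_real_, a = 0L, A = 0L, defined = FALSE))
  a <- sum(vapply(common, function(s) {
    length(intersect(names_for(table, u1, s), names_for(table, u2, s))) > 0L
  }, logical(1)))
  list(D = 1 - a / A, a = as.integer(a), A = as.integer(A), defined = TRUE)
}

#' Shared-name distance matrix over all unit pairs
#'
#' Computes the flora-corrected index for every pair of units. Pairs with no
#' commonly surveyed species are undefined: in strict mode this is an error
#' (the caller should merge or drop the offending units); otherwise the pair
#' is masked in `defined` and a summary is reported — no distance is ever
#' imputed.
#'
#' @param table a `folk_table`.
#' @param strict error on undefined pairs instead of masking them?
#' @return a `dissimilarity_matrix` (fields `units`, `values`, `defined`).
#' @export
shared_name_matrix <- function(table, strict = FALSE) {
  stopifnot(inherits(table, "folk_table"))
  units <- table$units
  n <- length(units)
  if (n < 2L) stop("shared_name_matrix(): need at least 2 units", call. = FALSE)

  # coverage incidence: unit x species
  cov <- matrix(0L, n, length(table$species), dimnames = list(units, table$species))
  rec <- table$records
  cov[cbind(match(rec$unit_id, units), match(rec$species_id, table$species))] <- 1L
  A <- tcrossprod(cov)                 # commonly surveyed species per pair

  # per species, pairs sharing >= 1 name: accumulate over species
  a <- matrix(0, n, n)
  for (sp in split(rec, rec$species_id)) {
    key <- paste(sp$unit_id, sp$name, sep = "\r")
    sp <- sp[!duplicated(key), , drop = FALSE]
    inc <- matrix(0L, n, length(unique(sp$name)))
    inc[cbind(match(sp$unit_id, units), match(sp$name, unique(sp$name)))] <- 1L
    a <- a + (tcrossprod(inc) > 0)
  }
  defined <- A > 0
  values <- matrix(NA_real_, n, n)
  values[defined] <- 1 - a[defined] / A[defined]
  diag(values) <- 0; diag(defined) <- TRUE
  n_undef <- sum(!defined[upper.tri(defined)])
  if (n_undef > 0L) {
    if (strict) {
      stop("shared_name_matrix(): ", n_undef, " unit pair(s) have no commonly ",
           "surveyed species; merge or drop those units, or use strict = FALSE ",
           "to mask them", call. = FALSE)
    }
    message("shared_name_matrix: ", n_undef,
            " undefined pair(s) (no commonly surveyed species) masked")
  }
  new_dissimilarity_matrix(values, defined, units)
}

#' Jaccard distance between two name sets
#'
#' \eqn{1 - |X \cap Y| / |X \cup Y|}.
#'
#' @param x,y character vectors treated as sets; not both empty.
#' @export
jaccard_distance <- function(x, y) {
  x <- unique(x); y <- unique(y)
  un <- length(union(x, y))
  if (un == 0L) stop("jaccard_distance(): both sets empty — distance undefined", call. = FALSE)
  1 - length(intersect(x, y)) / un
}

#' Jaccard distance matrix over unit name inventories
#'
#' @param occurrence an `occurrence_table` (binary unit-by-name matrix);
#'   every unit must record at least one name.
#' @return a `dissimilarity_matrix` with all pairs defined.
#' @export
jaccard_matrix <- function(occurrence) {
  stopifnot(inherits(occurrence, "occurrence_table"))
  m <- unclass(occurrence)
  if (nrow(m) < 2L) stop("jaccard_matrix(): need at least 2 units", call. = FALSE)
  empty <- rownames(m)[rowSums(m) == 0L]
  if (length(empty) > 0L) {
    stop("jaccard_matrix(): unit(s) with empty name set: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  un <- outer(sizes, sizes, "+") - inter
  values <- 1 - inter / un
  diag(values) <- 0
  new_dissimilarity_matrix(values, matrix(TRUE, nrow(m), nrow(m)), rownames(m))
}

#' Write a dissimilarity matrix as square CSV (undefined pairs as empty cells)
#' @param d a `dissimilarity_matrix`.
#' @param path output path.
#' @export
write_dissimilarity <- function(d, path) {
  stopifnot(inherits(d, "dissimilarity_matrix"))
  v <- d$values
  v[!d$defined] <- NA
  df <- data.frame(unit_id = d$units, v, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Coerce a dissimilarity matrix to `stats::dist`
#'
#' Fails if any pair is undefined; masked matrices must be repaired upstream
#' (merge or drop units) before clustering.
#' @param m a `dissimilarity_matrix`.
#' @export
as.dist.dissimilarity_matrix <- function(m, diag = FALSE, upper = FALSE) {
  if (!all(m$defined)) {
    stop("undefined pairs present; merge or drop units before clustering", call. = FALSE)
  }
  stats::as.dist(m$values, diag = diag, upper = upper)
}
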