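# Domain types: a soil sample (reference or query) described by eight
# numeric characteristics, and an ordered database of reference soils.

#' Canonical soil characteristics
#'
#' The eight numeric characteristics describing a soil, in canonical order:
#' residual BChE activity `ra` (A/A0, %), residual luminescence of the
#' two-enzyme (`t2`) and three-enzyme (`t3`) bioluminescent systems
#' (I/I0, %), optical density of the aqueous extract at 250 nm (`d250`),
#' humus mass fraction (`humus`, %), pH in KCl (`ph`), and the physical
#' clay and sand fractions (`clay`, `sand`, %). All distance computations,
#' normalization tables and file I/O use this order.
#'
#' @return Character vector of the eight internal field names.
#' @export
soil_features <- function() {
  c("ra", "t2", "t3", "d250", "humus", "ph", "clay", "sand")
}

# Canonical on-disk JSON keys, in the order they are written.
.canonical_keys <- c(
  ra = "RA", t2 = "T2", t3 = "T3", d250 = "D250", humus = "Humus",
  ph = "pH", clay = "Clay", sand = "Sand", name = "Sample Name",
  category = "Category"
)

# Display labels for report tables.
.feature_labels <- c(
  ra = "RA", t2 = "T2", t3 = "T3", d250 = "D250", humus = "Humus",
  ph = "pH", clay = "Clay", sand = "Sand"
)

# Check the numeric invariants of one record; `where` names the record in
# error messages (e.g. "record 3").
.check_soil_values <- function(vals, where = "sample") {
  feats <- soil_features()
  for (f in feats) {
    v <- vals[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v) || !is.numeric(v))
      stop(sprintf("%s: missing or non-numeric field '%s'", where, f),
           call. = FALSE)
    if (!is.finite(v))
      stop(sprintf("%s: field '%s' is not finite", where, f), call. = FALSE)
  }
  nonneg <- c("ra", "t2", "t3", "d250", "humus", "clay", "sand")
  for (f in nonneg) {
    if (vals[[f]] < 0)
      stop(sprintf("%s: field '%s' must be >= 0 (got %g)", where, f,
                   vals[[f]]), call. = FALSE)
  }
  if (vals$ph < 0 || vals$ph > 14)
    stop(sprintf("%s: pH must lie in [0, 14] (got %g)", where, vals$ph),
         call. = FALSE)
  invisible(TRUE)
}

#' Construct a soil sample
#'
#' Builds a single validated soil sample, usable both as a query against a
#' reference database and as one record of such a database. The clay and
#' sand fractions are different granulometric windows (< 0.001 mm silt vs
#' 0.05--0.25 mm fine sand) and are not required to sum to 100.
#'
#' @param ra Residual BChE activity, percent (A/A0 x 100).
#' @param t2 Residual luminescence of the two-enzyme system, percent.
#' @param t3 Residual luminescence of the three-enzyme system, percent.
#' @param d250 Optical density of the 1:5 aqueous extract at 250 nm.
#' @param humus Mass fraction of organic matter, percent.
#' @param ph pH (in KCl), pH units; must lie in \[0, 14\].
#' @param clay Physical clay fraction, percent.
#' @param sand Physical sand fraction, percent.
#' @param name Optional sample label (e.g. `"sand"`, `"light loam"`).
#' @param category Optional type-category label.
#' @return An object of class `soil_sample` (a named list).
#' @examples
#' soil_sample(108.79, 90.78, 78.55, 0.25, 0.38, 8, 6.7, 90.4, name = "sand")
#' @export
soil_sample <- function(ra, t2, t3, d250, humus, ph, clay, sand,
                        name = NULL, category = NULL) {
  x <- list(ra = as.numeric(ra), t2 = as.numeric(t2), t3 = as.numeric(t3),
            d250 = as.numeric(d250), humus = as.numeric(humus),
            ph = as.numeric(ph), clay = as.numeric(clay),
            sand = as.numeric(sand),
            name = if (is.null(name)) NA_character_ else as.character(name),
            category = if (is.null(category)) NA_character_
                       else as.character(category))
  .check_soil_values(x, where = if (is.na(x$name)) "sample"
                                else sprintf("sample '%s'", x$name))
  structure(x, class = "soil_sample")
}

#' @export
print.soil_sample <- function(x, ...) {
  cat(sprintf("<soil_sample> %s\n",
              if (is.na(x$name)) "(unnamed)" else x$name))
  v <- vapply(soil_features(), function(f) x[[f]], numeric(1))
  print(v)
  invisible(x)
}

#' Construct a reference soil database
#'
#' Wraps a data frame (or list of records) of reference soils into a
#' validated, ordered database. Record order is preserved exactly: the
#' minimum-deviation search breaks distance ties by the lowest index, so
#' order is part of the data contract.
#'
#' @param records A data frame with (at least) the eight numeric
#'   characteristic columns named as in [soil_features()], plus optional
#'   `name` and `category` columns; or a list of `soil_sample`s / named
#'   lists. Extra columns are preserved but ignored by all computations.
#' @param source Provenance note, e.g. a file path or `"synthetic"`.
#' @return An object of class `soil_db` (a data frame with attribute
#'   `source`).
#' @export
soil_db <- function(records, source = "in-memory") {
  if (is.data.frame(records)) {
    df <- as.data.frame(records, stringsAsFactors = FALSE)
  } else if (is.list(records)) {
    rows <- lapply(records, function(r) {
      r <- unclass(r)
      as.data.frame(r[!vapply(r, is.null, logical(1))],
                    stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    stop("records must be a data frame or a list of records", call. = FALSE)
  }
  if (is.null(df) || nrow(df) == 0L)
    stop("empty reference database: at least one record is required",
         call. = FALSE)
  for (col in c("name", "category"))
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  miss <- setdiff(soil_features(), names(df))
  if (length(miss) > 0L)
    stop(sprintf("reference database is missing field(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  for (f in soil_features()) df[[f]] <- as.numeric(df[[f]])
  # vectorized invariant checks; report the first offending record
  for (f in soil_features()) {
    v <- df[[f]]
    bad <- !is.finite(v)
    if (any(bad))
      stop(sprintf("record %d: missing or non-finite field '%s'",
                   which(bad)[1], f), call. = FALSE)
  }
  for (f in c("ra", "t2", "t3", "d250", "humus", "clay", "sand")) {
    bad <- df[[f]] < 0
    if (any(bad))
      stop(sprintf("record %d: field '%s' must be >= 0 (got %g)",
                   which(bad)[1], f, df[[f]][which(bad)[1]]), call. = FALSE)
  }
  bad <- df$ph < 0 | df$ph > 14
  if (any(bad))
    stop(sprintf("record %d: pH must lie in [0, 14] (got %g)",
                 which(bad)[1], df$ph[which(bad)[1]]), call. = FALSE)
  rownames(df) <- NULL
  structure(df, source = source, class = c("soil_db", "data.frame"))
}

#' @export
print.soil_db <- function(x, ...) {
  cat(sprintf("<soil_db> %d reference record(s), source: %s\n",
              nrow(x), attr(x, "source")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Number of records in a reference database
#' @param db A `soil_db`.
#' @return Integer record count.
#' @export
n_records <- function(db) {
  stopifnot(inherits(db, "soil_db"))
  nrow(db)
}

#' Extract one record of a database as a soil sample
#' @param db A `soil_db`.
#' @param i Record index (1-based).
#' @return A `soil_sample`.
#' @export
db_record <- function(db, i) {
  stopifnot(inherits(db, "soil_db"))
  if (i < 1L || i > nrow(db)) stop("record index out of bounds", call. = FALSE)
  r <- as.list(db[i, , drop = FALSE])
  soil_sample(r$ra, r$t2, r$t3, r$d250, r$humus, r$ph, r$clay, r$sand,
              name = if (is.na(r$name)) NULL else r$name,
              category = if (is.na(r$category)) NULL else r$category)
}

#' Soil texture class from the physical clay fraction
#'
#' Advisory helper naming the texture variety from the physical clay
#' fraction, on the conventional physical-clay scale: < 5 loose sand,
#' 5--10 cohesive sand, 10--20 sandy loam, 20--30 light loam, 30--40
#' medium loam, 40--50 heavy loam, >= 50 clay. Boundary values belong to
#' the coarser (lower-clay) class. The helper never overrides a stored
#' sample name: real databases may label a sample differently from its
#' measured clay fraction.
#'
#' @param clay_percent Physical clay fraction in percent, in \[0, 100\].
#'   Vectorized.
#' @return Character vector of texture class labels.
#' @examples
#' texture_class(6.7)   # "cohesive sand"
#' texture_class(47.5)  # "heavy loam"
#' @export
texture_class <- function(clay_percent) {
  if (any(!is.finite(clay_percent)) ||
      any(clay_percent < 0) || any(clay_percent > 100))
    stop("clay_percent must lie in [0, 100]", call. = FALSE)
  labs <- c("loose sand", "cohesive sand", "sandy loam", "light loam",
            "medium loam", "heavy loam", "clay")
  # right-closed intervals: a boundary value falls in the coarser class
  as.character(cut(clay_percent, breaks = c(-Inf, 5, 10, 20, 30, 40, 50, Inf),
                   labels = labs, right = TRUE))
}
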