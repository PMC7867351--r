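# Readers/writers for the flat JSON reference-database format and its
# JavaScript-wrapped dialect ("var refs = [...];"). The .js dialect is
# handled by prefix/suffix stripping only -- no script evaluation.

# Normalize a JSON key to an internal field name, or NA if unknown.
.normalize_key <- function(key) {
  k <- gsub("[ _\\.]", "", tolower(key))
  map <- c(ra = "ra", t2 = "t2", t3 = "t3", d250 = "d250", humus = "humus",
           ph = "ph", clay = "clay", claycontent = "clay", sand = "sand",
           sandcontent = "sand", samplename = "name", name = "name",
           category = "category")
  if (k %in% names(map)) unname(map[[k]]) else NA_character_
}

# Strip a leading assignment prefix (everything before the first '[' or
# '{') and anything after the last ']' or '}' (trailing ';', whitespace).
# Returns list(payload, offset) where offset is the 1-based byte position
# of the payload start in the original text.
.strip_js_wrapper <- function(text) {
  starts <- gregexpr("[[{]", text)[[1]]
  ends <- gregexpr("[]}]", text)[[1]]
  if (starts[1] == -1L || ends[1] == -1L)
    stop("no JSON payload found: expected a '[' or '{' in the input",
         call. = FALSE)
  first <- starts[1]
  last <- ends[length(ends)]
  if (last < first)
    stop("no JSON payload found: unbalanced brackets", call. = FALSE)
  list(payload = substr(text, first, last), offset = first)
}

#' Load a reference soil database
#'
#' Reads a reference database from a JSON file (a flat array of objects
#' keyed by `RA`, `T2`, `T3`, `D250`, `Humus`, `pH`, `Clay`, `Sand`,
#' `Sample Name`) or from the JavaScript-wrapped dialect in which that
#' array is assigned to a variable (`var refs = [...];`). Keys are matched
#' case-insensitively; `Sample Name`, `name` and `sample_name` are all
#' accepted for the label. Unknown keys are preserved as extra columns but
#' ignored by all computations. Record order is preserved exactly as read.
#'
#' @param source Path to the file, or a character string containing the
#'   document itself (anything holding a newline or a bracket is treated
#'   as inline text).
#' @param dialect `"auto"` (default) strips any assignment prefix and
#'   trailing semicolon before parsing -- an identity on plain JSON;
#'   `"json"` parses the text verbatim; `"js-wrapped"` requires stripping.
#' @return A validated [soil_db] whose `source` attribute records the
#'   origin.
#' @seealso [write_reference_db()]
#' @export
load_reference_db <- function(source, dialect = c("auto", "json", "js-wrapped")) {
  dialect <- match.arg(dialect)
  inline <- length(source) > 1L || grepl("[[{\n]", source)
  if (inline) {
    text <- paste(source, collapse = "\n")
    origin <- "inline text"
  } else {
    if (!file.exists(source))
      stop(sprintf("cannot read '%s': no such file", source), call. = FALSE)
    text <- paste(readLines(source, warn = FALSE), collapse = "\n")
    origin <- source
  }
  if (dialect == "json") {
    payload <- text
    offset <- 1L
  } else {
    stripped <- .strip_js_wrapper(text)
    payload <- stripped$payload
    offset <- stripped$offset
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(payload, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf(
        "malformed JSON in %s (payload starts at byte %d): %s",
        origin, offset, conditionMessage(e)), call. = FALSE)
    })
  if (!is.list(parsed))
    stop(sprintf("%s: expected a JSON array of records", origin),
         call. = FALSE)
  if (length(parsed) == 0L)
    stop(sprintf("%s: empty reference database (no records)", origin),
         call. = FALSE)

  rows <- lapply(seq_along(parsed), function(i) {
    rec <- parsed[[i]]
    if (!is.list(rec))
      stop(sprintf("record %d: expected a JSON object", i), call. = FALSE)
    out <- list()
    for (key in names(rec)) {
      field <- .normalize_key(key)
      val <- rec[[key]]
      if (is.na(field)) {
        # unknown extra field: preserved verbatim under its original key
        out[[key]] <- if (is.null(val)) NA else val
      } else {
        out[[field]] <- val
      }
    }
    for (f in soil_features()) {
      if (is.null(out[[f]]) || !is.numeric(out[[f]]))
        stop(sprintf("record %d: missing numeric field '%s'", i,
                     .canonical_keys[[f]]), call. = FALSE)
    }
    out
  })

  cols <- unique(unlist(lapply(rows, names)))
  cols <- c(intersect(c(soil_features(), "name", "category"), cols),
            setdiff(cols, c(soil_features(), "name", "category")))
  df <- as.data.frame(
    lapply(stats::setNames(cols, cols), function(cl) {
      vals <- lapply(rows, function(r)
        if (is.null(r[[cl]])) NA else r[[cl]])
      unlist(vals, use.names = FALSE)
    }),
    stringsAsFactors = FALSE, check.names = FALSE)
  soil_db(df, source = origin)
}

#' Write a reference soil database
#'
#' Serializes a database to the flat JSON array-of-objects format, or to
#' the JavaScript-wrapped dialect (an assignment prefix plus the same
#' payload and a trailing `;`). Numbers are written at full double
#' precision so that a write/load round trip reproduces every numeric
#' field bit-exactly -- the minimum-deviation search must not depend on
#' serialization.
#'
#' @param db A [soil_db].
#' @param sink Output file path.
#' @param dialect `"json"` (default) or `"js-wrapped"`.
#' @param var_name Variable name used by the `js-wrapped` dialect.
#' @return `sink`, invisibly.
#' @export
write_reference_db <- function(db, sink, dialect = c("json", "js-wrapped"),
                               var_name = "reference_soils") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(db, "soil_db"))
  df <- as.data.frame(db)
  extra <- setdiff(names(df), c(soil_features(), "name", "category"))
  recs <- lapply(seq_len(nrow(df)), function(i) {
    rec <- list()
    for (f in soil_features()) rec[[.canonical_keys[[f]]]] <- df[[f]][i]
    if (!is.na(df$name[i])) rec[["Sample Name"]] <- df$name[i]
    if (!is.na(df$category[i])) rec[["Category"]] <- df$category[i]
    for (e in extra) if (!is.na(df[[e]][i])) rec[[e]] <- df[[e]][i]
    rec
  })
  # digits = I(17): 17 significant digits round-trip any double exactly
  json <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE)
  text <- if (dialect == "js-wrapped")
    sprintf("var %s = %s;\n", var_name, json) else paste0(json, "\n")
  ok <- tryCatch({ writeLines(text, sink, sep = ""); TRUE },
                 error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop(sprintf("cannot write '%s': %s", sink, conditionMessage(ok)),
         call. = FALSE)
  invisible(sink)
}
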