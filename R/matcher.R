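# Euclidean-distance computation, minimum-deviation reference search,
# and comparison normalization for display.

#' Extract the canonical feature vector of a sample or record
#'
#' Returns the eight numeric characteristics in canonical order
#' ([soil_features()]: RA, T2, T3, D250, Humus, pH, Clay, Sand), excluding
#' the name and category labels. Two records with equal numeric fields
#' yield equal vectors regardless of their names.
#'
#' @param x A [soil_sample], a one-row data frame (e.g. one row of a
#'   [soil_db]), a named list with the eight fields, or a bare numeric
#'   vector of length 8 already in canonical order.
#' @return A numeric vector of length 8.
#' @export
features_of <- function(x) {
  if (is.numeric(x)) {
    if (length(x) != 8L)
      stop("a bare feature vector must have exactly 8 entries",
           call. = FALSE)
    v <- unname(as.numeric(x))
  } else if (is.data.frame(x)) {
    if (nrow(x) != 1L)
      stop("expected a single record (one row)", call. = FALSE)
    miss <- setdiff(soil_features(), names(x))
    if (length(miss) > 0L)
      stop(sprintf("record is missing field(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    v <- as.numeric(x[1, soil_features()])
  } else if (is.list(x)) {
    miss <- setdiff(soil_features(), names(x))
    if (length(miss) > 0L)
      stop(sprintf("record is missing field(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    v <- vapply(soil_features(), function(f) as.numeric(x[[f]]), numeric(1))
    v <- unname(v)
  } else {
    stop("cannot extract features from this object", call. = FALSE)
  }
  if (any(!is.finite(v)))
    stop("feature vector contains non-finite values", call. = FALSE)
  v
}

#' Euclidean distance between feature vectors
#'
#' `d(p, q) = sqrt(sum_k (p_k - q_k)^2)`, the deviation measure minimized
#' by the reference search. Computed on raw feature values: units are
#' mixed (percent, optical-density units, pH units), so characteristics
#' with large numeric ranges dominate -- see the `standardize` option of
#' [find_reference()].
#'
#' @param p,q Feature vectors of equal length (anything accepted by
#'   [features_of()] of length 8, or bare numeric vectors of any common
#'   length).
#' @return Nonnegative distance.
#' @export
euclidean_distance <- function(p, q) {
  pv <- if (is.numeric(p)) as.numeric(p) else features_of(p)
  qv <- if (is.numeric(q)) as.numeric(q) else features_of(q)
  if (length(pv) != length(qv))
    stop(sprintf("dimension mismatch: %d vs %d", length(pv), length(qv)),
         call. = FALSE)
  sqrt(sum((pv - qv)^2))
}

#' Find the closest reference soil
#'
#' Scans the database for the record minimizing the Euclidean distance to
#' the query's feature vector, mirroring the minimum-deviation search: the
#' running minimum starts at infinity and is replaced only on a strictly
#' smaller distance, so ties are broken toward the LOWEST index.
#'
#' With `standardize = TRUE`, every coordinate of the database and the
#' query is first divided by that coordinate's standard deviation across
#' the database records, balancing the influence of characteristics with
#' very different numeric ranges. This is an extension, off by default:
#' the raw-value distance reproduces the published behaviour. A
#' zero-variance coordinate cannot be scaled and is dropped from the
#' distance with a warning.
#'
#' @param db A [soil_db].
#' @param query A query sample (anything accepted by [features_of()]).
#' @param standardize Scale coordinates by per-feature standard deviation
#'   before computing distances. Default `FALSE`.
#' @return An object of class `soil_match`: a list with `index` (1-based
#'   record position), `reference` (the matched record as a one-row data
#'   frame), `distance`, `normalized` (the [normalize_for_display()]
#'   table), `standardized` flag, and `query` (the echoed feature vector).
#' @examples
#' db <- soil_db(data.frame(
#'   ra = c(108.79, 101.09), t2 = c(90.78, 102.81), t3 = c(78.55, 86.81),
#'   d250 = c(0.25, 0.16), humus = c(0.38, 0.33), ph = c(8, 7.9),
#'   clay = c(6.7, 5.9), sand = c(90.4, 85.4), name = c("sand", "sand")))
#' find_reference(db, c(108.79, 90.78, 78.55, 0.25, 0.38, 8, 6.7, 90.4))
#' @export
find_reference <- function(db, query, standardize = FALSE) {
  stopifnot(inherits(db, "soil_db"))
  if (nrow(db) == 0L)
    stop("empty reference database", call. = FALSE)
  q <- features_of(query)
  X <- as.matrix(as.data.frame(db)[, soil_features()])
  keep <- rep(TRUE, ncol(X))
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    keep <- sds > 0
    if (!all(keep))
      warning(sprintf(
        "zero-variance coordinate(s) dropped from standardized distance: %s",
        paste(soil_features()[!keep], collapse = ", ")), call. = FALSE)
    X <- sweep(X[, keep, drop = FALSE], 2, sds[keep], "/")
    qs <- q[keep] / sds[keep]
  } else {
    qs <- q
  }
  d <- unname(sqrt(rowSums(sweep(X, 2, qs, "-")^2)))
  idx <- which.min(d)  # first minimum = strict '<' update rule
  ref <- as.data.frame(db)[idx, , drop = FALSE]
  rownames(ref) <- NULL
  structure(list(index = idx,
                 reference = ref,
                 distance = d[idx],
                 normalized = normalize_for_display(ref, q),
                 standardized = standardize,
                 query = q),
            class = "soil_match")
}

#' @export
print.soil_match <- function(x, ...) {
  nm <- x$reference$name
  cat(sprintf("<soil_match> reference #%d%s, distance %.6g%s\n",
              x$index,
              if (is.na(nm)) "" else sprintf(" '%s'", nm),
              x$distance,
              if (x$standardized) " (standardized coordinates)" else ""))
  print(x$normalized, row.names = FALSE)
  invisible(x)
}

#' Normalized side-by-side comparison table
#'
#' For charting, the matched reference and the query are brought onto one
#' scale with `y = y_i / y_max x 100%`, where `y_max` is the MATCHED
#' REFERENCE's value of each characteristic -- the standard sample's value
#' is taken as 100%. The percentage deviation from the standard is more
#' informative than the mixed-unit absolute values. When a reference
#' value is zero the ratio is undefined: that row keeps the absolute
#' values and is flagged `normalizable = FALSE`.
#'
#' @param reference The matched reference record (anything accepted by
#'   [features_of()]).
#' @param query The query sample.
#' @return A data frame with one row per characteristic: `characteristic`,
#'   absolute `reference` and `query` values, `reference_pct` (100 where
#'   normalizable), `query_pct`, and the `normalizable` flag.
#' @export
normalize_for_display <- function(reference, query) {
  r <- features_of(reference)
  q <- features_of(query)
  ok <- r != 0
  data.frame(
    characteristic = unname(.feature_labels[soil_features()]),
    reference = r,
    query = q,
    reference_pct = ifelse(ok, 100, r),
    query_pct = ifelse(ok, q / r * 100, q),
    normalizable = ok,
    stringsAsFactors = FALSE)
}
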