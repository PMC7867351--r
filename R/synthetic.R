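# Seeded generator of synthetic reference databases. The real 51-sample
# standard-soil collection is not published beyond its structure and
# per-feature ranges; the generator emulates that stated world so the
# matcher and reports can be exercised and tested.

#' Default per-feature ranges of the synthetic generator
#'
#' Closed intervals bounding every generated value. All but sand come
#' from the reported spread of the 51-sample collection: RA 95--155%
#' (no inhibition below 95%, activation up to 155%), T2 49--103%,
#' T3 22--100%, D250 0.16--1.59 OD units, humus 0.37--8.50%, pH (KCl)
#' 5.45--8.00, physical clay 8.6--47.5%. No sand range is reported;
#' 8--92% brackets the printed example values (81.7--90.4%) at the sandy
#' end while leaving room for heavy loams at the other.
#'
#' @return Named list of `c(lower, upper)` ranges, one per feature.
#' @export
default_feature_ranges <- function() {
  list(ra = c(95, 155), t2 = c(49, 103), t3 = c(22, 100),
       d250 = c(0.16, 1.59), humus = c(0.37, 8.50), ph = c(5.45, 8.00),
       clay = c(8.6, 47.5), sand = c(8, 92))
}

#' Configuration for the synthetic reference-database generator
#'
#' Defaults mirror the structure of the real collection: 17 type
#' categories of 3 replicate reference examples each, i.e. 51 records.
#'
#' @param n_categories Number of soil type categories (default 17).
#' @param replicates Reference examples per category (default 3).
#' @param seed Integer random seed; equal seeds give bit-identical
#'   databases.
#' @param ranges Per-feature closed intervals; see
#'   [default_feature_ranges()].
#' @param texture_gradient Enable the qualitative field correlations:
#'   heavier (clayier) soils give more concentrated extracts (higher
#'   D250) and, together with high humus, inhibit the luminescent systems
#'   more (lower T2/T3); sandier soils have lower clay. Default `TRUE`.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_categories = 17L, replicates = 3L, seed = 1L,
                             ranges = default_feature_ranges(),
                             texture_gradient = TRUE) {
  n_categories <- as.integer(n_categories)
  replicates <- as.integer(replicates)
  if (is.na(n_categories) || n_categories < 1L)
    stop("n_categories must be >= 1", call. = FALSE)
  if (is.na(replicates) || replicates < 1L)
    stop("replicates must be >= 1", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single integer", call. = FALSE)
  miss <- setdiff(soil_features(), names(ranges))
  if (length(miss) > 0L)
    stop(sprintf("ranges is missing feature(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  for (f in soil_features()) {
    r <- ranges[[f]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop(sprintf("range for '%s' must be c(lower, upper) with lower <= upper",
                   f), call. = FALSE)
  }
  structure(list(n_categories = n_categories, replicates = replicates,
                 seed = as.integer(seed), ranges = ranges[soil_features()],
                 texture_gradient = isTRUE(texture_gradient)),
            class = "generator_config")
}

.clip <- function(x, r) pmin(pmax(x, r[1]), r[2])

# Position of x inside range r on [0, 1]; 0.5 for a degenerate range.
.range_norm <- function(x, r) {
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else rep(0.5, length(x))
}

#' Generate a synthetic reference soil database
#'
#' Draws `n_categories` category-level centers and `replicates` records
#' around each. Each category takes its clay center uniformly from the
#' clay range and its humus center from one of three tiers (low / mid /
#' high, cycled across categories) echoing stepped organic-matter
#' increments. With `texture_gradient` on, D250 rises with the clay
#' center, T2 and T3 fall with a clay-plus-humus severity score, and sand
#' falls with clay -- all with small jitter, so the correlations hold at
#' the category-center level. Replicates add uniform within-category
#' noise of half-width 5% of each feature's range. Every value is clipped
#' to its configured range, so range conformance holds by construction.
#' Identical seeds yield bit-identical databases; the caller's RNG state
#' is left untouched.
#'
#' @param cfg A [generator_config] (default configuration if omitted).
#' @return A [soil_db] of `n_categories x replicates` records with
#'   systematic category labels (texture class + humus tier), `source`
#'   `"synthetic"`.
#' @examples
#' db <- generate_reference_db(generator_config(seed = 42))
#' n_records(db)  # 51
#' @export
generate_reference_db <- function(cfg = generator_config()) {
  if (!inherits(cfg, "generator_config"))
    stop("cfg must be a generator_config", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  rg <- cfg$ranges
  nc <- cfg$n_categories
  span <- function(f) rg[[f]][2] - rg[[f]][1]
  jit <- function(f) stats::runif(nc, -0.05, 0.05) * span(f)

  clay_c <- stats::runif(nc, rg$clay[1], rg$clay[2])
  clay_n <- .range_norm(clay_c, rg$clay)

  # humus tiers occupy the lower/middle/upper parts of the humus range,
  # echoing stepped ~1% / ~3% / ~5% organic-matter increments
  tiers <- rep(c("low", "mid", "high"), length.out = nc)
  tier_frac <- list(low = c(0.00, 0.20), mid = c(0.25, 0.55),
                    high = c(0.60, 1.00))
  humus_c <- vapply(seq_len(nc), function(i) {
    fr <- tier_frac[[tiers[i]]]
    stats::runif(1, rg$humus[1] + fr[1] * span("humus"),
                 rg$humus[1] + fr[2] * span("humus"))
  }, numeric(1))
  humus_n <- .range_norm(humus_c, rg$humus)

  if (cfg$texture_gradient) {
    sev <- 0.6 * clay_n + 0.4 * humus_n  # inhibition severity, in [0, 1]
    d250_c <- .clip(rg$d250[1] + clay_n * span("d250") + jit("d250"), rg$d250)
    t3_c <- .clip(rg$t3[2] - sev * span("t3") + jit("t3"), rg$t3)
    t2_c <- .clip(rg$t2[2] - 0.85 * sev * span("t2") + jit("t2"), rg$t2)
    sand_c <- .clip(rg$sand[2] - clay_n * span("sand") + jit("sand"), rg$sand)
  } else {
    d250_c <- stats::runif(nc, rg$d250[1], rg$d250[2])
    t3_c <- stats::runif(nc, rg$t3[1], rg$t3[2])
    t2_c <- stats::runif(nc, rg$t2[1], rg$t2[2])
    sand_c <- stats::runif(nc, rg$sand[1], rg$sand[2])
  }
  ra_c <- stats::runif(nc, rg$ra[1], rg$ra[2])
  ph_c <- stats::runif(nc, rg$ph[1], rg$ph[2])

  centers <- data.frame(ra = ra_c, t2 = t2_c, t3 = t3_c, d250 = d250_c,
                        humus = humus_c, ph = ph_c, clay = clay_c,
                        sand = sand_c)
  tex <- texture_class(clay_c)
  cat_label <- sprintf("C%02d %s / %s humus", seq_len(nc), tex, tiers)

  nrep <- cfg$replicates
  rows <- vector("list", nc)
  for (i in seq_len(nc)) {
    rec <- lapply(soil_features(), function(f) {
      noise <- stats::runif(nrep, -0.05, 0.05) * span(f)
      .clip(centers[[f]][i] + noise, rg[[f]])
    })
    names(rec) <- soil_features()
    rec$name <- rep(tex[i], nrep)
    rec$category <- rep(cat_label[i], nrep)
    rows[[i]] <- as.data.frame(rec, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  db <- soil_db(df, source = "synthetic")
  attr(db, "centers") <- centers
  db
}

#' Summarize a reference database
#'
#' Per-feature minimum, maximum and mean, plus record counts per category
#' (falling back to the sample name where no category label is stored).
#'
#' @param db A [soil_db].
#' @return An object of class `soil_db_summary`: a list with `n_records`,
#'   a `features` data frame (feature, min, max, mean), and a `categories`
#'   table whose counts sum to the record count.
#' @export
summarize_db <- function(db) {
  stopifnot(inherits(db, "soil_db"))
  if (nrow(db) == 0L) stop("empty reference database", call. = FALSE)
  df <- as.data.frame(db)
  feats <- data.frame(
    feature = unname(.feature_labels[soil_features()]),
    min = vapply(soil_features(), function(f) min(df[[f]]), numeric(1)),
    max = vapply(soil_features(), function(f) max(df[[f]]), numeric(1)),
    mean = vapply(soil_features(), function(f) mean(df[[f]]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(feats) <- NULL
  cat_col <- ifelse(is.na(df$category),
                    ifelse(is.na(df$name), "(unlabelled)", df$name),
                    df$category)
  structure(list(n_records = nrow(df), features = feats,
                 categories = table(cat_col, dnn = NULL)),
            class = "soil_db_summary")
}

#' @export
print.soil_db_summary <- function(x, ...) {
  cat(sprintf("<soil_db_summary> %d record(s), %d categor(ies)\n",
              x$n_records, length(x$categories)))
  print(x$features, row.names = FALSE)
  cat("category counts:\n")
  print(x$categories)
  invisible(x)
}
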