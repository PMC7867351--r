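# Shared fixtures, built in code. The four-record example database is the
# printed example of the reference file format; it doubles as the
# worked-example fixture for the matcher.

example4_df <- function() {
  data.frame(
    ra = c(108.79, 101.09, 101.09, 104.95),
    t2 = c(90.78, 102.81, 98.46, 101.59),
    t3 = c(78.55, 86.81, 71.99, 71.93),
    d250 = c(0.25, 0.16, 0.25, 0.48),
    humus = c(0.38, 0.33, 0.31, 0.55),
    ph = c(8, 7.9, 8, 5.3),
    clay = c(6.7, 5.9, 6.3, 8.5),
    sand = c(90.4, 85.4, 88.7, 81.7),
    name = c("sand", "sand", "sand", "light loam"),
    stringsAsFactors = FALSE)
}

example4_db <- function() soil_db(example4_df(), source = "example4")

example4_path <- function() {
  system.file("extdata", "example_reference_soils.json",
              package = "soilmatch")
}

# A random but valid database with features drawn inside the default
# generator ranges. Not the synthetic generator: kept independent so the
# matcher oracle tests do not depend on generator structure.
random_db <- function(n) {
  rg <- default_feature_ranges()
  df <- as.data.frame(lapply(rg, function(r) runif(n, r[1], r[2])))
  soil_db(df, source = "random")
}

random_query <- function() {
  rg <- default_feature_ranges()
  vapply(rg, function(r) runif(1, r[1], r[2]), numeric(1))
}

# Independent exhaustive scan mirroring the flowchart literally:
# running minimum starts at +Inf, replaced only on strictly smaller
# distance (ties keep the earliest index).
brute_force_match <- function(db, q) {
  qv <- features_of(q)
  X <- as.data.frame(db)[, soil_features()]
  best <- Inf
  idx <- NA_integer_
  for (i in seq_len(nrow(X))) {
    d <- sqrt(sum((as.numeric(X[i, ]) - qv)^2))
    if (d < best) {
      best <- d
      idx <- i
    }
  }
  list(index = idx, distance = best)
}
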