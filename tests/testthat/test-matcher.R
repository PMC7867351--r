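test_that("features_of extracts the canonical eight-feature vector", {
  db <- example4_db()
  expect_equal(features_of(db[1, , drop = FALSE]),
               c(108.79, 90.78, 78.55, 0.25, 0.38, 8, 6.7, 90.4))
  # name excluded: equal numerics with different names give equal vectors
  a <- soil_sample(1, 2, 3, 0.4, 5, 6, 7, 8, name = "a")
  b <- soil_sample(1, 2, 3, 0.4, 5, 6, 7, 8, name = "b")
  expect_identical(features_of(a), features_of(b))
  expect_error(features_of(list(ra = 1, t2 = 2)), "missing field")
  expect_error(features_of(c(1, 2, 3)), "exactly 8")
})

test_that("euclidean_distance matches hand-computed values", {
  r1 <- features_of(example4_db()[1, , drop = FALSE])
  expect_equal(euclidean_distance(r1, r1), 0)
  expect_equal(euclidean_distance(c(0, 0, 0, 0, 0, 0, 0, 0),
                                  c(3, 4, 0, 0, 0, 0, 0, 0)), 5)
  # frozen term-by-term hand evaluation for example rows 1 and 2:
  # sum of squares 297.8991, sqrt = 17.25975376...
  r2 <- features_of(example4_db()[2, , drop = FALSE])
  expect_equal(euclidean_distance(r1, r2), sqrt(297.8991),
               tolerance = 1e-12)
  expect_equal(euclidean_distance(r1, r2), 17.2597537642, tolerance = 1e-9)
  expect_error(euclidean_distance(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("euclidean_distance satisfies the metric axioms", {
  set.seed(99)
  for (rep in 1:1000) {
    p <- runif(8, -50, 150)
    q <- runif(8, -50, 150)
    r <- runif(8, -50, 150)
    dpq <- euclidean_distance(p, q)
    expect_gte(dpq, 0)
    expect_equal(dpq, euclidean_distance(q, p))
    expect_lte(euclidean_distance(p, r), dpq + euclidean_distance(q, r) + 1e-9)
  }
  expect_equal(euclidean_distance(c(1:8), c(1:8)), 0)
})

test_that("find_reference returns each record as its own best match", {
  db <- example4_db()
  for (i in seq_len(n_records(db))) {
    m <- find_reference(db, db_record(db, i))
    expect_equal(m$distance, 0)
    # rows 2 and 3 share no feature vector, so self-match index is exact
    expect_equal(m$index, i)
  }
})

test_that("ties break to the lowest index (strict-< update rule)", {
  df <- example4_df()[c(1, 2, 1, 3), ]
  db <- soil_db(df)
  m <- find_reference(db, db_record(db, 3))
  expect_equal(m$index, 1L)
  expect_equal(m$distance, 0)
})

test_that("a perturbed query still matches its reference (hand oracle)", {
  db <- example4_db()
  q <- c(109.0, 90.78, 78.55, 0.25, 0.38, 8, 6.7, 90.4)  # row 1, RA +0.21
  m <- find_reference(db, q)
  expect_equal(m$reference$name, "sand")
  expect_equal(m$index, 1L)
  expect_equal(m$distance, 0.21, tolerance = 1e-12)
  bf <- brute_force_match(db, q)
  expect_equal(m$index, bf$index)
  expect_equal(m$distance, bf$distance)
})

test_that("find_reference agrees with the exhaustive-scan oracle", {
  set.seed(123)
  for (rep in 1:40) {
    db <- random_db(sample(1:100, 1))
    for (j in 1:5) {
      q <- random_query()
      m <- find_reference(db, q)
      bf <- brute_force_match(db, q)
      expect_identical(m$index, bf$index)
      expect_equal(m$distance, bf$distance, tolerance = 1e-12)
    }
  }
})

test_that("permuting records permutes a unique matched index", {
  set.seed(5)
  for (rep in 1:20) {
    db <- random_db(20)
    q <- random_query()
    m <- find_reference(db, q)
    X <- as.data.frame(db)[, soil_features()]
    d <- apply(X, 1, function(r) euclidean_distance(as.numeric(r), q))
    if (sum(abs(d - min(d)) < 1e-12) > 1L) next  # only unique minima
    perm <- sample(nrow(db))
    db_p <- soil_db(as.data.frame(db)[perm, ])
    m_p <- find_reference(db_p, q)
    expect_equal(m_p$index, which(perm == m$index))
  }
})

test_that("standardize scales by per-feature sd and drops zero variance", {
  db <- example4_db()
  q <- features_of(db_record(db, 1))
  expect_equal(find_reference(db, q, standardize = TRUE)$distance, 0)
  # zero-variance coordinate: all equal ra
  df3 <- example4_df()
  df3$ra <- 100
  db3 <- soil_db(df3)
  expect_warning(find_reference(db3, q, standardize = TRUE),
                 "zero-variance.*ra")
})

test_that("normalize_for_display takes the reference value as 100%", {
  db <- example4_db()
  r1 <- db_record(db, 1)
  tab <- normalize_for_display(r1, r1)
  expect_true(all(tab$reference_pct == 100))
  expect_true(all(tab$query_pct == 100))
  expect_true(all(tab$normalizable))
  # D250: reference 0.25, query 0.50 -> 200%
  q <- features_of(r1)
  q[4] <- 0.50
  tab2 <- normalize_for_display(r1, q)
  expect_equal(tab2$query_pct[tab2$characteristic == "D250"], 200)
  # zero reference value: absolute values kept, flagged not normalizable
  z <- soil_sample(100, 90, 80, 0.2, 0, 7, 10, 50)
  tab3 <- normalize_for_display(z, features_of(r1))
  hrow <- tab3[tab3$characteristic == "Humus", ]
  expect_false(hrow$normalizable)
  expect_equal(hrow$reference_pct, 0)
  expect_equal(hrow$query_pct, 0.38)
})
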