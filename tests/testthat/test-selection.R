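test_that("symmetric uncertainty matches hand and oracle values", {
  expect_equal(symmetric_uncertainty(c(0, 0, 1, 1), c("a", "a", "b", "b")),
               1)
  expect_equal(symmetric_uncertainty(c(0, 1, 0, 1), c("a", "a", "b", "b")),
               0)
  # H(f) = 0.8113, H(C) = 1, H(C|f) = 0.6887 -> SU = 0.3437
  su <- symmetric_uncertainty(c(0, 0, 0, 1), c("a", "a", "b", "b"))
  expect_equal(round(su, 4), 0.3437)
  expect_equal(su, oracle_su(c(0, 0, 0, 1), c("a", "a", "b", "b")),
               tolerance = 1e-12)
  # degenerate: both variables constant
  expect_equal(symmetric_uncertainty(c(1, 1), c("a", "a")), 0)
})

test_that("SU is symmetric, bounded, and measured in bits", {
  set.seed(23)
  for (i in 1:30) {
    f <- sample(1:4, 40, replace = TRUE)
    y <- sample(c("I", "II", "III", "IV"), 40, replace = TRUE)
    su <- symmetric_uncertainty(f, y)
    expect_gte(su, 0)
    expect_lte(su, 1)
    expect_equal(su, symmetric_uncertainty(y, f), tolerance = 1e-12)
    expect_equal(su, oracle_su(f, y), tolerance = 1e-12)
  }
  # bijective relabelling gives SU = 1
  f <- rep(1:4, each = 5)
  y <- rep(c("IV", "II", "I", "III"), each = 5)
  expect_equal(symmetric_uncertainty(f, y), 1)
  # entropy of a uniform 4-class variable is exactly 2 bits
  expect_equal(dnajtype:::entropy_counts(rep(10, 4)), 2)
})

test_that("MDL discretization finds forced cuts and collapses noise", {
  # perfectly separating threshold -> exactly 2 bins split at the class
  # boundary
  v <- c(1:6, 101:106)
  y <- rep(c("a", "b"), each = 6)
  bins <- discretize_feature(v, y)
  expect_equal(length(unique(bins)), 2)
  expect_true(all(bins[1:6] == bins[1]) && all(bins[7:12] == bins[7]))
  expect_true(bins[1] != bins[7])

  # constant feature -> a single bin
  expect_equal(unique(discretize_feature(rep(3.3, 10),
                                         rep(c("a", "b"), 5))), 1L)

  # informative cut position agrees with the exhaustive-search oracle
  set.seed(29)
  v <- c(rnorm(6, 0, 0.3), rnorm(6, 5, 0.3))
  y <- rep(c("a", "b"), each = 6)
  cut <- oracle_best_cut(v, y)
  bins <- discretize_feature(v, y)
  expect_equal(unname(bins), unname(1L + as.integer(v > cut)))

  # equal-frequency fallback gives the requested granularity
  bins <- discretize_feature(seq_len(100), rep(c("a", "b"), 50),
                             method = "eqfreq", bins = 10)
  expect_equal(length(unique(bins)), 10)
})

test_that("feature ranking orders by decreasing SU with stable ties", {
  set.seed(31)
  y <- rep(c("I", "II"), each = 10)
  x <- cbind(rnorm(20), as.numeric(factor(y)), rnorm(20))
  rk <- rank_features(x, y)
  expect_equal(rk$order[1], 2)
  expect_equal(rk$su_scores[1], 1)
  expect_true(all(diff(rk$su_scores) <= 1e-12))

  # identical columns stay in original-index order
  x2 <- cbind(a = x[, 2], b = rnorm(20), c = x[, 2])
  rk2 <- rank_features(x2, y)
  expect_equal(rk2$order[1:2], c(1, 3))

  # oracle re-ranking of a 10-feature fixture
  x3 <- matrix(rnorm(200), 20, 10)
  x3[, 4] <- x3[, 4] + 3 * (y == "I")
  x3[, 8] <- x3[, 8] + 1.5 * (y == "I")
  rk3 <- rank_features(x3, y)
  su_oracle <- vapply(seq_len(10), function(j) {
    oracle_su(discretize_feature(x3[, j], y), y)
  }, numeric(1))
  expect_equal(rk3$order, order(-su_oracle, seq_len(10)))
  expect_equal(rk3$su_scores, su_oracle[rk3$order], tolerance = 1e-12)
})

test_that("incremental selection returns the smallest best prefix", {
  rk <- structure(list(order = 1:10, su_scores = seq(1, 0.1, by = -0.1),
                       feature_names = NULL),
                  class = "ranked_features")
  ifs <- incremental_feature_selection(rk, function(idx) length(idx) %% 3)
  expect_equal(ifs$sizes, 1:10)
  expect_length(ifs$curve, 10)
  expect_equal(ifs$best_size, 2) # scores 1,2,0,1,2,... -> first argmax
  expect_equal(ifs$best_features, 1:2)
  expect_error(incremental_feature_selection(rk, length, step = 0),
               "positive")
  # a larger step still evaluates the full set
  ifs2 <- incremental_feature_selection(rk, length, step = 4)
  expect_equal(ifs2$sizes, c(4, 8, 10))
})

test_that("IFS recovers a small planted informative feature set", {
  set.seed(37)
  n_per <- 30
  y <- rep(c("I", "II", "III", "IV"), each = n_per)
  x <- matrix(rnorm(120 * 30), 120, 30)
  shifts <- matrix(rnorm(4 * 5, sd = 2), 4, 5)
  for (j in 1:5) x[, j] <- x[, j] + shifts[as.integer(factor(y)), j]
  colnames(x) <- paste0("f", 1:30)

  rk <- rank_features(x, y)
  expect_true(all(rk$order[1:5] %in% 1:5)) # planted features rank first

  ifs <- incremental_feature_selection(
    rk, evaluator_centroid(x, y, n_folds = 3, seed = 3))
  expect_gte(ifs$best_size, 3)
  expect_lte(ifs$best_size, 10) # peak in the neighbourhood of the 5 planted
  expect_gte(ifs$best_score, max(ifs$curve) - 1e-12)
})
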