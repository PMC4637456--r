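# Small separable fixture shared by the training tests: 4 classes with
# distinct means in 8 dimensions, majority class III.
make_toy_training <- function(seed = 41, n = c(I = 10, II = 10, III = 40,
                                               IV = 6)) {
  set.seed(seed)
  y <- factor(rep(names(n), times = n), levels = c("I", "II", "III", "IV"))
  centers <- matrix(rnorm(4 * 8, sd = 3), 4, 8)
  x <- centers[as.integer(y), ] + matrix(rnorm(length(y) * 8), ncol = 8)
  colnames(x) <- paste0("f", 1:8)
  list(x = x, y = y)
}

test_that("SMOTE expands a 20-row class to 60 keeping the originals", {
  set.seed(43)
  x <- matrix(rnorm(20 * 5), 20, 5)
  out <- smote_expand(x, 60, k = 5, seed = 7)
  expect_equal(nrow(out), 60)
  expect_equal(unname(out[1:20, ]), unname(x))

  # every synthetic row lies on a segment between two real rows
  for (i in 21:60) {
    dmin <- min(apply(utils::combn(20, 2), 2, function(pr) {
      point_segment_distance(out[i, ], x[pr[1], ], x[pr[2], ])
    }))
    expect_lt(dmin, 1e-9)
  }

  # determinism and no-op cases
  expect_equal(smote_expand(x, 60, k = 5, seed = 7), out)
  expect_equal(unname(smote_expand(x, 20, seed = 1)), unname(x))
  two <- matrix(rep(c(1, 2, 3), 2), 2, 3, byrow = TRUE)
  four <- smote_expand(two, 4, k = 1, seed = 1)
  expect_true(all(apply(four, 1, function(r) all(r == c(1, 2, 3)))))
})

test_that("SMOTE validates its inputs and clips k", {
  x <- matrix(rnorm(12), 4, 3)
  expect_error(smote_expand(x, 3, seed = 1), "below the current")
  expect_error(smote_expand(x[1, , drop = FALSE], 5, seed = 1),
               "at least 2")
  expect_warning(smote_expand(x, 8, k = 10, seed = 1), "clipped to 3")
})

test_that("majority partition is a near-equal random split", {
  parts <- partition_majority(955, 20, seed = 3)
  sizes <- lengths(parts)
  expect_equal(sort(unname(sizes), decreasing = TRUE),
               c(rep(48, 15), rep(47, 5)))
  expect_equal(unname(sort(unlist(parts))), 1:955)

  parts2 <- partition_majority(40, 20, seed = 3)
  expect_true(all(lengths(parts2) == 2))
  expect_equal(partition_majority(955, 20, seed = 3), parts)
  expect_error(partition_majority(10, 20), "cannot split")
})

test_that("subdatasets combine all minority rows with one majority subpart", {
  y <- rep(c("I", "II", "III", "IV"), times = c(57, 50, 955, 54))
  x <- matrix(rnorm(length(y) * 3), ncol = 3)
  subs <- build_subdatasets(x, y, ensemble_config(n_subsets = 20), seed = 5)
  expect_length(subs, 20)
  for (s in subs) {
    tab <- table(s$y)
    expect_equal(as.integer(tab[c("I", "II", "IV")]), c(57L, 50L, 54L))
    expect_true(tab[["III"]] %in% c(47, 48))
    expect_true(all(c("I", "II", "III", "IV") %in% names(tab[tab > 0])))
  }
  # across subdatasets, the majority subparts partition the majority rows
  expect_equal(sum(vapply(subs, function(s) sum(s$y == "III"),
                          numeric(1))), 955)

  # degenerate single subset is the whole training set
  one <- build_subdatasets(x, y, ensemble_config(n_subsets = 1), seed = 5)
  expect_equal(nrow(one[[1]]$x), length(y))

  yf <- factor(y, levels = c("I", "II", "III", "IV"))
  expect_error(build_subdatasets(x[y != "IV", ], yf[y != "IV"]),
               "absent")
})

test_that("the learner cycle is assigned round-robin", {
  toy <- make_toy_training()
  cfg <- ensemble_config(n_subsets = 20, smote_target = 12, smote_k = 3,
                         rf_ntree = 25, rbf_centers = 5, seed = 2)
  fit <- dnaj_ensemble(toy$x, toy$y, cfg)
  expect_s3_class(fit, "dnaj_ensemble")
  expect_length(fit$subclassifiers, 20)
  expect_equal(as.integer(table(fit$learners)[c("rbf-network",
                                                "random-forest",
                                                "naive-bayes",
                                                "logistic-regression")]),
               rep(5L, 4))
  expect_equal(dim(fit$class_centroids), c(4L, 8L))

  cfg1 <- ensemble_config(n_subsets = 1, learner_cycle = "naive-bayes",
                          smote_target = 12, smote_k = 3, seed = 2)
  fit1 <- dnaj_ensemble(toy$x, toy$y, cfg1)
  expect_equal(fit1$learners, "naive-bayes")
  expect_error(ensemble_config(learner_cycle = "svm"), "unknown learner")
})

test_that("vote tallies sum to the subclassifier count and are deterministic", {
  toy <- make_toy_training()
  cfg <- ensemble_config(n_subsets = 8, smote_target = 12, smote_k = 3,
                         rf_ntree = 25, rbf_centers = 5, seed = 2)
  fit <- dnaj_ensemble(toy$x, toy$y, cfg)
  v <- predict(fit, toy$x, type = "votes")
  expect_true(all(rowSums(v) == 8))
  expect_equal(dim(v), c(nrow(toy$x), 4L))

  # retraining with the same seed reproduces the predictions exactly
  fit2 <- dnaj_ensemble(toy$x, toy$y, cfg)
  expect_equal(predict(fit2, toy$x), predict(fit, toy$x))
  expect_equal(predict(fit2, toy$x, type = "votes"), v)

  # the separable toy problem is learned essentially perfectly
  expect_gte(mean(predict(fit, toy$x) == toy$y), 0.9)
})

test_that("top-vote ties break towards the nearest class centroid", {
  votes <- matrix(c(8, 4, 8, 0), 1, 4,
                  dimnames = list(NULL, c("I", "II", "III", "IV")))
  centroids <- rbind(I = c(0, 0), II = c(5, 5), III = c(3, 0),
                     IV = c(9, 9))
  # query at (1, 0): distance 1 to centroid I, 2 to the tied III -> I
  expect_equal(dnajtype:::resolve_votes(votes, matrix(c(1, 0), 1, 2),
                                        centroids), "I")
  # query nearer III flips the tie the other way
  expect_equal(dnajtype:::resolve_votes(votes, matrix(c(2.9, 0), 1, 2),
                                        centroids), "III")
  # unanimity needs no tie-break
  una <- matrix(c(0, 0, 20, 0), 1, 4,
                dimnames = list(NULL, c("I", "II", "III", "IV")))
  expect_equal(dnajtype:::resolve_votes(una, matrix(c(9, 9), 1, 2),
                                        centroids), "III")
})

test_that("feature selection restricts training and prediction columns", {
  toy <- make_toy_training()
  cfg <- ensemble_config(n_subsets = 4, smote_target = 12, smote_k = 3,
                         rf_ntree = 25, seed = 2)
  fit <- dnaj_ensemble(toy$x, toy$y, cfg, features = 1:5)
  expect_length(fit$feature_names, 5)
  # full-width and pre-subset inputs both predict
  p1 <- predict(fit, toy$x)
  p2 <- predict(fit, toy$x[, 1:5])
  expect_equal(p1, p2)
  expect_error(predict(fit, toy$x[, 1:3]), "expects")
})
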