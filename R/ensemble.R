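# Imbalance-aware ensemble: SMOTE expansion of the rarest class, 20-way
# undersampling of the majority class, and 20 heterogeneous one-versus-rest
# subclassifiers combined by majority vote with nearest-centroid
# tie-breaking.

#' Ensemble configuration
#'
#' @param n_subsets number of majority-class subparts / subclassifiers
#'   (default 20).
#' @param smote_target size the rarest class is expanded to by SMOTE
#'   (default 60, i.e. a 20-sequence type IV class tripled).
#' @param smote_k number of nearest neighbours SMOTE interpolates towards
#'   (default 5; clipped with a warning when the class is smaller).
#' @param learner_cycle learner families assigned to subclassifiers
#'   round-robin; defaults to RBF network, random forest, naive Bayes and
#'   logistic regression (five subclassifiers of each at `n_subsets = 20`).
#' @param seed integer seed from which all training randomness (SMOTE,
#'   majority partition, learner seeds) is derived.
#' @param smote_scope `"paper_faithful_pre_cv"` expands the rarest class once,
#'   before cross-validation folds are drawn (synthetic sequences then also
#'   appear in test folds); `"train_fold_only"` expands inside each training
#'   fold only, avoiding oversampling leakage into test folds.
#' @param rf_ntree trees per random-forest subclassifier.
#' @param rbf_centers Gaussian kernel centres of the RBF network.
#' @return an object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_subsets = 20, smote_target = 60, smote_k = 5,
                            learner_cycle = c("rbf-network", "random-forest",
                                              "naive-bayes",
                                              "logistic-regression"),
                            seed = 1,
                            smote_scope = c("paper_faithful_pre_cv",
                                            "train_fold_only"),
                            rf_ntree = 200, rbf_centers = 10) {
  smote_scope <- match.arg(smote_scope)
  stopifnot(n_subsets >= 1, length(learner_cycle) >= 1)
  known <- c("rbf-network", "random-forest", "naive-bayes",
             "logistic-regression")
  bad <- setdiff(learner_cycle, known)
  if (length(bad) > 0) {
    stop("unknown learner id(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_subsets = as.integer(n_subsets),
                 smote_target = as.integer(smote_target),
                 smote_k = as.integer(smote_k),
                 learner_cycle = learner_cycle,
                 seed = as.integer(seed), smote_scope = smote_scope,
                 rf_ntree = as.integer(rf_ntree),
                 rbf_centers = as.integer(rbf_centers)),
            class = "ensemble_config")
}

#' SMOTE oversampling of a minority class
#'
#' Expands a block of same-class feature rows to `target_count` rows: the
#' originals are kept, and each synthetic row is generated by picking a real
#' row, one of its `k` nearest same-class neighbours (Euclidean), and a
#' uniform point on the segment between them
#' (`row + u * (neighbour - row)`, `u ~ U[0, 1]`).
#'
#' @param minority_rows numeric matrix of minority-class feature rows
#'   (at least 2).
#' @param target_count desired number of rows (at least `nrow`).
#' @param k neighbour count (clipped to `nrow - 1` with a warning).
#' @param seed RNG seed; output is deterministic given the seed.
#' @return matrix of `target_count` rows, the originals first.
#' @export
smote_expand <- function(minority_rows, target_count, k = 5, seed = 1) {
  x <- as_feature_matrix(minority_rows)
  n <- nrow(x)
  if (n < 2) stop("SMOTE needs at least 2 minority rows", call. = FALSE)
  if (target_count < n) {
    stop("'target_count' (", target_count, ") is below the current class ",
         "size (", n, ")", call. = FALSE)
  }
  if (target_count == n) return(x)
  if (k > n - 1) {
    warning("k = ", k, " clipped to ", n - 1, " (class has ", n, " rows)",
            call. = FALSE)
    k <- n - 1
  }
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  nn <- matrix(nn, nrow = n)
  n_syn <- target_count - n
  syn <- with_seed(seed, {
    base <- sample.int(n, n_syn, replace = TRUE)
    pick <- sample.int(k, n_syn, replace = TRUE)
    u <- stats::runif(n_syn)
    x[base, , drop = FALSE] +
      u * (x[nn[cbind(base, pick)], , drop = FALSE] -
             x[base, , drop = FALSE])
  })
  out <- rbind(x, syn)
  rownames(out) <- c(rownames(x) %||% paste0("orig_", seq_len(n)),
                     paste0("syn_", seq_len(n_syn)))
  out
}

#' Partition majority-class rows into near-equal subparts
#'
#' Randomly permutes the rows under `seed` and splits them into `n_subsets`
#' contiguous groups whose sizes differ by at most 1 (larger groups first).
#'
#' @param majority_rows feature matrix, or a single integer row count.
#' @param n_subsets number of groups.
#' @param seed RNG seed for the permutation.
#' @return list of `n_subsets` integer vectors of row indices; the groups
#'   are disjoint and cover every row.
#' @export
partition_majority <- function(majority_rows, n_subsets, seed = 1) {
  n <- if (is.matrix(majority_rows) || is.data.frame(majority_rows)) {
    nrow(majority_rows)
  } else {
    as.integer(majority_rows)
  }
  if (n < n_subsets) {
    stop("cannot split ", n, " rows into ", n_subsets, " subparts",
         call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(n))
  base <- n %/% n_subsets
  extra <- n %% n_subsets
  sizes <- rep(base, n_subsets) + c(rep(1L, extra),
                                    rep(0L, n_subsets - extra))
  split(perm, rep(seq_len(n_subsets), times = sizes))
}

#' Build balanced subdatasets by majority undersampling
#'
#' Every subdataset contains all training rows of the three non-majority
#' classes (the rarest one already SMOTE-expanded upstream, per the
#' configured scope) plus one subpart of the majority class, so each of the
#' `n_subsets` subclassifiers sees a far more balanced class mixture than
#' the raw data while the ensemble as a whole uses every majority row.
#'
#' @param x training feature matrix.
#' @param y training class labels (all classes must be present).
#' @param config an [ensemble_config].
#' @param seed RNG seed for the majority partition.
#' @return list of `n_subsets` lists with elements `x`, `y`, `subpart_id`.
#' @export
build_subdatasets <- function(x, y, config = ensemble_config(), seed = 1) {
  x <- as_feature_matrix(x)
  y <- as.factor(y)
  counts <- table(y)
  if (any(counts == 0)) {
    stop("class(es) absent from training rows: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  majority <- names(counts)[which.max(counts)]
  maj_idx <- which(y == majority)
  min_idx <- which(y != majority)
  parts <- partition_majority(length(maj_idx), config$n_subsets, seed = seed)
  lapply(seq_along(parts), function(i) {
    idx <- c(min_idx, maj_idx[parts[[i]]])
    list(x = x[idx, , drop = FALSE], y = y[idx], subpart_id = i)
  })
}

# --- base learners -----------------------------------------------------

# Each learner is fit one-versus-rest: one binary scorer per class, class
# probabilities collected into a matrix, argmax at prediction.

fit_ovr <- function(x, y, fit_binary) {
  classes <- levels(y)
  models <- lapply(classes, function(cl) {
    fit_binary(x, factor(ifelse(y == cl, "pos", "neg"),
                         levels = c("neg", "pos")))
  })
  names(models) <- classes
  models
}

predict_ovr <- function(models, x, predict_prob) {
  probs <- vapply(models, function(m) predict_prob(m, x),
                  numeric(nrow(x)))
  probs <- matrix(probs, nrow = nrow(x),
                  dimnames = list(NULL, names(models)))
  colnames(probs)[max.col(probs, ties.method = "first")]
}

fit_subclassifier <- function(learner, x, y, seed, config) {
  y <- as.factor(y)
  model <- with_seed(seed, switch(
    learner,
    "random-forest" = fit_ovr(x, y, function(xx, yy) {
      randomForest::randomForest(xx, yy, ntree = config$rf_ntree)
    }),
    "naive-bayes" = fit_ovr(x, y, function(xx, yy) {
      m <- e1071::naiveBayes(as.data.frame(xx), yy)
      # floor class-conditional sds: zero-variance features in a small
      # subdataset otherwise give NaN densities
      m$tables <- lapply(m$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], 1e-6)
        tb
      })
      m
    }),
    "logistic-regression" = fit_ovr(x, y, fit_binary_logistic),
    "rbf-network" = fit_rbf_network(x, y, config$rbf_centers),
    stop("unknown learner id: ", learner, call. = FALSE)
  ))
  structure(list(learner = learner, model = model), class = "dnaj_sublearner")
}

predict_subclassifier <- function(sub, x) {
  switch(
    sub$learner,
    "random-forest" = predict_ovr(sub$model, x, function(m, xx) {
      stats::predict(m, xx, type = "prob")[, "pos"]
    }),
    "naive-bayes" = predict_ovr(sub$model, x, function(m, xx) {
      stats::predict(m, as.data.frame(xx), type = "raw")[, "pos"]
    }),
    "logistic-regression" = predict_ovr(sub$model, x,
                                        predict_binary_logistic),
    "rbf-network" = predict_rbf_network(sub$model, x)
  )
}

# Binary logistic regression via glm; rank deficiency and separation
# warnings are expected on small balanced subdatasets and are suppressed.
fit_binary_logistic <- function(x, y) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$.y <- y
  m <- suppressWarnings(stats::glm(.y ~ ., data = df, family =
                                     stats::binomial()))
  # strip heavy environments; keep what predict.glm needs
  m$data <- NULL
  m$model <- NULL
  m
}

predict_binary_logistic <- function(m, x) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  suppressWarnings(unname(stats::predict(m, newdata = df,
                                         type = "response")))
}

# RBF network: a Gaussian kernel feature layer over k-means centres followed
# by one-versus-rest logistic readouts.
fit_rbf_network <- function(x, y, n_centers) {
  ux <- unique(x)
  k <- min(n_centers, nrow(ux))
  centers <- if (k < 2) {
    matrix(colMeans(x), nrow = 1)
  } else {
    stats::kmeans(ux, centers = k, nstart = 1, iter.max = 30)$centers
  }
  dc <- stats::dist(centers)
  sigma <- if (length(dc) == 0 || stats::median(dc) == 0) 1 else
    stats::median(dc)
  phi <- rbf_layer(x, centers, sigma)
  list(centers = centers, sigma = sigma,
       readout = fit_ovr(phi, y, fit_binary_logistic))
}

rbf_layer <- function(x, centers, sigma) {
  phi <- vapply(seq_len(nrow(centers)), function(i) {
    exp(-rowSums(sweep(x, 2, centers[i, ])^2) / (2 * sigma^2))
  }, numeric(nrow(x)))
  matrix(phi, nrow = nrow(x))
}

predict_rbf_network <- function(m, x) {
  phi <- rbf_layer(x, m$centers, m$sigma)
  predict_ovr(m$readout, phi, predict_binary_logistic)
}

# --- the ensemble fitter ----------------------------------------------

#' Fit the imbalance-aware J-protein type ensemble
#'
#' The main fitting function. Optionally SMOTE-expands the rarest class to
#' `config$smote_target`, partitions the majority class into
#' `config$n_subsets` subparts, builds one balanced subdataset per subpart
#' (all non-majority rows + that subpart) and trains one subclassifier per
#' subdataset, cycling through the configured learner families. Prediction
#' is by majority vote over the subclassifiers; top-vote ties are resolved
#' towards the tied class whose training centroid is nearest (Euclidean) to
#' the query feature vector.
#'
#' @param x numeric feature matrix (rows = sequences), e.g. from
#'   [feature_matrix()].
#' @param y class labels (factor or character).
#' @param config an [ensemble_config]; all randomness derives from
#'   `config$seed`.
#' @param features optional vector of column indices (a ranked-prefix
#'   selection); the model trains and predicts on these columns only.
#' @param balance apply SMOTE expansion of the rarest class before building
#'   subdatasets (default `TRUE`; set `FALSE` when the rows are already
#'   expanded upstream, as in pre-CV scope cross-validation).
#' @return an object of class `dnaj_ensemble` with `predict`, `print` and
#'   `summary` methods.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(
#'   class_counts = c(I = 12, II = 12, III = 40, IV = 6),
#'   length_range = c(60, 90), seed = 7))
#' fm <- feature_matrix(sim, feature_config(lnc = 15, gamma_max = 2,
#'                                          lambda_max = 2))
#' fit <- dnaj_ensemble(fm, attr(fm, "labels"),
#'                      ensemble_config(n_subsets = 4, smote_target = 12,
#'                                      rf_ntree = 50))
#' table(predict(fit, fm))
dnaj_ensemble <- function(x, y, config = ensemble_config(), features = NULL,
                          balance = TRUE) {
  x <- as_feature_matrix(x)
  y <- as.factor(y)
  if (nrow(x) != length(y)) {
    stop("'x' and 'y' sizes do not match", call. = FALSE)
  }
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  seeds <- with_seed(config$seed,
                     sample.int(2^30, config$n_subsets + 2))
  if (balance) {
    ex <- expand_rarest(x, y, config, seed = seeds[config$n_subsets + 1])
    x <- ex$x
    y <- ex$y
  }
  subsets <- build_subdatasets(x, y, config,
                               seed = seeds[config$n_subsets + 2])
  learners <- rep_len(config$learner_cycle, config$n_subsets)
  subclassifiers <- lapply(seq_along(subsets), function(i) {
    fit_subclassifier(learners[i], subsets[[i]]$x, subsets[[i]]$y,
                      seed = seeds[i], config = config)
  })
  structure(list(subclassifiers = subclassifiers, learners = learners,
                 selected_features = features,
                 n_features = ncol(x),
                 feature_names = colnames(x),
                 class_centroids = centroid_matrix(x, y),
                 classes = levels(y), config = config),
            class = "dnaj_ensemble")
}

# SMOTE the rarest class up to the configured target (no-op when it is
# already at least that large); returns the augmented rows and labels.
expand_rarest <- function(x, y, config, seed) {
  counts <- table(y)
  rare <- names(counts)[which.min(counts)]
  if (counts[[rare]] >= config$smote_target || counts[[rare]] < 2) {
    return(list(x = x, y = y))
  }
  idx <- which(y == rare)
  expanded <- smote_expand(x[idx, , drop = FALSE], config$smote_target,
                           k = config$smote_k, seed = seed)
  n_syn <- nrow(expanded) - length(idx)
  list(x = rbind(x, expanded[-seq_along(idx), , drop = FALSE]),
       y = factor(c(as.character(y), rep(rare, n_syn)), levels = levels(y)))
}

#' Predict J-protein types with a fitted ensemble
#'
#' @param object a `dnaj_ensemble`.
#' @param newdata feature matrix; either the full-width matrix the model was
#'   fitted from (columns are subset by the stored selection) or a matrix
#'   already restricted to the selected features.
#' @param type `"class"` for the predicted labels, `"votes"` for the
#'   per-row vote tallies (rows sum to the number of subclassifiers).
#' @param ... unused.
#' @return factor of predicted classes, or an integer tally matrix.
#' @export
predict.dnaj_ensemble <- function(object, newdata,
                                  type = c("class", "votes"), ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata)
  p <- object$n_features
  if (ncol(x) != p) {
    if (!is.null(object$selected_features) &&
        max(object$selected_features) <= ncol(x)) {
      x <- x[, object$selected_features, drop = FALSE]
    } else {
      stop("newdata has ", ncol(x), " columns; model expects ", p,
           call. = FALSE)
    }
  }
  votes <- matrix(0L, nrow = nrow(x), ncol = length(object$classes),
                  dimnames = list(rownames(x), object$classes))
  for (sub in object$subclassifiers) {
    v <- predict_subclassifier(sub, x)
    votes[cbind(seq_len(nrow(x)), match(v, object$classes))] <-
      votes[cbind(seq_len(nrow(x)), match(v, object$classes))] + 1L
  }
  if (type == "votes") return(votes)
  factor(resolve_votes(votes, x, object$class_centroids),
         levels = object$classes)
}

# Majority vote with nearest-centroid tie-breaking among top-vote classes.
resolve_votes <- function(votes, x, centroids) {
  vapply(seq_len(nrow(votes)), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) == 1) return(colnames(votes)[top])
    tied <- colnames(votes)[top]
    d <- vapply(tied, function(cl) {
      sum((x[i, ] - centroids[cl, ])^2)
    }, numeric(1))
    tied[which.min(d)]
  }, character(1))
}

#' @export
print.dnaj_ensemble <- function(x, ...) {
  cat("J-protein type ensemble:", length(x$subclassifiers),
      "subclassifiers\n")
  tab <- table(x$learners)
  cat("  learners:", paste(names(tab), tab, sep = " x ", collapse = ", "),
      "\n")
  cat("  features:", x$n_features,
      if (is.null(x$selected_features)) "(all)" else "(selected prefix)",
      "\n")
  invisible(x)
}

#' @export
summary.dnaj_ensemble <- function(object, ...) {
  structure(list(n_subclassifiers = length(object$subclassifiers),
                 learner_counts = table(object$learners),
                 n_features = object$n_features,
                 selected = !is.null(object$selected_features),
                 classes = object$classes,
                 config = object$config),
            class = "summary.dnaj_ensemble")
}

#' @export
print.summary.dnaj_ensemble <- function(x, ...) {
  cat("Ensemble of", x$n_subclassifiers, "one-versus-rest subclassifiers\n")
  print(x$learner_counts)
  cat("Feature columns:", x$n_features, "\n")
  cat("Classes:", paste(x$classes, collapse = ", "), "\n")
  cat("SMOTE target:", x$config$smote_target,
      "| scope:", x$config$smote_scope, "\n")
  invisible(x)
}
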