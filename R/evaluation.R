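# Per-class confusion accounting, Sn/Sp/Acc/AvgSn metrics and the
# class-stratified k-fold cross-validation driver.

#' Per-class stratified fold plan
#'
#' Each class is independently permuted under `seed` and split into
#' `n_folds` near-equal parts (sizes differ by at most 1 within a class);
#' fold k's test set is the union of part k of every class, so every fold
#' sees every class.
#'
#' @param y class labels.
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed.
#' @return integer vector of fold assignments (1..n_folds), one per sample.
#' @export
make_fold_plan <- function(y, n_folds = 10, seed = 1) {
  y <- as.factor(y)
  counts <- table(y)
  small <- names(counts)[counts > 0 & counts < n_folds]
  if (length(small) > 0) {
    stop("class(es) smaller than n_folds = ", n_folds, ": ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) == 0) next
      fold[idx[sample.int(length(idx))]] <-
        rep(seq_len(n_folds), length.out = length(idx))
    }
  })
  fold
}

#' One-versus-rest confusion counts
#'
#' @param truth true class labels.
#' @param predicted predicted class labels of equal length.
#' @param classes class alphabet (defaults to the union of factor levels).
#' @return data frame with one row per class: `tp`, `fn`, `fp`, `tn`; each
#'   row sums to the total sample count.
#' @export
confusion_counts <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) {
    stop("'truth' and 'predicted' must have the same length", call. = FALSE)
  }
  truth <- as.factor(truth)
  predicted <- as.factor(predicted)
  classes <- classes %||% union(levels(truth), levels(predicted))
  n <- length(truth)
  out <- t(vapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    fp <- sum(truth != cl & predicted == cl)
    c(tp = tp, fn = fn, fp = fp, tn = n - tp - fn - fp)
  }, numeric(4)))
  data.frame(class = classes, out, row.names = NULL)
}

#' Classification metrics: Sn, Sp, Acc, AvgSn
#'
#' One-versus-rest sensitivity `Sn_i = TP_i / (TP_i + FN_i)` and specificity
#' `Sp_i = TN_i / (TN_i + FP_i)` per class, overall accuracy
#' `Acc = sum(TP_i) / N` and the unweighted mean sensitivity
#' `AvgSn = mean(Sn_i)`. AvgSn weights every class equally, so it is the
#' headline measure on imbalanced J-protein data where accuracy is dominated
#' by the type III majority. A class absent from `truth` has undefined
#' sensitivity; it is reported as `NA` and excluded from AvgSn with a
#' warning.
#'
#' @inheritParams confusion_counts
#' @return an object of class `dnaj_metrics`: per-class table (`tp`, `fn`,
#'   `fp`, `tn`, `sn`, `sp`), `acc`, `avg_sn`, `n`.
#' @export
#' @examples
#' compute_metrics(c("I", "II", "III", "IV"), c("I", "II", "III", "IV"))
compute_metrics <- function(truth, predicted, classes = NULL) {
  cc <- confusion_counts(truth, predicted, classes)
  cc$sn <- ifelse(cc$tp + cc$fn > 0, cc$tp / (cc$tp + cc$fn), NA_real_)
  cc$sp <- ifelse(cc$tn + cc$fp > 0, cc$tn / (cc$tn + cc$fp), NA_real_)
  if (anyNA(cc$sn)) {
    warning("class(es) absent from truth: ",
            paste(cc$class[is.na(cc$sn)], collapse = ", "),
            "; AvgSn averages the remaining classes", call. = FALSE)
  }
  structure(list(per_class = cc,
                 acc = sum(cc$tp) / length(truth),
                 avg_sn = mean(cc$sn, na.rm = TRUE),
                 n = length(truth)),
            class = "dnaj_metrics")
}

#' @export
print.dnaj_metrics <- function(x, ...) {
  tab <- x$per_class
  tab$sn <- round_half_up(tab$sn, 3)
  tab$sp <- round_half_up(tab$sp, 3)
  print(tab[, c("class", "tp", "fn", "fp", "tn", "sn", "sp")],
        row.names = FALSE)
  cat(sprintf("N = %d   Acc = %.3f   AvgSn = %.3f\n",
              x$n, round_half_up(x$acc, 3), round_half_up(x$avg_sn, 3)))
  invisible(x)
}

#' Average sensitivity from per-class sensitivities
#'
#' The unweighted mean of per-class sensitivities — the arithmetic behind
#' every AvgSn row in a per-class performance table.
#'
#' @param sn numeric vector of per-class sensitivities.
#' @return their mean.
#' @export
#' @examples
#' round_half_up(average_sensitivity(c(0.905, 0.745, 0.851, 1)), 3) # 0.875
average_sensitivity <- function(sn) mean(sn)

#' Cross-validate the ensemble (or a single-model baseline)
#'
#' Runs class-stratified k-fold cross-validation. With
#' `model = "ensemble"` each training fold is balanced per the configured
#' SMOTE scope, subdatasets are built, the ensemble trained and the test
#' fold predicted. With `model = "random-forest"` a single multiclass random
#' forest is trained on the raw, unbalanced training folds — the natural
#' baseline the ensemble is designed to beat on minority-class sensitivity.
#'
#' Metrics are reported two ways: `pooled` (all test-fold predictions
#' collected, metrics computed once — stable for classes with very few
#' sequences) and `fold_mean` (mean over per-fold metric values). Under the
#' pre-CV SMOTE scope, synthetic minority rows take part in both folds and
#' metrics (that is what the expansion-before-CV protocol implies);
#' `pooled_real` restricts to non-synthetic rows for reference.
#'
#' @param x feature matrix.
#' @param y class labels.
#' @param config an [ensemble_config].
#' @param features optional selected feature indices.
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed for fold assignment, SMOTE and training.
#' @param model `"ensemble"` or `"random-forest"`.
#' @return an object of class `dnaj_cv`: `pooled`, `pooled_real`,
#'   `fold_mean` (data frame of per-fold Acc/AvgSn and their means),
#'   `predictions` (data frame: id, fold, synthetic, truth, prediction, one
#'   vote column per class for the ensemble).
#' @export
cross_validate <- function(x, y, config = ensemble_config(),
                           features = NULL, n_folds = 10, seed = 1,
                           model = c("ensemble", "random-forest")) {
  model <- match.arg(model)
  x <- as_feature_matrix(x)
  y <- as.factor(y)
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  ids <- rownames(x) %||% paste0("s", seq_len(nrow(x)))
  synthetic <- rep(FALSE, nrow(x))

  pre_cv <- model == "ensemble" &&
    config$smote_scope == "paper_faithful_pre_cv"
  if (pre_cv) {
    n0 <- nrow(x)
    ex <- expand_rarest(x, y, config, seed = seed + 1L)
    x <- ex$x
    y <- ex$y
    n_syn <- nrow(x) - n0
    if (n_syn > 0) {
      ids <- c(ids, paste0("smote_", seq_len(n_syn)))
      synthetic <- c(synthetic, rep(TRUE, n_syn))
    }
  }

  fold <- make_fold_plan(y, n_folds = n_folds, seed = seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  votes <- matrix(NA_integer_, nrow = length(y), ncol = length(levels(y)),
                  dimnames = list(NULL, levels(y)))
  fold_rows <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    te <- !tr
    if (model == "ensemble") {
      cfg <- config
      cfg$seed <- as.integer((seed + 131L * k) %% 2^30)
      fit <- dnaj_ensemble(x[tr, , drop = FALSE], y[tr], cfg,
                           balance = !pre_cv &&
                             config$smote_scope == "train_fold_only")
      v <- predict(fit, x[te, , drop = FALSE], type = "votes")
      votes[te, ] <- v
      pred[te] <- resolve_votes(v, x[te, , drop = FALSE],
                                fit$class_centroids)
    } else {
      fit <- with_seed(seed + 131L * k, randomForest::randomForest(
        x[tr, , drop = FALSE], y[tr], ntree = config$rf_ntree))
      pred[te] <- stats::predict(fit, x[te, , drop = FALSE])
    }
    m <- compute_metrics(y[te], pred[te], classes = levels(y))
    fold_rows[[k]] <- data.frame(fold = k, acc = m$acc, avg_sn = m$avg_sn)
  }
  fold_tab <- do.call(rbind, fold_rows)
  preds <- data.frame(id = ids, fold = fold, synthetic = synthetic,
                      truth = y, prediction = pred)
  if (model == "ensemble") preds <- cbind(preds, votes)
  structure(list(
    pooled = compute_metrics(y, pred, classes = levels(y)),
    pooled_real = compute_metrics(y[!synthetic], pred[!synthetic],
                                  classes = levels(y)),
    fold_mean = list(per_fold = fold_tab,
                     acc = mean(fold_tab$acc),
                     avg_sn = mean(fold_tab$avg_sn)),
    predictions = preds,
    model = model, n_folds = n_folds, seed = seed,
    smote_scope = if (model == "ensemble") config$smote_scope else "none"),
    class = "dnaj_cv")
}

#' @export
print.dnaj_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s, SMOTE scope: %s)\n",
              x$n_folds, x$model, x$smote_scope))
  cat("Pooled test-fold metrics:\n")
  print(x$pooled)
  cat(sprintf("Fold-mean: Acc = %.3f, AvgSn = %.3f\n",
              round_half_up(x$fold_mean$acc, 3),
              round_half_up(x$fold_mean$avg_sn, 3)))
  invisible(x)
}
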