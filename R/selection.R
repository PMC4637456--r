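# Symmetric-uncertainty feature ranking and incremental feature selection.
# SU is defined on discrete variables, so numeric features are first
# discretized; the default discretizer is the Fayyad-Irani recursive
# entropy/MDL method (the standard behaviour for SU attribute evaluation on
# numeric data), with an unsupervised equal-frequency fallback.

# Shannon entropy (bits) of a count vector; empty cells contribute 0.
entropy_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# Fayyad-Irani MDL cut points on a sorted arrangement; returns numeric cut
# values (midpoints), possibly empty.
mdlp_cuts <- function(values, labels) {
  ord <- order(values)
  v <- values[ord]
  y <- as.integer(factor(labels))[ord]
  n_class <- max(y)
  cuts <- numeric(0)
  recurse <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 2) return(invisible(NULL))
    vv <- v[lo:hi]
    yy <- y[lo:hi]
    cand <- which(vv[-n] < vv[-1]) # split after position i (1..n-1)
    if (length(cand) == 0) return(invisible(NULL))
    # cumulative class counts along the sorted segment
    cum <- apply(outer(yy, seq_len(n_class), "=="), 2, cumsum)
    cum <- matrix(cum, nrow = n)
    total <- cum[n, ]
    H_S <- entropy_counts(total)
    left <- cum[cand, , drop = FALSE]
    right <- sweep(-left, 2, total, "+")
    ent_rows <- function(m) apply(m, 1, entropy_counts)
    nl <- rowSums(left)
    nr <- rowSums(right)
    e_l <- ent_rows(left)
    e_r <- ent_rows(right)
    went <- (nl * e_l + nr * e_r) / n
    best <- which.min(went)
    gain <- H_S - went[best]
    k <- sum(total > 0)
    k1 <- sum(left[best, ] > 0)
    k2 <- sum(right[best, ] > 0)
    delta <- log2(3^k - 2) - (k * H_S - k1 * e_l[best] - k2 * e_r[best])
    if (gain <= (log2(n - 1) + delta) / n) return(invisible(NULL))
    i <- cand[best]
    cuts <<- c(cuts, (vv[i] + vv[i + 1]) / 2)
    recurse(lo, lo + i - 1)
    recurse(lo + i, hi)
    invisible(NULL)
  }
  recurse(1, length(v))
  sort(cuts)
}

#' Discretize a numeric feature for symmetric-uncertainty scoring
#'
#' @param values numeric feature vector.
#' @param labels class vector of the same length (needed by the supervised
#'   method; at least 2 distinct labels).
#' @param method `"mdl"` (Fayyad-Irani recursive entropy/MDL partitioning,
#'   default) or `"eqfreq"` (unsupervised equal-frequency bins).
#' @param bins number of bins for the equal-frequency method (default 10).
#' @return integer vector of bin labels (1-based). A feature for which no
#'   cut passes the MDL criterion - including a constant feature - maps to a
#'   single bin, which downstream yields SU = 0.
#' @export
discretize_feature <- function(values, labels, method = c("mdl", "eqfreq"),
                               bins = 10) {
  method <- match.arg(method)
  if (length(values) != length(labels)) {
    stop("'values' and 'labels' must have the same length", call. = FALSE)
  }
  if (method == "mdl") {
    if (length(unique(labels)) < 2) {
      stop("supervised discretization needs at least 2 distinct labels",
           call. = FALSE)
    }
    cuts <- mdlp_cuts(values, labels)
  } else {
    qs <- stats::quantile(values, probs = seq_len(bins - 1) / bins,
                          names = FALSE, type = 7)
    cuts <- unique(qs)
    cuts <- cuts[cuts > min(values) & cuts < max(values)]
  }
  findInterval(values, cuts) + 1L
}

#' Symmetric uncertainty between a discrete feature and the class
#'
#' `SU(f, C) = 2 * IG(f; C) / (H(f) + H(C))`, with entropies in bits,
#' `IG = H(C) - H(C | f)`. SU is a normalised mutual information: 0 under
#' empirical independence, 1 when the two variables determine each other.
#'
#' @param feature_bins discrete feature values (integer bins or any discrete
#'   vector).
#' @param labels class vector of equal length.
#' @return SU score in `[0, 1]`; 0 when `H(f) + H(C) = 0`.
#' @export
#' @examples
#' symmetric_uncertainty(c(0, 0, 1, 1), c("a", "a", "b", "b")) # 1
#' symmetric_uncertainty(c(0, 1, 0, 1), c("a", "a", "b", "b")) # 0
symmetric_uncertainty <- function(feature_bins, labels) {
  if (length(feature_bins) != length(labels)) {
    stop("'feature_bins' and 'labels' must have the same length",
         call. = FALSE)
  }
  tab <- table(feature_bins, labels)
  n <- sum(tab)
  h_f <- entropy_counts(rowSums(tab))
  h_c <- entropy_counts(colSums(tab))
  if (h_f + h_c == 0) return(0)
  # H(C | f) = sum_j P(f_j) H(C | f_j)
  h_cf <- sum(apply(tab, 1, function(r) sum(r) / n * entropy_counts(r)))
  ig <- h_c - h_cf
  min(max(2 * ig / (h_f + h_c), 0), 1)
}

#' Rank features by symmetric uncertainty with the class
#'
#' Every feature column is discretized, scored by [symmetric_uncertainty()]
#' and sorted by decreasing SU; ties keep the original column order.
#'
#' @param x numeric feature matrix (columns = features).
#' @param y class vector.
#' @param method discretization method, see [discretize_feature()].
#' @return object of class `ranked_features` with elements `order`
#'   (feature indices, decreasing SU) and `su_scores` (SU per feature, in
#'   ranked order), plus `feature_names` when `x` has column names.
#' @export
rank_features <- function(x, y, method = c("mdl", "eqfreq")) {
  x <- as_feature_matrix(x)
  method <- match.arg(method)
  if (length(unique(y)) < 2) {
    stop("feature ranking needs at least 2 classes", call. = FALSE)
  }
  su <- vapply(seq_len(ncol(x)), function(j) {
    bins <- discretize_feature(x[, j], y, method = method)
    symmetric_uncertainty(bins, y)
  }, numeric(1))
  ord <- order(-su, seq_along(su))
  structure(list(order = ord, su_scores = su[ord],
                 feature_names = colnames(x)[ord]),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, n = 10, ...) {
  cat("Feature ranking by symmetric uncertainty (", length(x$order),
      " features)\n", sep = "")
  top <- utils::head(data.frame(
    index = x$order,
    name = x$feature_names %||% rep(NA_character_, length(x$order)),
    su = round(x$su_scores, 4)), n)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Incremental feature selection over a ranked list
#'
#' Walks growing prefixes of the ranked feature list, scoring each prefix
#' with an evaluation callback (average sensitivity from a cross-validated
#' model), and returns the best prefix; on ties the smaller prefix wins,
#' since the point of the procedure is the lowest dimension achieving the
#' best score.
#'
#' @param ranked a `ranked_features` object from [rank_features()].
#' @param evaluator function taking a vector of global feature indices and
#'   returning a single numeric score (AvgSn). See [evaluator_centroid()]
#'   and [evaluator_ensemble()].
#' @param step prefix-size increment (default 1, which examines every prefix;
#'   larger steps give a cheaper scan and always include the full set).
#' @return object of class `dnaj_ifs`: `sizes`, `curve` (score per evaluated
#'   prefix), `best_size`, `best_score`, `best_features` (global indices).
#' @export
incremental_feature_selection <- function(ranked, evaluator, step = 1) {
  stopifnot(inherits(ranked, "ranked_features"))
  if (step < 1) stop("'step' must be a positive integer", call. = FALSE)
  n <- length(ranked$order)
  sizes <- unique(c(seq(step, n, by = step), n))
  curve <- vapply(sizes, function(k) evaluator(ranked$order[seq_len(k)]),
                  numeric(1))
  best <- which.max(curve) # which.max returns the first (smallest) argmax
  structure(list(sizes = sizes, curve = curve,
                 best_size = sizes[best], best_score = curve[best],
                 best_features = ranked$order[seq_len(sizes[best])]),
            class = "dnaj_ifs")
}

#' @export
print.dnaj_ifs <- function(x, ...) {
  cat("Incremental feature selection:", length(x$sizes),
      "prefixes evaluated\n")
  cat(sprintf("  best prefix: %d features, AvgSn = %.3f\n",
              x$best_size, x$best_score))
  invisible(x)
}

#' @export
plot.dnaj_ifs <- function(x, ...) {
  graphics::plot(x$sizes, x$curve, type = "l", xlab = "Number of features",
                 ylab = "AvgSn", ...)
  graphics::abline(v = x$best_size, lty = 2)
  invisible(x)
}

#' Prefix evaluators for incremental feature selection
#'
#' `evaluator_centroid()` is a cheap surrogate: stratified cross-validated
#' nearest-centroid classification, suitable for desk-scale IFS scans (it is
#' not the full ensemble protocol). `evaluator_ensemble()` is the faithful
#' evaluator: the full imbalance-aware ensemble under per-class k-fold
#' cross-validation, at correspondingly higher cost.
#'
#' @param x feature matrix.
#' @param y class labels.
#' @param n_folds folds for the internal cross-validation.
#' @param seed RNG seed for fold assignment (and ensemble training).
#' @param config [ensemble_config] for the faithful evaluator.
#' @return a function mapping a vector of feature indices to AvgSn.
#' @export
evaluator_centroid <- function(x, y, n_folds = 5, seed = 1) {
  x <- as_feature_matrix(x)
  y <- as.factor(y)
  fold <- make_fold_plan(y, n_folds = n_folds, seed = seed)
  function(idx) {
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      cen <- centroid_matrix(x[tr, idx, drop = FALSE], y[tr])
      pred[!tr] <- nearest_centroid(x[!tr, idx, drop = FALSE], cen)
    }
    mean_sensitivity(y, pred)
  }
}

#' @rdname evaluator_centroid
#' @export
evaluator_ensemble <- function(x, y, config = ensemble_config(),
                               n_folds = 10, seed = 1) {
  x <- as_feature_matrix(x)
  y <- as.factor(y)
  function(idx) {
    cv <- cross_validate(x[, idx, drop = FALSE], y, config = config,
                         n_folds = n_folds, seed = seed)
    cv$pooled$avg_sn
  }
}

# Per-class centroid matrix (classes x features) and nearest-centroid labels.
centroid_matrix <- function(x, y) {
  y <- droplevels(as.factor(y))
  m <- vapply(levels(y), function(cl) colMeans(x[y == cl, , drop = FALSE]),
              numeric(ncol(x)))
  t(matrix(m, nrow = ncol(x), dimnames = list(colnames(x), levels(y))))
}

nearest_centroid <- function(x, centroids) {
  d <- vapply(seq_len(nrow(centroids)), function(i) {
    rowSums(sweep(x, 2, centroids[i, ])^2)
  }, numeric(nrow(x)))
  d <- matrix(d, nrow = nrow(x))
  rownames(centroids)[max.col(-d, ties.method = "first")]
}

# Unweighted mean of per-class sensitivities over classes present in truth.
mean_sensitivity <- function(truth, pred) {
  truth <- as.factor(truth)
  sn <- vapply(levels(truth), function(cl) {
    n <- sum(truth == cl)
    if (n == 0) return(NA_real_)
    sum(truth == cl & pred == cl) / n
  }, numeric(1))
  mean(sn, na.rm = TRUE)
}
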