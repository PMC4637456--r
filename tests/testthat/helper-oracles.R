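# Independent brute-force oracles, deliberately written as naive loops so
# they share no code path with the package implementation.

AA_ALPHA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_sequence <- function(L) {
  paste(sample(AA_ALPHA, L, replace = TRUE), collapse = "")
}

# Lagged property autocovariances, property-major, lags ascending.
oracle_pseaac <- function(sequence, properties, gamma_max) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  out <- numeric(0)
  for (j in seq_len(ncol(properties))) {
    p <- properties[chars, j]
    pbar <- sum(p) / L
    for (g in seq_len(gamma_max)) {
      s <- 0
      for (i in seq_len(L - g)) {
        s <- s + (p[i] - pbar) * (p[i + g] - pbar)
      }
      out <- c(out, s / (L - g))
    }
  }
  unname(out)
}

# Sigmoid-normalised PSSM column autocovariances, column-major, lags
# ascending.
oracle_pssm_ac <- function(scores, lambda_max) {
  L <- nrow(scores)
  E <- matrix(0, L, 20)
  for (i in seq_len(L)) {
    for (j in 1:20) E[i, j] <- 1 / (1 + exp(-scores[i, j]))
  }
  out <- numeric(0)
  for (j in 1:20) {
    m <- sum(E[, j]) / L
    for (l in seq_len(lambda_max)) {
      s <- 0
      for (i in seq_len(L - l)) s <- s + (E[i, j] - m) * (E[i + l, j] - m)
      out <- c(out, s / (L - l))
    }
  }
  out
}

# Symmetric uncertainty via the mutual-information route (the package uses
# the conditional-entropy route).
oracle_su <- function(f, y) {
  tab <- table(f, y)
  n <- sum(tab)
  pj <- rowSums(tab) / n
  pc <- colSums(tab) / n
  mi <- 0
  for (a in seq_len(nrow(tab))) {
    for (b in seq_len(ncol(tab))) {
      p <- tab[a, b] / n
      if (p > 0) mi <- mi + p * log2(p / (pj[a] * pc[b]))
    }
  }
  hf <- -sum(pj[pj > 0] * log2(pj[pj > 0]))
  hc <- -sum(pc[pc > 0] * log2(pc[pc > 0]))
  if (hf + hc == 0) return(0)
  as.numeric(2 * mi / (hf + hc))
}

# One-versus-rest confusion counts by explicit looping.
oracle_confusion <- function(truth, pred, classes) {
  out <- list()
  for (cl in classes) {
    tp <- fn <- fp <- tn <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == cl && pred[i] == cl) tp <- tp + 1
      else if (truth[i] == cl) fn <- fn + 1
      else if (pred[i] == cl) fp <- fp + 1
      else tn <- tn + 1
    }
    out[[cl]] <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  }
  out
}

# Best single binary split by exhaustive search over all midpoints
# (minimum weighted class entropy); returns the cut value.
oracle_best_cut <- function(values, labels) {
  vs <- sort(unique(values))
  ent <- function(y) {
    p <- table(y) / length(y)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  best <- NULL
  best_e <- Inf
  for (i in seq_len(length(vs) - 1)) {
    cut <- (vs[i] + vs[i + 1]) / 2
    left <- labels[values <= cut]
    right <- labels[values > cut]
    e <- (length(left) * ent(left) + length(right) * ent(right)) /
      length(labels)
    if (e < best_e) {
      best_e <- e
      best <- cut
    }
  }
  best
}

# Distance from point p to the segment [a, b].
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  denom <- sum(ab^2)
  t <- if (denom == 0) 0 else max(0, min(1, sum((p - a) * ab) / denom))
  sqrt(sum((p - (a + t * ab))^2))
}
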