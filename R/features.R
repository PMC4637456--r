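# Hybrid feature extraction: split amino acid composition (SAAC), pseudo
# amino acid composition (PseAAC, lagged property autocovariances) and
# autocovariance of the sigmoid-normalised PSSM.

#' Feature extraction configuration
#'
#' @param lnc number of residues in each of the N- and C-terminal segments
#'   for the split amino acid composition (default 22, the value at which
#'   terminal-composition discrimination of J-protein types peaks).
#' @param gamma_max maximum sequence lag for the PseAAC property
#'   autocovariances (default 8).
#' @param lambda_max maximum lag for the PSSM column autocovariances
#'   (default 5).
#' @param short_sequence_policy what to do with sequences shorter than
#'   `2 * lnc + 1`: `"error"` (default for training) or `"thirds"` (split
#'   into three near-equal contiguous parts; default for prediction-time
#'   robustness).
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(lnc = 22, gamma_max = 8, lambda_max = 5,
                           short_sequence_policy = c("error", "thirds")) {
  short_sequence_policy <- match.arg(short_sequence_policy)
  stopifnot(lnc >= 1, gamma_max >= 1, lambda_max >= 1)
  structure(list(lnc = as.integer(lnc), gamma_max = as.integer(gamma_max),
                 lambda_max = as.integer(lambda_max),
                 short_sequence_policy = short_sequence_policy),
            class = "feature_config")
}

#' Feature names for a configuration
#'
#' The global feature order is frozen: the 60 SAAC entries (N-terminal,
#' middle, C-terminal segment; residues alphabetical within each), then
#' PseAAC property-major with ascending lags (`pseaac.p1.g1 ... p12.g<max>`),
#' then PSSM autocovariances column-major with ascending lags
#' (`pssm.A.l1 ... pssm.Y.l<max>`). Ranked-feature indices are therefore
#' portable across runs and datasets.
#'
#' @param config a [feature_config].
#' @return character vector of length `60 + 12 * gamma_max + 20 * lambda_max`.
#' @export
feature_names <- function(config = feature_config()) {
  saac <- paste0("saac.", rep(c("N", "M", "C"), each = 20), ".", AA20)
  pse <- paste0("pseaac.p", rep(seq_len(12), each = config$gamma_max),
                ".g", seq_len(config$gamma_max))
  pac <- paste0("pssm.", rep(AA20, each = config$lambda_max),
                ".l", seq_len(config$lambda_max))
  c(saac, pse, pac)
}

#' Block index of the hybrid feature vector
#'
#' @param config a [feature_config].
#' @return named list of integer index spans for blocks `saac`, `pseaac`,
#'   `pssm_ac`.
#' @export
feature_blocks <- function(config = feature_config()) {
  n_pse <- 12L * config$gamma_max
  n_pac <- 20L * config$lambda_max
  list(saac = 1:60,
       pseaac = 60L + seq_len(n_pse),
       pssm_ac = 60L + n_pse + seq_len(n_pac))
}

#' Split amino acid composition
#'
#' Splits the sequence into an N-terminal segment of `lnc` residues, a
#' C-terminal segment of `lnc` residues and the remaining centre, and
#' concatenates the three 20-letter frequency vectors (alphabetical residue
#' order within each part). Terminal composition bias carries type signal
#' that whole-sequence composition dilutes.
#'
#' @param sequence amino-acid sequence string.
#' @param lnc terminal segment length.
#' @param policy short-sequence policy, `"error"` or `"thirds"`; sequences
#'   shorter than `2 * lnc + 1` are either rejected or split into three
#'   contiguous near-equal thirds.
#' @return numeric vector of length 60; each nonempty part sums to 1.
#' @export
compute_saac <- function(sequence, lnc = 22, policy = c("error", "thirds")) {
  policy <- match.arg(policy)
  check_sequence(sequence)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (L >= 2 * lnc + 1) {
    parts <- list(chars[1:lnc],
                  chars[(lnc + 1):(L - lnc)],
                  chars[(L - lnc + 1):L])
  } else if (policy == "error") {
    stop("sequence length ", L, " < 2*lnc + 1 = ", 2 * lnc + 1,
         " (use policy = \"thirds\" to split short sequences)",
         call. = FALSE)
  } else {
    cut1 <- floor(L / 3)
    cut2 <- floor(2 * L / 3)
    parts <- list(if (cut1 >= 1) chars[1:cut1] else character(0),
                  if (cut2 >= cut1 + 1) chars[(cut1 + 1):cut2]
                  else character(0),
                  chars[(cut2 + 1):L])
  }
  out <- unlist(lapply(parts, function(p) {
    if (length(p) == 0) return(rep(0, 20))
    as.vector(table(factor(p, levels = AA20))) / length(p)
  }), use.names = FALSE)
  names(out) <- feature_names(feature_config())[1:60]
  out
}

#' Pseudo amino acid composition (property autocovariances)
#'
#' Maps the sequence to twelve physicochemical property profiles and, for
#' each property j and lag gamma, computes the mean-centred lagged
#' autocovariance
#' `(1 / (L - gamma)) * sum_i (p_ij - mean_j) * (p_(i+gamma)j - mean_j)`,
#' where `mean_j` is the mean of property j over the sequence. Captures
#' sequence-order information that composition alone discards.
#'
#' @param sequence amino-acid sequence string of length `L > gamma_max`.
#' @param properties 20 x 12 property matrix from [aa_properties()].
#' @param gamma_max maximum lag.
#' @return numeric vector of length `12 * gamma_max`, property-major with
#'   ascending lags within each property.
#' @export
compute_pseaac <- function(sequence, properties = aa_properties(),
                           gamma_max = 8) {
  check_sequence(sequence)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (L <= gamma_max) {
    stop("sequence length ", L, " must exceed gamma_max = ", gamma_max,
         call. = FALSE)
  }
  P <- properties[match(chars, rownames(properties)), , drop = FALSE]
  np <- ncol(properties)
  Pc <- sweep(P, 2, colMeans(P))
  ac <- matrix(0, nrow = gamma_max, ncol = np) # lag x property
  for (g in seq_len(gamma_max)) {
    ac[g, ] <- colSums(Pc[1:(L - g), , drop = FALSE] *
                         Pc[(1 + g):L, , drop = FALSE]) / (L - g)
  }
  out <- as.vector(ac) # property-major: p1 lags 1..g, p2 lags, ...
  names(out) <- paste0("pseaac.p", rep(seq_len(np), each = gamma_max),
                       ".g", seq_len(gamma_max))
  out
}

#' Sigmoid normalisation of a PSSM
#'
#' Squashes each raw log-odds score through `1 / (1 + exp(-x))`, mapping the
#' matrix into (0, 1) and damping the influence of extreme scores before
#' autocovariance extraction.
#'
#' @param pssm a [pssm_profile] or a numeric matrix.
#' @return numeric matrix of the same shape with entries in (0, 1).
#' @export
sigmoid_normalize <- function(pssm) {
  m <- if (inherits(pssm, "pssm_profile")) pssm$scores else as.matrix(pssm)
  1 / (1 + exp(-m))
}

#' PSSM autocovariance features
#'
#' Operates on the sigmoid-normalised matrix: for each of the 20 residue
#' columns j and each lag lambda,
#' `AC(lambda, j) = (1 / (L - lambda)) * sum_i (E_ij - mean_j) *
#' (E_(i+lambda)j - mean_j)` with `mean_j` the column mean of the normalised
#' matrix. Captures local evolutionary-conservation patterns along the
#' sequence.
#'
#' @param pssm a [pssm_profile] with more rows than `lambda_max`.
#' @param lambda_max maximum lag.
#' @return numeric vector of length `20 * lambda_max`, column-major with
#'   ascending lags within each residue column. All zeros for a fallback
#'   (all-zero) profile, whose normalised matrix is constant 0.5.
#' @export
compute_pssm_ac <- function(pssm, lambda_max = 5) {
  stopifnot(inherits(pssm, "pssm_profile"))
  E <- sigmoid_normalize(pssm)
  L <- nrow(E)
  if (L <= lambda_max) {
    stop("PSSM has ", L, " rows; needs more than lambda_max = ", lambda_max,
         call. = FALSE)
  }
  Ec <- sweep(E, 2, colMeans(E))
  ac <- matrix(0, nrow = lambda_max, ncol = 20) # lag x column
  for (l in seq_len(lambda_max)) {
    ac[l, ] <- colSums(Ec[1:(L - l), , drop = FALSE] *
                         Ec[(1 + l):L, , drop = FALSE]) / (L - l)
  }
  out <- as.vector(ac)
  names(out) <- paste0("pssm.", rep(AA20, each = lambda_max),
                       ".l", seq_len(lambda_max))
  out
}

#' Extract the hybrid feature vector of one record
#'
#' Concatenates the SAAC, PseAAC and PSSM-autocovariance blocks. With the
#' default configuration (`lnc = 22`, `gamma_max = 8`, `lambda_max = 5`) the
#' vector has `60 + 96 + 100 = 256` entries.
#'
#' @param record a [protein_record]; if it carries no PSSM an all-zero
#'   fallback profile is used.
#' @param config a [feature_config].
#' @param properties property matrix from [aa_properties()].
#' @return named numeric vector of length
#'   `60 + 12 * gamma_max + 20 * lambda_max`.
#' @export
extract_features <- function(record, config = feature_config(),
                             properties = aa_properties()) {
  stopifnot(inherits(record, "protein_record"))
  pssm <- record$pssm %||% zero_pssm(nchar(record$sequence))
  res <- tryCatch(
    c(compute_saac(record$sequence, config$lnc,
                   config$short_sequence_policy),
      compute_pseaac(record$sequence, properties, config$gamma_max),
      compute_pssm_ac(pssm, config$lambda_max)),
    error = function(e) {
      stop("record '", record$id, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  res
}

#' Feature matrix of a dataset
#'
#' @param dataset a `dnaj_dataset` from [assemble_dataset()] or
#'   [simulate_dataset()].
#' @param config a [feature_config].
#' @param properties property matrix from [aa_properties()].
#' @return numeric matrix, one row per record (rownames = ids, colnames =
#'   [feature_names()]), with the label factor attached as attribute
#'   `labels`.
#' @export
feature_matrix <- function(dataset, config = feature_config(),
                           properties = aa_properties()) {
  stopifnot(inherits(dataset, "dnaj_dataset"))
  rows <- lapply(dataset$records, extract_features, config = config,
                 properties = properties)
  x <- do.call(rbind, rows)
  rownames(x) <- vapply(dataset$records, function(r) r$id, character(1))
  structure(x, labels = dataset_labels(dataset))
}

#' Write / read a feature table
#'
#' Tab-separated export with an `id` column, a `label` column and one column
#' per global feature name; the round-trip restores the matrix and labels.
#'
#' @param x feature matrix with attribute `labels` (from [feature_matrix()]).
#' @param path file path.
#' @return `path` invisibly (write) or the feature matrix with `labels`
#'   attribute (read).
#' @export
write_feature_table <- function(x, path) {
  labs <- attr(x, "labels")
  df <- data.frame(id = rownames(x) %||% as.character(seq_len(nrow(x))),
                   label = as.character(labs),
                   as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  x <- as.matrix(df[, setdiff(names(df), c("id", "label")), drop = FALSE])
  rownames(x) <- df$id
  structure(x, labels = as_jtype(df$label))
}
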