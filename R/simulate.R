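# Synthetic 4-class imbalanced benchmark: sequences with class-specific
# composition bias, optional planted N-terminal motifs, and synthetic PSSM
# profiles with class-dependent column means. Content is synthetic; only
# the imbalance regime mirrors real J-protein data.

#' Simulation configuration
#'
#' Defaults mirror the class imbalance of a curated J-protein benchmark
#' (63 type I, 55 type II, 1061 type III, 20 type IV) so the SMOTE and
#' undersampling machinery runs in its intended regime; `scale` shrinks all
#' counts proportionally (floored at 2 per class) for fast runs.
#'
#' @param class_counts named integer vector of sequences per class.
#' @param length_range min/max sequence length (uniform); the minimum must
#'   leave room for the default terminal segments (`> 2 * lnc`).
#' @param composition_bias weight in `[0, 1)` mixing a class-specific
#'   Dirichlet-drawn letter distribution into the uniform background; 0
#'   means all classes share the uniform composition (no signal).
#' @param terminal_motif optional named character vector (class -> motif)
#'   planted at the N-terminus of every sequence of that class.
#' @param pssm_signal standard deviation of the class-specific PSSM column
#'   mean shifts (integer log-odds scale); 0 removes all class signal from
#'   the profiles.
#' @param pssm_noise per-cell noise standard deviation of the synthetic
#'   PSSM scores (clamped to integer log-odds in `[-6, 8]`).
#' @param seed RNG seed; generation is fully deterministic given the config.
#' @param scale divisor applied to `class_counts` (minimum 2 per class).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(class_counts = c(I = 63, II = 55, III = 1061,
                                        IV = 20),
                       length_range = c(80, 300),
                       composition_bias = 0.3,
                       terminal_motif = NULL,
                       pssm_signal = 1.5, pssm_noise = 2,
                       seed = 1, scale = 1) {
  stopifnot(all(class_counts >= 1), length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2],
            composition_bias >= 0, composition_bias < 1,
            pssm_signal >= 0, pssm_noise >= 0, scale >= 1)
  counts <- pmax(2L, as.integer(round(class_counts / scale)))
  names(counts) <- names(class_counts)
  if (!is.null(terminal_motif)) {
    for (m in terminal_motif) {
      check_sequence(toupper(m), id = "<terminal_motif>")
      if (nchar(m) > length_range[1]) {
        stop("terminal motif longer than the minimum sequence length",
             call. = FALSE)
      }
    }
  }
  structure(list(class_counts = counts,
                 length_range = as.integer(length_range),
                 composition_bias = composition_bias,
                 terminal_motif = terminal_motif,
                 pssm_signal = pssm_signal, pssm_noise = pssm_noise,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a labelled benchmark dataset
#'
#' Per class, a letter distribution is drawn once
#' (`(1 - w) * uniform + w * Dirichlet(1)` with `w = composition_bias`) and
#' sequences are sampled i.i.d. from it, with the class motif (if any)
#' overwriting the N-terminus. Each sequence gets a synthetic PSSM: integer
#' log-odds `round(b_cj + noise)` clamped to `[-6, 8]`, where `b_cj` is a
#' class-level column shift drawn once per class with sd `pssm_signal`.
#'
#' @param config a [sim_config].
#' @return a `dnaj_dataset` (records carry labels and PSSMs); the config is
#'   attached as attribute `sim_config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$composition_bias
  lr <- config$length_range
  records <- with_seed(config$seed, {
    out <- list()
    for (cl in names(config$class_counts)) {
      dirich <- stats::rgamma(20, shape = 1)
      probs <- (1 - w) / 20 + w * dirich / sum(dirich)
      b <- stats::rnorm(20, 0, config$pssm_signal)
      motif <- if (!is.null(config$terminal_motif) &&
                   cl %in% names(config$terminal_motif)) {
        config$terminal_motif[[cl]]
      }
      for (i in seq_len(config$class_counts[[cl]])) {
        L <- sample(lr[1]:lr[2], 1)
        chars <- sample(AA20, L, replace = TRUE, prob = probs)
        if (!is.null(motif)) {
          chars[seq_len(nchar(motif))] <- strsplit(toupper(motif), "")[[1]]
        }
        scores <- matrix(
          pmin(8, pmax(-6, round(stats::rnorm(L * 20, 0,
                                              config$pssm_noise) +
                                   rep(b, each = L)))),
          nrow = L, ncol = 20)
        id <- sprintf("%s_%04d", cl, i)
        out[[id]] <- protein_record(id, paste(chars, collapse = ""),
                                    label = cl,
                                    pssm = pssm_profile(scores))
      }
    }
    out
  })
  ds <- new_dataset(unname(records), n_fallback = 0L)
  attr(ds, "sim_config") <- config
  ds
}

#' Permute the labels of a dataset
#'
#' Produces the no-signal null used for chance-level checks: class counts
#' are preserved but any association between sequence content and label is
#' destroyed.
#'
#' @param dataset a `dnaj_dataset`.
#' @param seed RNG seed.
#' @return a `dnaj_dataset` with uniformly permuted labels.
#' @export
simulate_null_labels <- function(dataset, seed = 1) {
  stopifnot(inherits(dataset, "dnaj_dataset"))
  labs <- vapply(dataset$records, function(r) r$label, character(1))
  perm <- with_seed(seed, sample(labs))
  records <- lapply(seq_along(dataset$records), function(i) {
    r <- dataset$records[[i]]
    protein_record(r$id, r$sequence, label = perm[i], pssm = r$pssm)
  })
  new_dataset(records, n_fallback = dataset$n_fallback_pssm)
}

#' Write a dataset to disk
#'
#' Emits `sequences.fasta`, `labels.tsv`, one PSI-BLAST-dialect
#' `pssm/<id>.pssm` file per record, and (for simulated data)
#' `sim_config.yaml` recording the generating configuration. The files
#' round-trip through [read_fasta()], [read_labels()] and
#' [assemble_dataset()].
#'
#' @param dataset a `dnaj_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "dnaj_dataset"))
  dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
  fasta <- unlist(lapply(dataset$records, function(r) {
    c(paste0(">", r$id), r$sequence)
  }))
  writeLines(fasta, file.path(dir, "sequences.fasta"))
  labs <- data.frame(
    id = vapply(dataset$records, function(r) r$id, character(1)),
    class = vapply(dataset$records, function(r) r$label, character(1)))
  utils::write.table(labs, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (r in dataset$records) {
    write_pssm(r$pssm, file.path(dir, "pssm", paste0(r$id, ".pssm")),
               sequence = r$sequence)
  }
  cfg <- attr(dataset, "sim_config")
  if (!is.null(cfg)) {
    yaml::write_yaml(unclass(cfg), file.path(dir, "sim_config.yaml"))
  }
  invisible(dir)
}
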