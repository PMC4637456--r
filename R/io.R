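# Reading and validating sequences, labels and PSSM profiles.

#' Create a protein record
#'
#' A protein record bundles an identifier, an amino-acid sequence over the 20
#' standard letters, an optional J-protein type label and an optional PSSM
#' profile.
#'
#' @param id character identifier.
#' @param sequence amino-acid sequence string (upper-cased internally).
#' @param label optional class label in `c("I","II","III","IV")`.
#' @param pssm optional [pssm_profile] whose row count equals the sequence
#'   length.
#' @return an object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, label = NULL, pssm = NULL) {
  sequence <- toupper(as.character(sequence))
  check_sequence(sequence, id = id)
  if (!is.null(label)) label <- as.character(as_jtype(label))
  if (!is.null(pssm)) {
    stopifnot(inherits(pssm, "pssm_profile"))
    if (nrow(pssm$scores) != nchar(sequence)) {
      stop("PSSM row count (", nrow(pssm$scores), ") does not match sequence ",
           "length (", nchar(sequence), ") for record '", id, "'",
           call. = FALSE)
    }
  }
  structure(list(id = as.character(id), sequence = sequence,
                 label = label, pssm = pssm),
            class = "protein_record")
}

# Validate a sequence over the 20 standard letters; error names the record
# and the first offending character.
check_sequence <- function(sequence, id = "<unnamed>") {
  if (!nzchar(sequence)) {
    stop("record '", id, "': empty sequence", call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), AA20)
  if (length(bad) > 0) {
    stop("record '", id, "': nonstandard letter(s) ",
         paste(sQuote(bad), collapse = ", "),
         " (only the 20 standard amino acids are accepted)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read protein sequences from FASTA
#'
#' Parses a FASTA file and validates every sequence against the 20-letter
#' standard amino-acid alphabet. Records containing nonstandard letters
#' (B, X, Z, U, O, gaps, ...) are rejected: in strict mode the whole read
#' fails with an error naming the record, in lenient mode offending records
#' are skipped with a warning. Strict mode is intended for assembling training
#' data, lenient mode for prediction-time inputs.
#'
#' @param path path to a FASTA file.
#' @param strict logical; fail on invalid records (`TRUE`, default) or skip
#'   them with a warning (`FALSE`).
#' @return list of [protein_record] objects.
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  out <- vector("list", length(seqs))
  keep <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    rec <- tryCatch(
      protein_record(ids[i], as.character(seqs[[i]])),
      error = function(e) e
    )
    if (inherits(rec, "error")) {
      if (strict) stop(conditionMessage(rec), call. = FALSE)
      warning("skipping record: ", conditionMessage(rec), call. = FALSE)
    } else {
      out[[i]] <- rec
      keep[i] <- TRUE
    }
  }
  out[keep]
}

#' Construct a PSSM profile
#'
#' @param scores numeric L x 20 matrix of log-odds scores with columns in
#'   alphabetical residue order (`A C D E ... Y`).
#' @param is_fallback logical flag marking the all-zero placeholder attached
#'   to sequences without a usable profile.
#' @return an object of class `pssm_profile`.
#' @export
pssm_profile <- function(scores, is_fallback = FALSE) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20 || nrow(scores) < 1) {
    stop("PSSM must have 20 columns and at least one row", call. = FALSE)
  }
  if (is_fallback && any(scores != 0)) {
    stop("a fallback PSSM must be all-zero", call. = FALSE)
  }
  colnames(scores) <- AA20
  structure(list(scores = scores, is_fallback = is_fallback),
            class = "pssm_profile")
}

#' All-zero fallback PSSM
#'
#' Sequences for which no homologue is found (so no profile can be computed)
#' are assigned an all-zero matrix; after sigmoid normalisation every element
#' is 0.5 and all its autocovariance features vanish.
#'
#' @param length sequence length (number of rows), at least 1.
#' @return a fallback [pssm_profile] of `length` x 20 zeros.
#' @export
zero_pssm <- function(length) {
  length <- as.integer(length)
  if (is.na(length) || length < 1) {
    stop("'length' must be a positive integer", call. = FALSE)
  }
  pssm_profile(matrix(0, nrow = length, ncol = 20), is_fallback = TRUE)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Reads the ASCII matrix dump produced by PSI-BLAST (`-out_ascii_pssm`):
#' header lines, then one row per residue whose first 20 numeric columns are
#' the log-odds scores. Columns are remapped from the header's residue order
#' (`A R N D C Q E G H I L K M F P S T W Y V`) to alphabetical order so that
#' downstream feature indices do not depend on the file dialect.
#'
#' @param path path to the PSSM file.
#' @param expected_length required number of rows (the sequence length).
#' @return a [pssm_profile] with `is_fallback = FALSE`.
#' @export
read_pssm <- function(path, expected_length) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  header_order <- NULL
  rows <- list()
  for (k in seq_along(lines)) {
    tok <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(tok) == 0 || !nzchar(tok[1])) next
    if (is.null(header_order)) {
      # header: 20 (or 40, scores + percentages) single residue letters
      if (length(tok) >= 20 && all(tok[1:20] %in% AA20) &&
          all(nchar(tok) == 1)) {
        header_order <- tok[1:20]
      }
      next
    }
    # data row: "<pos> <res> <20+ numbers ...>"
    if (grepl("^[0-9]+$", tok[1]) && length(tok) >= 22) {
      vals <- suppressWarnings(as.numeric(tok[3:22]))
      if (anyNA(vals)) {
        stop("malformed numeric field in PSSM row at line ", k, " of ", path,
             call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- vals
    }
  }
  if (is.null(header_order)) {
    stop("no residue-order header found in ", path,
         " (not a PSI-BLAST ASCII PSSM?)", call. = FALSE)
  }
  if (length(rows) != expected_length) {
    stop("PSSM ", path, " has ", length(rows), " rows but expected ",
         expected_length, call. = FALSE)
  }
  scores <- do.call(rbind, rows)
  colnames(scores) <- header_order
  pssm_profile(scores[, AA20, drop = FALSE], is_fallback = FALSE)
}

#' Write a PSSM profile in PSI-BLAST ASCII dialect
#'
#' Used by the synthetic benchmark generator and for fixture round-trips;
#' emits columns in the PSI-BLAST residue order so files are interchangeable
#' with real PSI-BLAST output as far as [read_pssm()] is concerned.
#'
#' @param pssm a [pssm_profile].
#' @param path output file path.
#' @param sequence optional sequence string used for the residue column
#'   (defaults to "A" everywhere).
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path, sequence = NULL) {
  stopifnot(inherits(pssm, "pssm_profile"))
  L <- nrow(pssm$scores)
  res <- if (is.null(sequence)) rep("A", L) else strsplit(sequence, "")[[1]]
  if (length(res) != L) {
    stop("sequence length does not match PSSM row count", call. = FALSE)
  }
  scores <- pssm$scores[, PSIBLAST_ORDER, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed",
               paste0("      ", paste(sprintf("%3s", PSIBLAST_ORDER),
                                      collapse = " "))),
             con)
  for (i in seq_len(L)) {
    writeLines(paste0(sprintf("%4d %s ", i, res[i]),
                      paste(sprintf("%3d", as.integer(round(scores[i, ]))),
                            collapse = " "),
                      " ", paste(rep("0", 2), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Read a two-column label table
#'
#' @param path tab-separated file with columns `id` and `class` (header
#'   optional).
#' @return named character vector mapping id to class.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 2) stop("label table needs two columns (id, class)",
                          call. = FALSE)
  if (identical(tolower(tab[1, 1]), "id")) tab <- tab[-1, , drop = FALSE]
  labels <- as.character(as_jtype(tab[[2]]))
  names(labels) <- tab[[1]]
  labels
}

#' Assemble a labelled dataset
#'
#' Attaches class labels to records and resolves a PSSM for every record:
#' from `pssm_dir/<id>.pssm` when present, otherwise the all-zero fallback
#' profile. The number of fallbacks applied is recorded on the returned
#' object and reported by its print method.
#'
#' @param records list of [protein_record] objects.
#' @param labels named character vector (id to class), e.g. from
#'   [read_labels()].
#' @param pssm_dir optional directory of `<id>.pssm` PSI-BLAST ASCII files.
#' @return an object of class `dnaj_dataset` with elements `records`
#'   (all labelled, all with a PSSM) and `class_counts`.
#' @export
assemble_dataset <- function(records, labels, pssm_dir = NULL) {
  ids <- vapply(records, function(r) r$id, character(1))
  missing <- setdiff(ids, names(labels))
  if (length(missing) > 0) {
    stop("no label for record(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n_fallback <- 0L
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    pssm <- r$pssm
    if (is.null(pssm) && !is.null(pssm_dir)) {
      f <- file.path(pssm_dir, paste0(r$id, ".pssm"))
      if (file.exists(f)) pssm <- read_pssm(f, nchar(r$sequence))
    }
    if (is.null(pssm)) {
      pssm <- zero_pssm(nchar(r$sequence))
      n_fallback <- n_fallback + 1L
    }
    out[[i]] <- protein_record(r$id, r$sequence, labels[[r$id]], pssm)
  }
  new_dataset(out, n_fallback = n_fallback)
}

# Internal constructor shared with the simulator.
new_dataset <- function(records, n_fallback = 0L) {
  labs <- vapply(records, function(r) r$label %||% NA_character_, character(1))
  if (anyNA(labs)) stop("all records in a dataset must be labelled",
                        call. = FALSE)
  counts <- table(factor(labs, levels = JTYPES))
  structure(list(records = records,
                 class_counts = stats::setNames(as.integer(counts),
                                                names(counts)),
                 n_fallback_pssm = as.integer(n_fallback)),
            class = "dnaj_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dnaj_dataset <- function(x, ...) {
  cat("J-protein dataset:", length(x$records), "sequences\n")
  cat("  class counts:",
      paste(names(x$class_counts), x$class_counts, sep = "=",
            collapse = ", "), "\n")
  cat("  fallback (all-zero) PSSMs:", x$n_fallback_pssm, "\n")
  invisible(x)
}

#' Sequence labels of a dataset
#' @param dataset a `dnaj_dataset`.
#' @return factor of class labels with levels I-IV.
#' @export
dataset_labels <- function(dataset) {
  as_jtype(vapply(dataset$records, function(r) r$label, character(1)))
}
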