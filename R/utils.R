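# Shared constants and small internal helpers.

# The 20 standard amino acids in alphabetical one-letter order. All feature
# blocks index residues in this order so feature names are stable.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residue column order printed by PSI-BLAST ASCII PSSM headers.
PSIBLAST_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# The four J-protein types.
JTYPES <- c("I", "II", "III", "IV")

#' Coerce labels to the J-protein type factor
#'
#' @param x character or factor of class labels.
#' @return factor with levels `c("I", "II", "III", "IV")`.
#' @keywords internal
#' @noRd
as_jtype <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), JTYPES)
  if (length(bad) > 0) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (expected I, II, III, IV)", call. = FALSE)
  }
  factor(x, levels = JTYPES)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library functions never perturb the
# user's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Display rounding used in reports: 0.8745 prints as 0.875 at 3 decimals,
#' unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.8745, 3)
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stop unless feature matrix-like input; returns a plain numeric matrix.
as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("feature input must be a numeric matrix or data frame", call. = FALSE)
  }
  x
}
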