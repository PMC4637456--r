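# Physicochemical property table used by the pseudo amino acid composition
# block. Twelve properties, one published AAindex scale per property; values
# are listed in alphabetical residue order (A C D E F G H I K L M N P Q R S
# T V W Y) and z-standardised over the 20 residues before use, so results do
# not depend on each scale's arbitrary units.

AA_PROPERTY_RAW <- local({
  m <- rbind(
    # hydrophobicity (Argos et al., 1982)
    ARGP820101 = c(0.61, 1.07, 0.46, 0.47, 2.02, 0.07, 0.61, 2.22, 1.15, 1.53,
                   1.18, 0.06, 1.95, 0.00, 0.60, 0.05, 0.05, 1.32, 2.65, 1.88),
    # hydrophilicity (Hopp-Woods, 1981)
    HOPT810101 = c(-0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0, -1.8,
                   -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5, -3.4, -2.3),
    # average accessible surface area (Janin et al., 1978)
    JANJ780101 = c(27.8, 15.5, 60.6, 68.2, 25.5, 24.5, 50.7, 22.8, 103.0, 27.6,
                   33.5, 60.1, 51.5, 68.7, 94.7, 42.0, 45.0, 23.7, 34.7, 55.2),
    # average flexibility indices (Bhaskaran-Ponnuswamy, 1988)
    BHAR880101 = c(0.357, 0.346, 0.511, 0.497, 0.314, 0.544, 0.323, 0.462,
                   0.466, 0.365, 0.295, 0.463, 0.509, 0.493, 0.529, 0.507,
                   0.444, 0.386, 0.305, 0.420),
    # net charge (Klein et al., 1984)
    KLEP840101 = c(0, 0, -1, -1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 1, 0, 0, 0,
                   0, 0),
    # side chain volume (Krigbaum-Komoriya, 1979)
    KRIW790103 = c(27.5, 44.6, 40.0, 62.0, 115.5, 0.0, 79.0, 93.5, 100.0, 93.5,
                   94.1, 58.7, 41.9, 80.7, 105.0, 29.3, 51.3, 71.5, 145.5,
                   117.3),
    # polarity (Grantham, 1974)
    GRAR740102 = c(8.1, 5.5, 13.0, 12.3, 5.2, 9.0, 10.4, 5.2, 11.3, 4.9, 5.7,
                   11.6, 8.0, 10.5, 10.5, 9.2, 8.6, 5.9, 5.4, 6.2),
    # heat capacity (Hutchens, 1970)
    HUTJ700101 = c(29.22, 50.70, 37.09, 41.84, 48.52, 23.71, 59.64, 45.00,
                   57.10, 48.03, 69.32, 38.30, 36.13, 44.02, 26.37, 32.40,
                   35.20, 40.35, 56.92, 51.73),
    # isoelectric point (Zimmerman et al., 1968)
    ZIMJ680104 = c(6.00, 5.05, 2.77, 3.22, 5.48, 5.97, 7.59, 6.02, 9.74, 5.98,
                   5.74, 5.41, 6.30, 5.65, 10.76, 5.68, 5.66, 5.96, 5.89,
                   5.66),
    # transfer free energy to surface (Bull-Breese, 1974)
    BULH740101 = c(-0.20, -0.45, -0.20, -0.30, -2.33, 0.00, -0.12, -2.26,
                   -0.35, -2.46, -1.47, 0.08, -0.98, 0.16, -0.12, -0.39,
                   -0.52, -1.56, -2.01, -2.24),
    # normalized van der Waals volume (Fauchere et al., 1988)
    FAUJ880103 = c(1.00, 2.43, 2.78, 3.78, 5.89, 0.00, 4.66, 4.00, 4.77, 4.00,
                   4.43, 2.95, 2.72, 3.95, 6.13, 1.60, 2.60, 3.00, 8.08, 6.47),
    # side chain interaction parameter (Krigbaum-Komoriya, 1979)
    KRIW790101 = c(4.32, 1.73, 6.04, 6.17, 2.59, 6.09, 5.66, 2.31, 7.92, 3.93,
                   2.44, 6.24, 7.19, 6.13, 6.55, 5.37, 5.16, 3.31, 2.78, 3.58)
  )
  colnames(m) <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  t(m) # 20 residues x 12 properties
})

#' Physicochemical property table
#'
#' Twelve amino-acid property scales (hydrophobicity, hydrophilicity, average
#' accessible surface area, average flexibility, net charge, side chain
#' volume, polarity, heat capacity, isoelectric point, transfer free energy
#' to surface, van der Waals volume, side chain interaction parameter), each
#' a published AAindex entry identified by its accession in the column names.
#'
#' @param standardize z-standardise each property over the 20 residues
#'   (default `TRUE`; the convention assumed by the pseudo amino acid
#'   composition block, which makes features invariant to each scale's units).
#' @return a 20 x 12 numeric matrix, residues (alphabetical) by properties;
#'   attribute `property_ids` holds the AAindex accessions.
#' @export
#' @examples
#' p <- aa_properties()
#' colMeans(p) # ~0 for every property
aa_properties <- function(standardize = TRUE) {
  m <- AA_PROPERTY_RAW
  if (standardize) {
    m <- scale(m)
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
    # population-sd standardisation is irrelevant to downstream covariances
    # (any common factor cancels into an overall scale); sample sd is used.
  }
  structure(m, property_ids = colnames(m))
}
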