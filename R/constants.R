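# Physicochemical constant tables. The same values are shipped as documented
# TSVs under inst/extdata/ (residue_masses.tsv, hydropathy.tsv, pka.tsv);
# the in-code vectors are the single source of truth.

#' Amino-acid alphabet used throughout
#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Monoisotopic residue masses (Da)
#'
#' Masses of amino-acid residues (i.e. minus one water) used for peptide
#' molecular-weight computation in a mass-spectrometry context.
#' @format Named numeric vector, one entry per residue letter.
#' @export
MONOISOTOPIC_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Mass of water (monoisotopic, Da), added once per peptide chain
#' @export
WATER_MONO <- 18.010565

#' Kyte-Doolittle hydropathy scale
#'
#' The scale that defines the GRAVY (grand average of hydropathy) score:
#' GRAVY is the arithmetic mean of these values over a sequence.
#' @format Named numeric vector in \[-4.5, 4.5\].
#' @export
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Default pKa table (Bjellqvist values) for isoelectric-point prediction
#'
#' `positive` groups gain a proton below their pKa (N-terminus, H, K, R);
#' `negative` groups lose one above it (C-terminus, C, D, E, Y). Any table
#' with the same two-component structure can be supplied to
#' [peptide_properties()].
#' @format List with numeric vectors `positive` and `negative`.
#' @export
PKA_BJELLQVIST <- list(
  positive = c(Nterm = 7.50, H = 5.98, K = 10.00, R = 12.00),
  negative = c(Cterm = 3.55, C = 9.00, D = 4.05, E = 4.45, Y = 10.00)
)

# internal: validate an amino-acid sequence, error names offending residue
check_sequence <- function(sequence, what = "sequence") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad)) {
    stop(sprintf("invalid residue '%s' at position %d in %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  }
  chars
}
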