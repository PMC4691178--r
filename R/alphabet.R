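#' Canonical amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes in alphabetical order. All
#' descriptors and PSSM columns in this package are indexed 1..20 against
#' this ordering, so column 1 is always alanine (A) and column 20 tyrosine
#' (Y), regardless of the ordering used by the file a matrix was read from.
#'
#' @return Character vector of length 20.
#' @examples
#' residue_alphabet()
#' match("R", residue_alphabet())  # arginine is residue index 15
#' @export
residue_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# PSI-BLAST writes its 20 score columns in this residue order; readers remap
# them into the alphabetical canonical order above.
PSIBLAST_COLUMN_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Residue physico-chemical scales used by PseAAC
#'
#' Hydrophobicity (Tanford-style) and hydrophilicity (Hopp–Woods-style)
#' values for the 20 standard residues, in canonical alphabetical order.
#' [encode_pseaac()] standardizes each scale to zero mean and unit
#' (population) standard deviation across the 20 residues before computing
#' sequence-order correlation factors; `standardize = TRUE` returns the
#' standardized values.
#'
#' @param standardize Logical; return the zero-mean, unit-SD version.
#' @return A list with numeric vectors `hydrophobicity` and
#'   `hydrophilicity`, each named by residue.
#' @examples
#' sc <- pseaac_scales(standardize = TRUE)
#' mean(sc$hydrophobicity)  # ~0
#' @export
pseaac_scales <- function(standardize = FALSE) {
  aa <- residue_alphabet()
  h1 <- c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19,
          G = 0.48, H = -0.40, I = 1.38, K = -1.50, L = 1.06,
          M = 0.64, N = -0.78, P = 0.12, Q = -0.85, R = -2.53,
          S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26)
  h2 <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5,
          G = 0.0, H = -0.5, I = -1.8, K = 3.0, L = -1.8,
          M = -1.3, N = 0.2, P = 0.0, Q = 0.2, R = 3.0,
          S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
  h1 <- h1[aa]
  h2 <- h2[aa]
  if (standardize) {
    h1 <- standardize_scale(h1)
    h2 <- standardize_scale(h2)
  }
  list(hydrophobicity = h1, hydrophilicity = h2)
}

# Center and scale to unit *population* SD (denominator 20), the convention
# used for pseudo-amino-acid correlation scales.
standardize_scale <- function(h) {
  h <- h - mean(h)
  h / sqrt(mean(h^2))
}

# map a sequence string to canonical residue indices 1..20; NA for unknowns
residue_indices <- function(sequence) {
  match(strsplit(sequence, "", fixed = TRUE)[[1]], residue_alphabet())
}
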