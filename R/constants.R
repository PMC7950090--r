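# Monoisotopic masses. Residue masses are the standard 20 amino-acid residues
# (peptide-bond residues, i.e. amino acid minus water).

#' Monoisotopic residue masses for the 20 standard amino acids
#'
#' Named numeric vector of peptide-bond residue masses in daltons
#' (free amino acid minus water).
#'
#' @format Named numeric vector of length 20 (one-letter codes).
#' @export
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

PROTON_MASS <- 1.00727646688
WATER_MASS  <- 18.0105646863
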