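# Physical constants used throughout the package. All masses are
# monoisotopic, in Daltons, stated to at least 9 decimals.

#' @keywords internal
PROTON_MASS <- 1.00727646688

#' @keywords internal
WATER_MASS <- 18.010564686

# Monoisotopic masses of the 20 standard amino-acid residues
# (peptide-bond residues, i.e. the free amino acid minus water).
#' @keywords internal
RESIDUE_MASS <- c(
  G = 57.021463721,
  A = 71.037113786,
  S = 87.032028409,
  P = 97.052763851,
  V = 99.068413915,
  T = 101.047678473,
  C = 103.009184477,
  L = 113.084063980,
  I = 113.084063980,
  N = 114.042927446,
  D = 115.026943025,
  Q = 128.058577510,
  K = 128.094963016,
  E = 129.042593090,
  M = 131.040484605,
  H = 137.058911861,
  F = 147.068413915,
  R = 156.101111026,
  Y = 163.063328537,
  W = 186.079312952
)

# Monoisotopic element masses, used to derive modification delta masses
# from elemental composition rather than hard-coding them.
#' @keywords internal
ELEMENT_MASS <- c(
  H = 1.007825032,
  C = 12.0,
  N = 14.003074005,
  O = 15.994914620,
  S = 31.972071000
)

#' @keywords internal
AA_ALPHABET <- names(RESIDUE_MASS)
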