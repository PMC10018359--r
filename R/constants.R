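# Physical constants (CGS units) and residue mass tables.
#
# Unit conventions used throughout the package:
#   length cm, time s, mass g, energy erg; sedimentation coefficients in
#   Svedberg (1 S = 1e-13 s); molar masses g/mol; densities g/ml;
#   viscosities poise; angular velocity omega = 2*pi*rpm/60.

#' @keywords internal
GAS_CONSTANT_ERG <- 8.31446e7    # erg mol^-1 K^-1

#' @keywords internal
AVOGADRO <- 6.02214076e23        # mol^-1

#' @keywords internal
BOLTZMANN_ERG <- GAS_CONSTANT_ERG / AVOGADRO  # erg K^-1

#' @keywords internal
SVEDBERG <- 1e-13                # s

WATER_MASS <- 18.02              # g/mol, terminal H2O of a peptide chain

# Average amino-acid residue masses (g/mol), residue = free amino acid - H2O.
AA_RESIDUE_MASS <- c(
  G = 57.05,  A = 71.08,  S = 87.08,  P = 97.12,  V = 99.13,
  T = 101.10, C = 103.14, L = 113.16, I = 113.16, N = 114.10,
  D = 115.09, Q = 128.13, K = 128.17, E = 129.12, M = 131.20,
  H = 137.14, F = 147.18, R = 156.19, Y = 163.18, W = 186.21
)

# Average 2'-deoxyribonucleoside masses (g/mol).
DNA_NUCLEOSIDE_MASS <- c(A = 251.24, C = 227.22, G = 267.24, T = 242.23)

# Mass added per internal phosphodiester linkage: HPO3 (79.98) - H2O (18.02).
DNA_LINKAGE_MASS <- 61.96

# Documented adduct masses (g/mol). Cy3 is the phosphoramidite-coupled dye
# as delivered on a synthetic oligonucleotide terminus (dye + phosphate
# linker); end chemistry otherwise 5'-OH / 3'-OH.
ADDUCT_MASS <- c(cy3 = 507.3)
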