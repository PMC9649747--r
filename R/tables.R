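# Bundled constant tables: amino-acid codes, Kyte-Doolittle hydropathy,
# average residue masses, van der Waals radii, side-chain sphere radii.

# 3-letter -> 1-letter for the 20 standard residues
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA_123 <- setNames(names(AA_321), unname(AA_321))

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values (Ile +4.5 ... Arg -4.5) used throughout the
#' package for sliding-window hydropathy, tunnel-lining hydrophobicity and
#' hydrophobic moments. Named by 1-letter amino-acid code.
#'
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' kd_scale()[["I"]]  # 4.5
kd_scale <- function() {
  c(
    I =  4.5, V =  4.2, L =  3.8, F =  2.8, C =  2.5,
    M =  1.9, A =  1.8, G = -0.4, T = -0.7, S = -0.8,
    W = -0.9, Y = -1.3, P = -1.6, H = -3.2, E = -3.5,
    Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
  )
}

# IUPAC average residue masses (monomer minus water), Daltons
AA_RESIDUE_MASS <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167, V =  99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

WATER_MASS <- 18.0153

# van der Waals radii by element (Angstrom); unknown elements fall back to
# carbon. Structure predictors emit heavy atoms only, so H is rarely seen.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
VDW_DEFAULT <- 1.70

vdw_radius_of <- function(element) {
  element <- toupper(trimws(as.character(element)))
  r <- unname(VDW_RADII[element])
  r[is.na(r)] <- VDW_DEFAULT
  r
}

# Volume-equivalent single-sphere radii for side chains (Angstrom), used by
# the pseudo-side-chain mutation model. Coarse by design: one sphere stands
# in for the whole side chain.
SIDECHAIN_RADIUS <- c(
  G = 1.0, A = 1.8, S = 2.0, C = 2.2, T = 2.3, P = 2.4, V = 2.5,
  L = 2.7, I = 2.7, N = 2.8, D = 2.8, M = 2.9, H = 3.0, E = 3.1,
  Q = 3.1, K = 3.2, F = 3.2, R = 3.4, Y = 3.4, W = 3.6
)

aa_three_to_one <- function(resid) {
  out <- unname(AA_321[toupper(resid)])
  out[is.na(out)] <- "X"
  out
}

aa_one_to_three <- function(aa) {
  out <- unname(AA_123[toupper(aa)])
  out[is.na(out)] <- "UNK"
  out
}
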