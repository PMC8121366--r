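# Internal lookup tables: van der Waals radii, atomic masses and electron
# counts, average amino-acid residue masses and residue electron counts.
# Radii follow common Shrake-Rupley practice (C 1.70, N 1.55, O 1.52,
# S 1.80 A); hydrogens carry 1.20 A but are excluded from SASA by default.

.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
)

.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, SE = 78.971
)

.atomic_electrons <- c(
  H = 1, C = 6, N = 7, O = 8, S = 16, P = 15,
  F = 9, CL = 17, BR = 35, I = 53, SE = 34
)

# Average (not monoisotopic) residue masses in Da (residue = amino acid - H2O).
.residue_masses <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

.water_mass <- 18.01528

# Electron counts of amino-acid residues (sum of atomic numbers of the
# residue formula), used as per-residue scattering weights in the Debye sum.
.residue_electrons <- c(
  G = 30, A = 38, S = 46, P = 52, V = 54, T = 54, C = 54,
  L = 62, I = 62, N = 60, D = 60, Q = 68, K = 70, E = 68,
  M = 70, H = 72, F = 78, R = 84, Y = 86, W = 98
)

.aa_standard <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "U", PYL = "O"
)

.aa_one_to_three <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

# Charged-group atoms for salt-bridge detection (basic vs acidic side chains).
.saltbridge_basic <- list(
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2")
)
.saltbridge_acidic <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
)

# Homologue-retrieval settings used upstream of the conservation pipeline
# (BLAST e-value <= 1e-10; staged iterative PSI-BLAST thresholds). Retrieval
# itself is out of scope; the constants are recorded for provenance.
#' Homologue retrieval configuration constants
#'
#' E-value acceptance thresholds used when collecting homologue sets upstream
#' of the conservation pipeline (single-pass search, and the three stages of
#' an iterative profile search). Sequence retrieval and alignment are inputs
#' to this package, not computed by it; the constants document the intended
#' provenance of input alignments.
#'
#' @return Named list with `blast_evalue` and `psiblast_stage_evalues`.
#' @export
retrieval_config <- function() {
  list(
    blast_evalue = 1e-10,
    psiblast_stage_evalues = c(1e-20, 1e-10, 1e-8),
    psiblast_max_iterations_per_stage = 4L
  )
}
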