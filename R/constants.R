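# Bundled lookup tables: element radii, accessibility references and
# per-amino-acid physicochemical scales used by the encoders.

#' @keywords internal
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @keywords internal
AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
         MSE = "M", SEC = "C", PYL = "K")

# Heavy-atom van der Waals radii (Angstrom). Hydrogens are ignored
# (united-atom convention); unknown elements fall back to carbon.
#' @keywords internal
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

#' @keywords internal
VDW_DEFAULT <- 1.70

# Theoretical maximum solvent accessibility per residue type
# (Tien et al. 2013, "theoretical" column, Angstrom^2); denominator of the
# relative accessibility (RASA) used by the 25% surface rule.
#' @keywords internal
MAX_ASA <- c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
             Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
             L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
             S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)

# Atchley et al. (2005) multivariate amino-acid factor scores.
# Columns: factor I (polarity), II (secondary-structure propensity),
# III (molecular size/volume), IV (codon composition/diversity),
# V (electrostatic charge).
#' @keywords internal
ATCHLEY <- matrix(c(
  -0.591, -1.302, -0.733,  1.570, -0.146,  # A
   1.538, -0.055,  1.502,  0.440,  2.897,  # R
   0.945,  0.828,  1.299, -0.169,  0.933,  # N
   1.050,  0.302, -3.656, -0.259, -3.242,  # D
  -1.343,  0.465, -0.862, -1.020, -0.255,  # C
   0.931, -0.179, -3.005, -0.503, -1.853,  # Q
   1.357, -1.453,  1.477,  0.113, -0.837,  # E
  -0.384,  1.652,  1.330,  1.045,  2.064,  # G
   0.336, -0.417, -1.673, -1.474, -0.078,  # H
  -1.239, -0.547,  2.131,  0.393,  0.816,  # I
  -1.019, -0.987, -1.505,  1.266, -0.912,  # L
   1.831, -0.561,  0.533, -0.277,  1.648,  # K
  -0.663, -1.524,  2.219, -1.005,  1.212,  # M
  -1.006, -0.590,  1.891, -0.397,  0.412,  # F
   0.189,  2.081, -1.628,  0.421, -1.392,  # P
  -0.228,  1.399, -4.760,  0.670, -2.647,  # S
  -0.032,  0.326,  2.213,  0.908,  1.313,  # T
  -0.595,  0.009,  0.672, -2.128, -0.184,  # W
   0.260,  0.830,  3.097, -0.838,  1.512,  # Y
  -1.337, -0.279, -0.544,  1.242, -1.262   # V
), nrow = 20, byrow = TRUE,
  dimnames = list(AA1, paste0("atchley_f", 1:5)))

# Kyte & Doolittle (1982) hydropathy scale.
#' @keywords internal
KD_SCALE <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
              Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
              L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
              S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# PSI-BLAST PSSM column order.
#' @keywords internal
PSSM_COLS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Default named layout of the 11-column 3D structural descriptor block.
#' @keywords internal
STRUCT_COLS <- c("asa", "rasa", "dpx_avg", "cx_avg", "angle_s", "curvature",
                 "hydrophobicity", "msa", "struct_x1", "struct_x2", "struct_x3")
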