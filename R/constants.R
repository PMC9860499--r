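# Frozen per-residue constants for the four scales the classifier uses.
# Values are embedded (not loaded at run time) so that classification is
# reproducible bit-for-bit. Order: A R N D C Q E G H I L K M F P S T W Y V.

# Normalized frequency of reverse (beta) turn, with weights; Levitt (1978)
# Biochemistry 17:4277. AAindex accession LEVM780103.
.BETA_TURN_VALUES <- c(
  A = 0.77, R = 0.88, N = 1.28, D = 1.41, C = 0.81, Q = 0.98, E = 0.99,
  G = 1.64, H = 0.68, I = 0.51, L = 0.58, K = 0.96, M = 0.41, F = 0.59,
  P = 1.91, S = 1.32, T = 1.04, W = 0.76, Y = 1.05, V = 0.47)

# Helix propensity used by the P/D discriminant: average relative fractional
# occurrence of the right-handed helical backbone state A^R(i)
# (Rackovsky & Scheraga 1982, Macromolecules 15:1340). AAindex accession
# RACS820102. This is the unique AAindex scale that, combined with the PPII
# propensities below and the published P/D boundary, reproduces the
# published three-way homopolymer partition of the 20 amino acids.
.HELIX_VALUES <- c(
  A = 1.58, R = 1.14, N = 0.77, D = 0.98, C = 1.04, Q = 1.24, E = 1.49,
  G = 0.66, H = 0.99, I = 1.09, L = 1.21, K = 1.27, M = 1.41, F = 1.00,
  P = 1.46, S = 1.05, T = 0.87, W = 1.23, Y = 0.68, V = 0.88)

# Interactivity (structure-based hydrophobicity) scale obtained by
# maximizing the mean correlation coefficient over single-domain globular
# proteins; Bastolla, Porto, Roman & Vendruscolo (2005) Proteins 58:22.
# AAindex accession BASU050102.
.PHI_VALUES <- c(
  A =  0.0728, R =  0.0394, N = -0.0390, D = -0.0552, C = 0.3557,
  Q =  0.0126, E = -0.0295, G = -0.0589, H =  0.0874, I = 0.3805,
  L =  0.3819, K = -0.0053, M =  0.1613, F =  0.4201, P = -0.0492,
  S = -0.0282, T =  0.0239, W =  0.4114, Y =  0.3113, V = 0.2947)

# Experimental polyproline-II propensities measured in unfolded GGXGG host
# peptides (Shi, Chen, Liu, Ng, Bracken & Kallenbach 2005, PNAS 102:17964),
# with Gly = 0.500 and Pro = 1.000 assigned by convention for the two
# unmeasured residues (Tomasso et al. 2016, PLoS Comput Biol 12:e1004686).
.PPII_VALUES <- c(
  A = 0.818, R = 0.638, N = 0.667, D = 0.552, C = 0.557, Q = 0.654,
  E = 0.684, G = 0.500, H = 0.428, I = 0.519, L = 0.574, K = 0.581,
  M = 0.498, F = 0.639, P = 1.000, S = 0.774, T = 0.553, W = 0.764,
  Y = 0.630, V = 0.743)

# Side-chain charge at neutral pH: +1 for K/R, -1 for D/E, 0 otherwise
# (histidine treated as neutral).
.CHARGE_VALUES <- c(
  A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0, H = 0, I = 0,
  L = 0, K = 1, M = 0, F = 0, P = 0, S = 0, T = 0, W = 0, Y = 0, V = 0)

#' Classifier constants
#'
#' The frozen decision constants of the window classifier, returned as a
#' named list so that every classification records the exact configuration
#' it used. Any change is an explicit versioned configuration, never a
#' silent edit.
#'
#' \describe{
#'   \item{windowLength}{25 residues}
#'   \item{phiCutoff}{0.08; a window is labeled F when its mean
#'     hydrophobicity phi exceeds this (strictly)}
#'   \item{phiFoldedMean}{0.1164; mean phi of the folded training set, so F
#'     distances are normalized by 0.1164 - 0.08 = 0.0364}
#'   \item{pdSlope, pdIntercept}{the P/D boundary
#'     v_model = -0.244 * alpha + 0.789}
#'   \item{pdNorm}{0.019; perpendicular distance from the boundary to
#'     either training-set mean, the unit of P/D classifier distance}
#'   \item{vizOrigin}{(v_model, beta-turn) = (0.558, 1.101), the
#'     disordered-set means used as the origin of the polar visualization}
#'   \item{minRegionLength, purity}{region-calling defaults, 20 and 0.9}
#' }
#'
#' @param version currently only `"v2"`
#' @return named list of constants
#' @export
classifierConstants <- function(version = "v2") {
  stopifnot(identical(version, "v2"))
  list(version = version,
       windowLength = 25L,
       phiCutoff = 0.08,
       phiFoldedMean = 0.1164,
       pdSlope = -0.244,
       pdIntercept = 0.789,
       pdNorm = 0.019,
       vizOrigin = c(vModel = 0.558, betaTurn = 1.101),
       minRegionLength = 20L,
       purity = 0.9)
}

# Hydrodynamic-radius model constants (disordered monomeric chains):
# Rh = 2.16 * N^(0.503 - 0.11*ln(fPPII)) + 0.26*|Qnet| - 0.29*N^0.5  [Angstrom]
.RH_R0 <- 2.16
.RH_NU0 <- 0.503
.RH_NU_LNF <- 0.11
.RH_QNET <- 0.26
.RH_SQRTN <- 0.29

# Universal gas constant, J mol^-1 K^-1, and the standard temperature (K)
# at which the standard free energy of phase separation is reported.
.GAS_R <- 8.314
.THERMO_T0 <- 273.15
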