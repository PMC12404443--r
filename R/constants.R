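# Amino-acid reference tables used across the package.

# three-letter <-> one-letter
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
  Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
  L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
  S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val"
)
AA_ONE <- setNames(names(AA_THREE), AA_THREE)
# PDB residue names are deposited in upper case
AA_ONE_UPPER <- setNames(names(AA_THREE), toupper(AA_THREE))

# Theoretical maximum accessible surface areas (A^2) per residue type
# (Tien et al. 2013, theoretical values), used to turn absolute SASA into
# fractional SASA (relative solvent accessibility).
MAX_ASA <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

# Partial molar side-chain volumes (ml/mole). The Met/Ile/Val triplet is the
# scale relevant to side-chain packing arguments in TRPV1 ankyrin repeats 4-5.
SIDECHAIN_VOLUME <- c(
  G = 43.3, A = 60.5, S = 60.6, C = 73.4, D = 74.8, T = 76.9,
  N = 78.0, P = 82.8, E = 89.9, V = 91.3, Q = 93.9, H = 98.8,
  M = 105.1, I = 107.5, L = 107.7, K = 108.5, F = 121.5,
  Y = 123.6, R = 127.3, W = 143.8
)

# Van der Waals radii per element (A); Bondi-type values for the elements
# that occur in protein heavy atoms. Unknown elements fall back to 1.8 A.
VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, H = 1.20, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)
VDW_DEFAULT <- 1.8

#' Amino-acid reference properties
#'
#' Per-residue reference values used throughout the package: the theoretical
#' maximum accessible surface area that normalizes absolute SASA into
#' fractional SASA, and partial molar side-chain volumes (the property that
#' separates tolerated from activity-changing substitutions at buried
#' positions such as TRPV1 M308: Met 105.1, Ile 107.5, Val 91.3 ml/mole).
#'
#' @return A tibble with columns `aa` (one-letter code), `aa3` (three-letter
#'   code), `max_asa` (A^2) and `sidechain_volume` (ml/mole).
#' @export
#' @examples
#' amino_acid_properties()
amino_acid_properties <- function() {
  tibble(
    aa = names(AA_THREE),
    aa3 = unname(AA_THREE),
    max_asa = unname(MAX_ASA[names(AA_THREE)]),
    sidechain_volume = unname(SIDECHAIN_VOLUME[names(AA_THREE)])
  )
}

# element -> vdW radius, warning once per unknown element set
vdw_radius <- function(element) {
  element <- toupper(trimws(element))
  r <- unname(VDW_RADII[element])
  if (anyNA(r)) {
    unknown <- unique(element[is.na(r)])
    warn(sprintf(
      "unknown element(s) %s: using default van der Waals radius %.1f A",
      paste(unknown, collapse = ", "), VDW_DEFAULT
    ))
    r[is.na(r)] <- VDW_DEFAULT
  }
  r
}
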