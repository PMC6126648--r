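# Bundled standard protein geometry: ideal bond lengths / angles with
# sigmas in the Engh & Huber style, peptide-plane and chirality targets,
# element electron counts, and internal-coordinate side-chain templates
# used both for restraint generation and for building ideal fixtures.

#' Amino-acid code maps
#'
#' Named vectors translating between 3-letter and 1-letter residue codes for
#' the 20 standard amino acids plus selenomethionine (MSE, coded M).
#'
#' @name aa_codes
#' @keywords internal
NULL

#' @rdname aa_codes
aa_3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", MSE = "M", PHE = "F", PRO = "P", SER = "S", THR = "T",
  TRP = "W", TYR = "Y", VAL = "V"
)

#' @rdname aa_codes
aa_1to3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

# Backbone atom names. CB is counted as main chain in clash analysis
# because its position is fixed by the backbone conformation.
BACKBONE_NAMES <- c("N", "CA", "C", "O")
MAINCHAIN_CLASH_NAMES <- c("N", "CA", "C", "O", "CB", "OXT")

# Electrons per element, for Gaussian-atom density synthesis.
ELEMENT_ELECTRONS <- c(
  H = 1, C = 6, N = 7, O = 8, S = 16, SE = 34, P = 15
)

# Residue codes treated as water.
WATER_CODES <- c("HOH", "WAT", "DOD")

# Deletable "exception" ligands: glycerol, ethanol, 1,2-ethanediol and
# PEG-like polymeric forms. Configurable through loopgraft_config().
EXCEPTION_LIGAND_CODES <- c("GOL", "EOH", "EDO", "PEG", "PGE", "PG4",
                            "P6G", "1PE", "2PE", "7PE", "PE3", "PE4")

#' Standard protein geometry table
#'
#' Ideal main-chain bond lengths, bond angles, peptide-plane and chirality
#' targets with their sigmas. Bonds named `C-N+` / angles involving `N+`
#' span the peptide bond to the following residue.
#'
#' @return A list with elements `bonds` (tibble: atom names, target, sigma),
#'   `angles` (tibble), `sigma_plane` (angstrom), `sigma_omega` (degrees),
#'   `chiral_target` / `sigma_chiral` (cubic angstrom) and `sigma_generic`
#'   values used for side-chain restraints.
#' @export
protein_geometry <- function() {
  bonds <- tibble::tribble(
    ~a, ~b, ~target, ~sigma,
    "N", "CA", 1.458, 0.019,
    "CA", "C", 1.525, 0.021,
    "C", "O", 1.231, 0.020,
    "C", "N+", 1.329, 0.014,
    "CA", "CB", 1.530, 0.020,
    "C", "OXT", 1.249, 0.019
  )
  angles <- tibble::tribble(
    ~a, ~b, ~c, ~target, ~sigma,
    "N", "CA", "C", 111.2, 2.8,
    "CA", "C", "N+", 116.2, 2.0,
    "C-", "N", "CA", 121.7, 1.8,
    "CA", "C", "O", 120.8, 1.7,
    "O", "C", "N+", 123.0, 1.6,
    "N", "CA", "CB", 110.4, 1.5,
    "CB", "CA", "C", 110.5, 1.5
  )
  list(
    bonds = bonds,
    angles = angles,
    sigma_plane = 0.02,
    sigma_omega = 3.0,
    chiral_target = ideal_ca_chiral_volume(),
    sigma_chiral = 0.2,
    sigma_bond_generic = 0.02,
    sigma_angle_generic = 2.0
  )
}

# Ideal C-alpha chiral volume computed from the ideal bonds/angles so that
# fragments built from this table score exactly zero. Memoised.
ideal_ca_chiral_volume <- local({
  cached <- NULL
  function() {
    if (!is.null(cached)) return(cached)
    # place CA at origin, N along x, C in xy plane; CB from its two angles
    n <- c(1.458, 0, 0)
    ang_nc <- 111.2 * pi / 180
    c_ <- 1.525 * c(cos(ang_nc), sin(ang_nc), 0)
    # CB direction: angles to N (110.4) and C (110.5); z > 0 for L chirality
    u <- n / 1.458; v <- c_ / 1.525
    cn <- cos(110.4 * pi / 180); cc <- cos(110.5 * pi / 180)
    # solve d . u = cn, d . v = cc, |d| = 1
    a11 <- 1; a12 <- sum(u * v); a22 <- 1
    det <- a11 * a22 - a12^2
    l1 <- (cn - a12 * cc) / det
    l2 <- (cc - a12 * cn) / det
    dpar <- l1 * u + l2 * v
    dz <- sqrt(max(0, 1 - sum(dpar^2)))
    cb <- 1.530 * (dpar + dz * c(0, 0, 1))
    vol <- chiral_volume(c(0, 0, 0), n, c_, cb)
    cached <<- abs(vol)  # positive target; sign convention (N, C, CB)
    cached
  }
})

# Internal-coordinate side-chain templates: each row places atom `name`
# from reference atoms a-b-c (NeRF) with the given bond length, angle at c
# and torsion a-b-c-name. One canonical rotamer per residue (chi1 = -60
# where applicable). Rows are ordered so references always exist.
sidechain_template <- function(resname) {
  t <- SIDECHAIN_TEMPLATES[[resname]]
  if (is.null(t)) return(NULL)
  t
}

sc_row <- function(name, el, a, b, c, bond, angle, tors) {
  data.frame(name = name, el = el, a = a, b = b, c = c,
             bond = bond, angle = angle, tors = tors,
             stringsAsFactors = FALSE)
}

# CB improper torsion C-N-CA-CB; sign fixed so the C-alpha chiral volume
# over (N, C, CB) is positive (L-amino acid).
CB_ROW <- sc_row("CB", "C", "C", "N", "CA", 1.530, 110.4, 122.6)

SIDECHAIN_TEMPLATES <- list(
  GLY = NULL,
  ALA = CB_ROW,
  SER = rbind(CB_ROW, sc_row("OG", "O", "N", "CA", "CB", 1.417, 110.8, -60)),
  CYS = rbind(CB_ROW, sc_row("SG", "S", "N", "CA", "CB", 1.808, 113.8, -60)),
  THR = rbind(CB_ROW,
              sc_row("OG1", "O", "N", "CA", "CB", 1.433, 109.6, -60),
              sc_row("CG2", "C", "N", "CA", "CB", 1.521, 110.5, 62)),
  VAL = rbind(CB_ROW,
              sc_row("CG1", "C", "N", "CA", "CB", 1.521, 110.5, 180),
              sc_row("CG2", "C", "N", "CA", "CB", 1.521, 110.5, 58)),
  ILE = rbind(CB_ROW,
              sc_row("CG1", "C", "N", "CA", "CB", 1.530, 110.4, -60),
              sc_row("CG2", "C", "N", "CA", "CB", 1.521, 110.5, 178),
              sc_row("CD1", "C", "CA", "CB", "CG1", 1.513, 113.8, 170)),
  LEU = rbind(CB_ROW,
              sc_row("CG", "C", "N", "CA", "CB", 1.530, 116.3, -60),
              sc_row("CD1", "C", "CA", "CB", "CG", 1.521, 110.7, 180),
              sc_row("CD2", "C", "CA", "CB", "CG", 1.521, 110.7, 60)),
  ASP = rbind(CB_ROW,
              sc_row("CG", "C", "N", "CA", "CB", 1.516, 112.6, -60),
              sc_row("OD1", "O", "CA", "CB", "CG", 1.249, 118.4, -20),
              sc_row("OD2", "O", "CA", "CB", "CG", 1.249, 118.4, 160)),
  ASN = rbind(CB_ROW,
              sc_row("CG", "C", "N", "CA", "CB", 1.516, 112.6, -60),
              sc_row("OD1", "O", "CA", "CB", "CG", 1.231, 120.8, -20),
              sc_row("ND2", "N", "CA", "CB", "CG", 1.328, 116.4, 160)),
  GLU = rbind(CB_ROW,
              sc_row("CG", "C", "N", "CA", "CB", 1.520, 114.1, -60),
              sc_row("CD", "C", "CA", "CB", "CG", 1.516, 112.6, 180),
              sc_row("OE1", "O", "CB", "CG", "CD", 1.249, 118.4, -20),
              sc_row("OE2", "O", "CB", "CG", "CD", 1.249, 118.4, 160)),
  GLN = rbind(CB_ROW,
              sc_row("CG", "C", "N", "CA", "CB", 1.520, 114.1, -60),
              sc_row("CD", "C", "CA", "CB", "CG", 1.516, 112.6, 180),
              sc_row("OE1", "O", "CB", "CG", "CD", 1.231, 120.8, -20),
              sc_row("NE2", "N", "CB", "CG", "CD", 1.328, 116.4, 160)),
  MET = rbind(CB_ROW,
              sc_row("CG", "C", "N", "CA", "CB", 1.520, 114.1, -60),
              sc_row("SD", "S", "CA", "CB", "CG", 1.803, 112.7, 180),
              sc_row("CE", "C", "CB", "CG", "SD", 1.791, 100.9, 180)),
  MSE = rbind(CB_ROW,
              sc_row("CG", "C", "N", "CA", "CB", 1.520, 114.1, -60),
              sc_row("SE", "SE", "CA", "CB", "CG", 1.950, 112.7, 180),
              sc_row("CE", "C", "CB", "CG", "SE", 1.950, 98.0, 180)),
  LYS = rbind(CB_ROW,
              sc_row("CG", "C", "N", "CA", "CB", 1.520, 114.1, -60),
              sc_row("CD", "C", "CA", "CB", "CG", 1.520, 111.3, 180),
              sc_row("CE", "C", "CB", "CG", "CD", 1.520, 111.3, 180),
              sc_row("NZ", "N", "CG", "CD", "CE", 1.489, 111.9, 180)),
  ARG = rbind(CB_ROW,
              sc_row("CG", "C", "N", "CA", "CB", 1.520, 114.1, -60),
              sc_row("CD", "C", "CA", "CB", "CG", 1.520, 111.3, 180),
              sc_row("NE", "N", "CB", "CG", "CD", 1.461, 112.0, 180),
              sc_row("CZ", "C", "CG", "CD", "NE", 1.329, 124.2, 180),
              sc_row("NH1", "N", "CD", "NE", "CZ", 1.326, 120.0, 0),
              sc_row("NH2", "N", "CD", "NE", "CZ", 1.326, 120.0, 180)),
  HIS = rbind(CB_ROW,
              sc_row("CG", "C", "N", "CA", "CB", 1.497, 113.8, -60),
              sc_row("ND1", "N", "CA", "CB", "CG", 1.378, 122.7, -75),
              sc_row("CD2", "C", "CA", "CB", "CG", 1.354, 131.0, 105),
              sc_row("CE1", "C", "CB", "CG", "ND1", 1.321, 109.3, 180),
              sc_row("NE2", "N", "CB", "CG", "CD2", 1.374, 107.2, 180)),
  PHE = rbind(CB_ROW,
              sc_row("CG", "C", "N", "CA", "CB", 1.502, 113.8, -60),
              sc_row("CD1", "C", "CA", "CB", "CG", 1.384, 120.8, 90),
              sc_row("CD2", "C", "CA", "CB", "CG", 1.384, 120.8, -90),
              sc_row("CE1", "C", "CB", "CG", "CD1", 1.382, 120.8, 180),
              sc_row("CE2", "C", "CB", "CG", "CD2", 1.382, 120.8, 180),
              sc_row("CZ", "C", "CG", "CD1", "CE1", 1.382, 120.0, 0)),
  TYR = rbind(CB_ROW,
              sc_row("CG", "C", "N", "CA", "CB", 1.512, 113.8, -60),
              sc_row("CD1", "C", "CA", "CB", "CG", 1.389, 120.8, 90),
              sc_row("CD2", "C", "CA", "CB", "CG", 1.389, 120.8, -90),
              sc_row("CE1", "C", "CB", "CG", "CD1", 1.382, 121.1, 180),
              sc_row("CE2", "C", "CB", "CG", "CD2", 1.382, 121.1, 180),
              sc_row("CZ", "C", "CG", "CD1", "CE1", 1.378, 119.6, 0),
              sc_row("OH", "O", "CD1", "CE1", "CZ", 1.376, 119.9, 180)),
  TRP = rbind(CB_ROW,
              sc_row("CG", "C", "N", "CA", "CB", 1.498, 113.6, -60),
              sc_row("CD1", "C", "CA", "CB", "CG", 1.365, 126.9, 90),
              sc_row("CD2", "C", "CA", "CB", "CG", 1.433, 126.6, -90),
              sc_row("NE1", "N", "CB", "CG", "CD1", 1.374, 110.2, 180),
              sc_row("CE2", "C", "CB", "CG", "CD2", 1.409, 107.2, 180),
              sc_row("CE3", "C", "CB", "CG", "CD2", 1.398, 133.9, 0),
              sc_row("CZ2", "C", "CG", "CD2", "CE2", 1.394, 122.4, 180),
              sc_row("CZ3", "C", "CG", "CD2", "CE3", 1.382, 118.8, 180),
              sc_row("CH2", "C", "CD2", "CE2", "CZ2", 1.368, 117.5, 0)),
  PRO = rbind(CB_ROW,
              sc_row("CG", "C", "N", "CA", "CB", 1.492, 104.5, 30),
              sc_row("CD", "C", "CA", "CB", "CG", 1.503, 106.1, -35))
)

# Atoms removed when a side chain is "cropped from the gamma atom onward"
# (mutation handling, clash rule 4): everything except backbone + CB.
crop_to_cb <- function(names) names %in% MAINCHAIN_CLASH_NAMES

element_of <- function(name) {
  # infer element from a PDB atom name (protein atoms only)
  nm <- toupper(trimws(name))
  if (nm %in% c("SE")) return("SE")
  first <- substr(nm, 1, 1)
  if (first %in% c("C", "N", "O", "S", "P", "H")) return(first)
  "C"
}
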