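# Chemical constant tables: residue codes, ideal covalent geometry for the
# synthetic generator and the stereochemistry check, side-chain torsion
# (chi) definitions and their terminal symmetries.
#
# Bond lengths and angles follow a standard ideal-geometry set
# (Engh & Huber-style averages, rounded); they are repo constants, used both
# to build idealized structures and as the reference values that the
# stereochemistry check validates against.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

AA3_FROM_1 <- stats::setNames(names(AA1), AA1)

# Fixed mapping of common non-standard residues onto their standard parent.
# Residues not listed here (and not standard) are dropped by
# standardize_structure() with a message.
NONSTANDARD_MAP <- c(
  MSE = "MET", SEC = "CYS", CSO = "CYS", CME = "CYS", PYL = "LYS",
  MLY = "LYS", SEP = "SER", TPO = "THR", PTR = "TYR", HYP = "PRO",
  HSD = "HIS", HSE = "HIS", HSP = "HIS", HID = "HIS", HIE = "HIS",
  HIP = "HIS"
)
# Atom renames applied together with a residue mapping (old name -> new).
NONSTANDARD_ATOM_MAP <- list(MSE = c(SE = "SD"))

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Ideal backbone internal coordinates (Angstrom / degrees).
BB_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  omega = 180
)

# Improper torsion C-N-CA-CB placing an ideal tetrahedral C-beta
# (L-configuration); together with bond 1.53 A and angle N-CA-CB 110.4 deg
# it reproduces the published backbone-based C-beta heuristic to < 0.01 A.
CB_GEOM <- list(bond = 1.53, angle = 110.4, torsion = 122.47)

# Proline's CB sits at a tighter N-CA-CB angle so the pyrrolidine ring can
# close onto the backbone nitrogen.
PRO_CB_GEOM <- list(bond = 1.53, angle = 101.0, torsion = 122.47)

# Published constant weights of the backbone-frame C-beta heuristic:
# CB = CA + wa * (b x c) + wb * b + wc * c, b = CA - N, c = C - CA.
CB_HEURISTIC_W <- c(a = -0.58273431, b = 0.56802827, c = -0.54067466)

topo_row <- function(atom, r1, r2, r3, bond, angle, chi = NA_integer_, offset = 0) {
  list(atom = atom, r1 = r1, r2 = r2, r3 = r3, bond = bond, angle = angle,
       chi = chi, offset = offset)
}

topo <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

# Side-chain heavy-atom topology beyond C-beta. Each atom is placed by
# internal coordinates from three reference atoms (NeRF): bonded to r3, bond
# angle against r2, torsion against r1. A non-NA `chi` makes the torsion
# chi[chi] + offset; otherwise the torsion is the fixed `offset`.
# Ring-closing bonds (PRO CD-N, aromatic/imidazole closures) are implied by
# near-planar ideal angles and are not part of the placement tree.
SIDECHAIN_TOPO <- list(
  ALA = NULL,
  GLY = NULL,
  SER = topo(topo_row("OG",  "N",  "CA", "CB", 1.417, 110.8, 1L)),
  CYS = topo(topo_row("SG",  "N",  "CA", "CB", 1.808, 113.8, 1L)),
  THR = topo(topo_row("OG1", "N",  "CA", "CB", 1.433, 109.6, 1L),
             topo_row("CG2", "N",  "CA", "CB", 1.521, 110.5, 1L, -120)),
  VAL = topo(topo_row("CG1", "N",  "CA", "CB", 1.527, 110.5, 1L),
             topo_row("CG2", "N",  "CA", "CB", 1.527, 110.5, 1L, 122)),
  ILE = topo(topo_row("CG1", "N",  "CA", "CB", 1.530, 110.4, 1L),
             topo_row("CG2", "N",  "CA", "CB", 1.521, 110.5, 1L, -122),
             topo_row("CD1", "CA", "CB", "CG1", 1.513, 113.8, 2L)),
  LEU = topo(topo_row("CG",  "N",  "CA", "CB", 1.530, 116.3, 1L),
             topo_row("CD1", "CA", "CB", "CG", 1.521, 110.5, 2L),
             topo_row("CD2", "CA", "CB", "CG", 1.521, 110.5, 2L, 122)),
  PRO = topo(topo_row("CG",  "N",  "CA", "CB", 1.492, 104.5, 1L),
             topo_row("CD",  "CA", "CB", "CG", 1.503, 103.0, 2L)),
  MET = topo(topo_row("CG",  "N",  "CA", "CB", 1.520, 114.1, 1L),
             topo_row("SD",  "CA", "CB", "CG", 1.803, 112.7, 2L),
             topo_row("CE",  "CB", "CG", "SD", 1.791, 100.9, 3L)),
  ASP = topo(topo_row("CG",  "N",  "CA", "CB", 1.516, 112.6, 1L),
             topo_row("OD1", "CA", "CB", "CG", 1.249, 118.4, 2L),
             topo_row("OD2", "CA", "CB", "CG", 1.249, 118.4, 2L, 180)),
  ASN = topo(topo_row("CG",  "N",  "CA", "CB", 1.516, 112.6, 1L),
             topo_row("OD1", "CA", "CB", "CG", 1.231, 120.8, 2L),
             topo_row("ND2", "CA", "CB", "CG", 1.328, 116.4, 2L, 180)),
  GLU = topo(topo_row("CG",  "N",  "CA", "CB", 1.520, 114.1, 1L),
             topo_row("CD",  "CA", "CB", "CG", 1.516, 112.6, 2L),
             topo_row("OE1", "CB", "CG", "CD", 1.249, 118.4, 3L),
             topo_row("OE2", "CB", "CG", "CD", 1.249, 118.4, 3L, 180)),
  GLN = topo(topo_row("CG",  "N",  "CA", "CB", 1.520, 114.1, 1L),
             topo_row("CD",  "CA", "CB", "CG", 1.516, 112.6, 2L),
             topo_row("OE1", "CB", "CG", "CD", 1.231, 120.8, 3L),
             topo_row("NE2", "CB", "CG", "CD", 1.328, 116.4, 3L, 180)),
  LYS = topo(topo_row("CG",  "N",  "CA", "CB", 1.520, 114.1, 1L),
             topo_row("CD",  "CA", "CB", "CG", 1.520, 111.3, 2L),
             topo_row("CE",  "CB", "CG", "CD", 1.508, 111.3, 3L),
             topo_row("NZ",  "CG", "CD", "CE", 1.489, 111.9, 4L)),
  ARG = topo(topo_row("CG",  "N",  "CA", "CB", 1.520, 114.1, 1L),
             topo_row("CD",  "CA", "CB", "CG", 1.520, 111.3, 2L),
             topo_row("NE",  "CB", "CG", "CD", 1.461, 112.0, 3L),
             topo_row("CZ",  "CG", "CD", "NE", 1.329, 124.2, 4L),
             topo_row("NH1", "CD", "NE", "CZ", 1.326, 120.0, NA_integer_, 0),
             topo_row("NH2", "CD", "NE", "CZ", 1.326, 120.0, NA_integer_, 180)),
  HIS = topo(topo_row("CG",  "N",  "CA", "CB", 1.497, 113.8, 1L),
             topo_row("ND1", "CA", "CB", "CG", 1.371, 122.7, 2L),
             topo_row("CD2", "CA", "CB", "CG", 1.356, 129.1, 2L, 180),
             topo_row("CE1", "CB", "CG", "ND1", 1.319, 109.0, NA_integer_, 180),
             topo_row("NE2", "CB", "CG", "CD2", 1.374, 107.2, NA_integer_, 180)),
  PHE = topo(topo_row("CG",  "N",  "CA", "CB", 1.502, 113.8, 1L),
             topo_row("CD1", "CA", "CB", "CG", 1.384, 120.7, 2L),
             topo_row("CD2", "CA", "CB", "CG", 1.384, 120.7, 2L, 180),
             topo_row("CE1", "CB", "CG", "CD1", 1.382, 120.7, NA_integer_, 180),
             topo_row("CE2", "CB", "CG", "CD2", 1.382, 120.7, NA_integer_, 180),
             topo_row("CZ",  "CG", "CD1", "CE1", 1.382, 120.0, NA_integer_, 0)),
  TYR = topo(topo_row("CG",  "N",  "CA", "CB", 1.502, 113.8, 1L),
             topo_row("CD1", "CA", "CB", "CG", 1.384, 120.7, 2L),
             topo_row("CD2", "CA", "CB", "CG", 1.384, 120.7, 2L, 180),
             topo_row("CE1", "CB", "CG", "CD1", 1.382, 120.7, NA_integer_, 180),
             topo_row("CE2", "CB", "CG", "CD2", 1.382, 120.7, NA_integer_, 180),
             topo_row("CZ",  "CG", "CD1", "CE1", 1.382, 120.0, NA_integer_, 0),
             topo_row("OH",  "CD1", "CE1", "CZ", 1.376, 119.9, NA_integer_, 180)),
  TRP = topo(topo_row("CG",  "N",  "CA", "CB", 1.498, 113.6, 1L),
             topo_row("CD1", "CA", "CB", "CG", 1.365, 126.9, 2L),
             topo_row("CD2", "CA", "CB", "CG", 1.433, 126.6, 2L, 180),
             topo_row("NE1", "CB", "CG", "CD1", 1.374, 110.2, NA_integer_, 180),
             topo_row("CE2", "CB", "CG", "CD2", 1.409, 107.2, NA_integer_, 180),
             topo_row("CE3", "CB", "CG", "CD2", 1.398, 133.9, NA_integer_, 0),
             topo_row("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, NA_integer_, 180),
             topo_row("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, NA_integer_, 180),
             topo_row("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, NA_integer_, 0))
)

#' Side-chain chi-angle definitions
#'
#' Ordered atom-name quadruples defining chi1..chi4 per residue type, plus
#' the set of angles whose terminal group is 2-fold symmetric (so chi and
#' chi + 180 are equivalent): ASP chi2, GLU chi3, PHE chi2, TYR chi2.
#' ASN/GLN/HIS amide and imidazole flips are chemically distinguishable and
#' deliberately not treated as symmetric.
#'
#' @format A list with elements `angles` (named list of character-vector
#'   quadruples per residue type) and `symmetric` (data frame of
#'   residue/chi-index pairs).
#' @export
chi_table <- function() {
  q <- function(...) c(...)
  angles <- list(
    ARG = list(q("N","CA","CB","CG"), q("CA","CB","CG","CD"), q("CB","CG","CD","NE"), q("CG","CD","NE","CZ")),
    ASN = list(q("N","CA","CB","CG"), q("CA","CB","CG","OD1")),
    ASP = list(q("N","CA","CB","CG"), q("CA","CB","CG","OD1")),
    CYS = list(q("N","CA","CB","SG")),
    GLN = list(q("N","CA","CB","CG"), q("CA","CB","CG","CD"), q("CB","CG","CD","OE1")),
    GLU = list(q("N","CA","CB","CG"), q("CA","CB","CG","CD"), q("CB","CG","CD","OE1")),
    HIS = list(q("N","CA","CB","CG"), q("CA","CB","CG","ND1")),
    ILE = list(q("N","CA","CB","CG1"), q("CA","CB","CG1","CD1")),
    LEU = list(q("N","CA","CB","CG"), q("CA","CB","CG","CD1")),
    LYS = list(q("N","CA","CB","CG"), q("CA","CB","CG","CD"), q("CB","CG","CD","CE"), q("CG","CD","CE","NZ")),
    MET = list(q("N","CA","CB","CG"), q("CA","CB","CG","SD"), q("CB","CG","SD","CE")),
    PHE = list(q("N","CA","CB","CG"), q("CA","CB","CG","CD1")),
    PRO = list(q("N","CA","CB","CG"), q("CA","CB","CG","CD")),
    SER = list(q("N","CA","CB","OG")),
    THR = list(q("N","CA","CB","OG1")),
    TRP = list(q("N","CA","CB","CG"), q("CA","CB","CG","CD1")),
    TYR = list(q("N","CA","CB","CG"), q("CA","CB","CG","CD1")),
    VAL = list(q("N","CA","CB","CG1"))
  )
  symmetric <- data.frame(
    resname = c("ASP", "GLU", "PHE", "TYR"),
    chi = c(2L, 3L, 2L, 2L),
    stringsAsFactors = FALSE
  )
  list(angles = angles, symmetric = symmetric)
}

# One fixed chi set per residue type (common rotamer), used by the
# `ideal_single` rotamer mode. Values chosen to keep the idealized helix
# and strand fixtures free of severe overlaps; PRO closes its ring.
IDEAL_CHI <- list(
  SER = 64, CYS = -65, THR = -60, VAL = 175,
  ILE = c(-61, 169), LEU = c(-65, 175), PRO = c(36, -2),
  MET = c(-65, -65, -70), ASP = c(-70, -15), ASN = c(-65, -60),
  GLU = c(-65, 180, -40), GLN = c(-65, 180, -40),
  LYS = c(-65, 180, -65, -65), ARG = c(-65, -65, -65, -85),
  HIS = c(-65, -65), PHE = c(-65, 65), TYR = c(-65, 65), TRP = c(-65, -65)
)

# Small rotamer menu for the `random_library` mode (per chi index).
ROTAMER_LIBRARY <- list(
  chi1 = c(-65, 180, 62),
  chi2 = c(-65, 180, 65, 90),
  chi3 = c(-65, 180, 65, -40),
  chi4 = c(-65, 180, 85)
)

# Atom-name swaps for residues whose terminal atoms have ambiguous naming
# (used by the lDDT symmetry resolution).
AMBIGUOUS_ATOM_SWAPS <- list(
  ASP = list(c("OD1", "OD2")),
  GLU = list(c("OE1", "OE2")),
  PHE = list(c("CD1", "CD2"), c("CE1", "CE2")),
  TYR = list(c("CD1", "CD2"), c("CE1", "CE2")),
  ARG = list(c("NH1", "NH2"))
)

element_of <- function(atom_name) {
  # Heavy-atom element from a PDB atom name (first non-digit character);
  # two-letter elements do not occur among standard amino-acid heavy atoms
  # except selenium, which standardize maps away.
  first <- substr(gsub("^[0-9]+", "", atom_name), 1L, 1L)
  ifelse(first %in% c("N", "C", "O", "S", "P", "H"), first, "C")
}
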