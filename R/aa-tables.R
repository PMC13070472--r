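# Canonical amino-acid tables: one/three letter codes, heavy-atom inventories
# (PDB atom naming, hydrogens excluded), and the hydropathy scale used by the
# synthetic label oracle.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA3_TO_1 <- structure(names(AA3), names = unname(AA3))

# Side-chain heavy atoms in PDB order; the backbone (N, CA, C, O) is shared.
AA_SIDECHAIN <- list(
  A = c("CB"),
  R = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  N = c("CB", "CG", "OD1", "ND2"),
  D = c("CB", "CG", "OD1", "OD2"),
  C = c("CB", "SG"),
  Q = c("CB", "CG", "CD", "OE1", "NE2"),
  E = c("CB", "CG", "CD", "OE1", "OE2"),
  G = character(0),
  H = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  I = c("CB", "CG1", "CG2", "CD1"),
  L = c("CB", "CG", "CD1", "CD2"),
  K = c("CB", "CG", "CD", "CE", "NZ"),
  M = c("CB", "CG", "SD", "CE"),
  F = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  P = c("CB", "CG", "CD"),
  S = c("CB", "OG"),
  T = c("CB", "OG1", "CG2"),
  W = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  Y = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  V = c("CB", "CG1", "CG2")
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Up to 14 heavy atoms per residue (TRP); canonical slot order used by the
# local-geometry descriptor.
MAX_HEAVY_ATOMS <- 14L

#' Canonical heavy-atom names for an amino-acid type
#'
#' Backbone atoms first (N, CA, C, O), then side-chain heavy atoms in PDB
#' order.  Hydrogens are never part of the inventory.
#'
#' @param aa one-letter amino-acid code.
#' @return character vector of atom names.
#' @export
aa_heavy_atoms <- function(aa) {
  stopifnot(aa %in% AA1)
  c(BACKBONE_ATOMS, AA_SIDECHAIN[[aa]])
}

# Kyte-Doolittle hydropathy; drives the synthetic contact-energy oracle.
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

element_of_atom <- function(name) {
  # First non-digit character of the PDB atom name gives the element for
  # standard amino-acid heavy atoms (C, N, O, S).
  substr(gsub("[0-9]", "", name), 1L, 1L)
}
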