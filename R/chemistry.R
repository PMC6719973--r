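# Per-residue chemistry and ideal side-chain geometry tables.
#
# All atom typing works on heavy atoms only: explicit hydrogens are never
# stored, and polar-hydrogen geometry is idealized at scoring time from the
# donor's antecedent atom (see polar_term). Flags follow a fixed per-residue
# table rather than on-the-fly bond perception, so annotation is deterministic
# for any input source.

#' @keywords internal
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' @keywords internal
AA3_TO_1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' @keywords internal
AA1_TO_3 <- structure(names(AA3_TO_1), names = unname(AA3_TO_1))

# Number of side-chain chi dihedrals per residue type. This doubles as the
# rotatable-bond count used by the flexibility term (terminal -OH/-NH3
# hydrogen rotations carry no heavy atoms and are not counted).
#' @keywords internal
N_CHI <- c(ALA = 0L, ARG = 4L, ASN = 2L, ASP = 2L, CYS = 1L, GLN = 3L,
           GLU = 3L, GLY = 0L, HIS = 2L, ILE = 2L, LEU = 2L, LYS = 4L,
           MET = 3L, PHE = 2L, PRO = 0L, SER = 1L, THR = 1L, TRP = 2L,
           TYR = 2L, VAL = 1L)

# van der Waals radii (A) by element; anything unknown falls back to carbon.
#' @keywords internal
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

#' @keywords internal
vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- VDW_RADII[["C"]]
  unname(r)
}

# Side-chain build recipes: each row places one heavy atom by NeRF from three
# previously placed atoms (a, b, p); the new atom bonds to p with the given
# bond length (A) and angle b-p-new (deg). The dihedral a-b-p-new is either a
# chi dihedral (chi column = 1..4, plus a fixed offset in deg) or a constant
# (chi = 0, offset = the dihedral itself). CB rows are implicit (shared by all
# non-Gly residues). Values are conventional ideal internal coordinates.
#' @keywords internal
SIDECHAIN_TOPOLOGY <- local({
  row <- function(atom, el, a, b, p, bond, angle, chi, offset)
    data.frame(atom = atom, element = el, a = a, b = b, p = p, bond = bond,
               angle = angle, chi = chi, offset = offset,
               stringsAsFactors = FALSE)
  list(
    ALA = NULL,
    SER = row("OG",  "O", "N",  "CA", "CB", 1.417, 110.8, 1L, 0),
    CYS = row("SG",  "S", "N",  "CA", "CB", 1.808, 113.8, 1L, 0),
    THR = rbind(
      row("OG1", "O", "N",  "CA", "CB", 1.433, 109.6, 1L, 0),
      row("CG2", "C", "N",  "CA", "CB", 1.521, 110.5, 1L, -120)),
    VAL = rbind(
      row("CG1", "C", "N",  "CA", "CB", 1.527, 110.5, 1L, 0),
      row("CG2", "C", "N",  "CA", "CB", 1.527, 110.5, 1L, 120)),
    LEU = rbind(
      row("CG",  "C", "N",  "CA", "CB", 1.530, 116.3, 1L, 0),
      row("CD1", "C", "CA", "CB", "CG", 1.521, 110.7, 2L, 0),
      row("CD2", "C", "CA", "CB", "CG", 1.521, 110.7, 2L, 120)),
    ILE = rbind(
      row("CG1", "C", "N",  "CA", "CB", 1.530, 110.4, 1L, 0),
      row("CG2", "C", "N",  "CA", "CB", 1.521, 110.5, 1L, -120),
      row("CD1", "C", "CA", "CB", "CG1", 1.513, 113.8, 2L, 0)),
    MET = rbind(
      row("CG",  "C", "N",  "CA", "CB", 1.520, 114.1, 1L, 0),
      row("SD",  "S", "CA", "CB", "CG", 1.803, 112.7, 2L, 0),
      row("CE",  "C", "CB", "CG", "SD", 1.791, 100.9, 3L, 0)),
    PHE = rbind(
      row("CG",  "C", "N",  "CA", "CB", 1.502, 113.8, 1L, 0),
      row("CD1", "C", "CA", "CB", "CG", 1.384, 120.8, 2L, 0),
      row("CD2", "C", "CA", "CB", "CG", 1.384, 120.8, 2L, 180),
      row("CE1", "C", "CB", "CG", "CD1", 1.382, 121.0, 0L, 180),
      row("CE2", "C", "CB", "CG", "CD2", 1.382, 121.0, 0L, 180),
      row("CZ",  "C", "CG", "CD1", "CE1", 1.382, 120.0, 0L, 0)),
    TYR = rbind(
      row("CG",  "C", "N",  "CA", "CB", 1.512, 113.9, 1L, 0),
      row("CD1", "C", "CA", "CB", "CG", 1.389, 120.8, 2L, 0),
      row("CD2", "C", "CA", "CB", "CG", 1.389, 120.8, 2L, 180),
      row("CE1", "C", "CB", "CG", "CD1", 1.382, 121.1, 0L, 180),
      row("CE2", "C", "CB", "CG", "CD2", 1.382, 121.1, 0L, 180),
      row("CZ",  "C", "CG", "CD1", "CE1", 1.378, 119.6, 0L, 0),
      row("OH",  "O", "CD1", "CE1", "CZ", 1.376, 119.9, 0L, 180)),
    TRP = rbind(
      row("CG",  "C", "N",  "CA", "CB", 1.498, 113.6, 1L, 0),
      row("CD1", "C", "CA", "CB", "CG", 1.365, 126.9, 2L, 0),
      row("CD2", "C", "CA", "CB", "CG", 1.433, 126.6, 2L, 180),
      row("NE1", "N", "CB", "CG", "CD1", 1.374, 110.2, 0L, 180),
      row("CE2", "C", "CG", "CD1", "NE1", 1.370, 109.0, 0L, 0),
      row("CE3", "C", "CB", "CG", "CD2", 1.398, 133.9, 0L, 180),
      row("CZ2", "C", "CG", "CD2", "CE2", 1.394, 122.4, 0L, 180),
      row("CZ3", "C", "CG", "CD2", "CE3", 1.382, 118.8, 0L, 180),
      row("CH2", "C", "CD2", "CE3", "CZ3", 1.368, 117.5, 0L, 0)),
    ASP = rbind(
      row("CG",  "C", "N",  "CA", "CB", 1.516, 112.6, 1L, 0),
      row("OD1", "O", "CA", "CB", "CG", 1.249, 118.4, 2L, 0),
      row("OD2", "O", "CA", "CB", "CG", 1.249, 118.4, 2L, 180)),
    ASN = rbind(
      row("CG",  "C", "N",  "CA", "CB", 1.516, 112.6, 1L, 0),
      row("OD1", "O", "CA", "CB", "CG", 1.231, 120.8, 2L, 0),
      row("ND2", "N", "CA", "CB", "CG", 1.328, 116.4, 2L, 180)),
    GLU = rbind(
      row("CG",  "C", "N",  "CA", "CB", 1.520, 114.1, 1L, 0),
      row("CD",  "C", "CA", "CB", "CG", 1.516, 112.6, 2L, 0),
      row("OE1", "O", "CB", "CG", "CD", 1.249, 118.4, 3L, 0),
      row("OE2", "O", "CB", "CG", "CD", 1.249, 118.4, 3L, 180)),
    GLN = rbind(
      row("CG",  "C", "N",  "CA", "CB", 1.520, 114.1, 1L, 0),
      row("CD",  "C", "CA", "CB", "CG", 1.516, 112.6, 2L, 0),
      row("OE1", "O", "CB", "CG", "CD", 1.231, 120.8, 3L, 0),
      row("NE2", "N", "CB", "CG", "CD", 1.328, 116.4, 3L, 180)),
    LYS = rbind(
      row("CG",  "C", "N",  "CA", "CB", 1.520, 114.1, 1L, 0),
      row("CD",  "C", "CA", "CB", "CG", 1.520, 111.3, 2L, 0),
      row("CE",  "C", "CB", "CG", "CD", 1.520, 111.3, 3L, 0),
      row("NZ",  "N", "CG", "CD", "CE", 1.489, 111.7, 4L, 0)),
    ARG = rbind(
      row("CG",  "C", "N",  "CA", "CB", 1.520, 114.1, 1L, 0),
      row("CD",  "C", "CA", "CB", "CG", 1.520, 111.3, 2L, 0),
      row("NE",  "N", "CB", "CG", "CD", 1.461, 111.5, 3L, 0),
      row("CZ",  "C", "CG", "CD", "NE", 1.329, 124.2, 4L, 0),
      row("NH1", "N", "CD", "NE", "CZ", 1.326, 120.0, 0L, 0),
      row("NH2", "N", "CD", "NE", "CZ", 1.326, 120.0, 0L, 180)),
    HIS = rbind(
      row("CG",  "C", "N",  "CA", "CB", 1.497, 113.7, 1L, 0),
      row("ND1", "N", "CA", "CB", "CG", 1.378, 122.7, 2L, 0),
      row("CD2", "C", "CA", "CB", "CG", 1.356, 131.0, 2L, 180),
      row("CE1", "C", "CB", "CG", "ND1", 1.321, 109.0, 0L, 180),
      row("NE2", "N", "CG", "ND1", "CE1", 1.374, 111.7, 0L, 0))
  )
})

# Interaction chemistry per residue type: which heavy atoms can donate or
# accept hydrogen bonds, which carry formal charge, which are lipophilic
# (carbon or sulfur with no bonded polar atom), and which form aromatic rings.
# Backbone N (donor) and O (acceptor) are common to all amino acids and are
# handled separately in annotate_chemistry().
#' @keywords internal
CHEM_FLAGS <- list(
  ALA = list(lipo = "CB"),
  ARG = list(donor = c("NE", "NH1", "NH2"), charge_pos = c("NH1", "NH2"),
             lipo = c("CB", "CG")),
  ASN = list(donor = "ND2", acceptor = "OD1", lipo = "CB"),
  ASP = list(acceptor = c("OD1", "OD2"), charge_neg = c("OD1", "OD2"),
             lipo = "CB"),
  CYS = list(lipo = c("CB", "SG")),
  GLN = list(donor = "NE2", acceptor = "OE1", lipo = c("CB", "CG")),
  GLU = list(acceptor = c("OE1", "OE2"), charge_neg = c("OE1", "OE2"),
             lipo = c("CB", "CG")),
  GLY = list(),
  HIS = list(donor = c("ND1", "NE2"), acceptor = c("ND1", "NE2"),
             lipo = "CB", ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  ILE = list(lipo = c("CB", "CG1", "CG2", "CD1")),
  LEU = list(lipo = c("CB", "CG", "CD1", "CD2")),
  LYS = list(donor = "NZ", charge_pos = "NZ", lipo = c("CB", "CG", "CD")),
  MET = list(lipo = c("CB", "CG", "SD", "CE")),
  PHE = list(lipo = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  PRO = list(lipo = c("CB", "CG")),
  SER = list(donor = "OG", acceptor = "OG"),
  THR = list(donor = "OG1", acceptor = "OG1", lipo = "CG2"),
  TRP = list(donor = "NE1",
             lipo = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
             ring = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  TYR = list(donor = "OH", acceptor = "OH",
             lipo = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
             ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  VAL = list(lipo = c("CB", "CG1", "CG2"))
)

# Pseudo-residue codes used by the synthetic pocket generator. Reading these
# codes back from PDB restores interaction flags without bond perception:
#   DNR neutral donor probe        ACC neutral acceptor probe
#   CAT cationic donor probe       ANI anionic acceptor probe
#   LIP lipophilic carbon probe    ARO six-carbon aromatic ring probe
#   BLK inert steric blocker
#' @keywords internal
PSEUDO_CHEM <- list(
  DNR = list(donor = "N1"),
  ACC = list(acceptor = "O1"),
  CAT = list(donor = "N1", charge_pos = "N1"),
  ANI = list(acceptor = "O1", charge_neg = "O1"),
  LIP = list(lipo = "C1"),
  ARO = list(lipo = paste0("C", 1:6), ring = paste0("C", 1:6)),
  BLK = list()
)

# Antecedent (bonded parent) of each polar atom, used to idealize the
# polar-hydrogen direction, together with the ideal antecedent-donor-acceptor
# angle (sp3 ~109.5 deg, sp2 ~120 deg). Probe atoms have no antecedent and are
# treated as orientationally ideal.
#' @keywords internal
POLAR_GEOM <- local({
  g <- function(res, atom, parent, ideal)
    data.frame(resname = res, atom = atom, parent = parent, ideal = ideal,
               stringsAsFactors = FALSE)
  rbind(
    g("*",   "N",   "CA", 120),   # backbone amide
    g("*",   "O",   "C",  120),   # backbone carbonyl
    g("SER", "OG",  "CB", 109.5),
    g("THR", "OG1", "CB", 109.5),
    g("TYR", "OH",  "CZ", 120),
    g("TRP", "NE1", "CD1", 126),
    g("HIS", "ND1", "CG", 126),
    g("HIS", "NE2", "CE1", 126),
    g("ASN", "ND2", "CG", 120),
    g("ASN", "OD1", "CG", 120),
    g("GLN", "NE2", "CD", 120),
    g("GLN", "OE1", "CD", 120),
    g("ASP", "OD1", "CG", 120),
    g("ASP", "OD2", "CG", 120),
    g("GLU", "OE1", "CD", 120),
    g("GLU", "OE2", "CD", 120),
    g("LYS", "NZ",  "CE", 109.5),
    g("ARG", "NE",  "CZ", 120),
    g("ARG", "NH1", "CZ", 120),
    g("ARG", "NH2", "CZ", 120)
  )
})

#' Default substitution alphabet
#'
#' The 18 standard amino acids scanned by the screen. Proline is excluded
#' (its backbone ring is incompatible with a fixed scaffold) and cysteine is
#' excluded by default (disulfide ambiguity); both can be re-added explicitly.
#'
#' @param include_pro,include_cys add PRO / CYS back to the alphabet.
#' @return character vector of 3-letter residue codes.
#' @export
#' @examples
#' default_alphabet()
default_alphabet <- function(include_pro = FALSE, include_cys = FALSE) {
  ab <- setdiff(AA3, c(if (!include_pro) "PRO", if (!include_cys) "CYS"))
  sort(ab)
}

#' Side-chain rotatable bond count
#'
#' Number of chi dihedrals of a residue type; this is the rotatable-bond count
#' charged by the flexibility term.
#'
#' @param code 3-letter residue code (vectorized).
#' @return integer vector.
#' @export
#' @examples
#' n_chi(c("GLY", "ALA", "LYS"))
n_chi <- function(code) {
  code <- toupper(code)
  bad <- setdiff(code, names(N_CHI))
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  unname(N_CHI[code])
}

#' @keywords internal
seq1_to_codes <- function(seq1) {
  ch <- strsplit(seq1, "")[[1]]
  bad <- setdiff(ch, names(AA1_TO_3))
  if (length(bad))
    stop("unknown 1-letter code(s): ", paste(bad, collapse = ", "))
  unname(AA1_TO_3[ch])
}

#' @keywords internal
codes_to_seq1 <- function(codes) {
  out <- AA3_TO_1[toupper(codes)]
  out[is.na(out)] <- "X"
  paste(out, collapse = "")
}
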