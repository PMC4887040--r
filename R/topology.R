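# Ideal residue geometry: CHARMM-22-style internal-coordinate templates for
# the 20 standard amino acids, explicit-hydrogen placement rules and coarse
# atomic partial charges used by the surrogate energy model.
#
# Each heavy-atom row places one atom from three previously placed atoms of
# the same residue (see chain_place_cpp): columns are
#   res atom ref1 ref2 ref3 length angle torsion type charge
# where type is "f" (fixed torsion) or "c1".."c4" (a free side-chain chi).
# Values are idealized; they are a documented surrogate for the all-atom
# force-field geometry, chosen to be internally self-consistent (every
# consumer measures them back from the same templates).

.SIDECHAIN_TOPOLOGY <- "
ALA CB  N   C   CA 1.530 110.1  122.6 f -0.27
SER CB  N   C   CA 1.530 110.1  122.6 f  0.05
SER OG  N   CA  CB 1.417 110.1    0.0 c1 -0.66
THR CB  N   C   CA 1.542 110.1  122.6 f  0.14
THR OG1 N   CA  CB 1.433 109.6    0.0 c1 -0.66
THR CG2 OG1 CA  CB 1.521 110.5 -122.0 f -0.27
CYS CB  N   C   CA 1.530 110.1  122.6 f -0.11
CYS SG  N   CA  CB 1.808 113.5    0.0 c1 -0.23
VAL CB  N   C   CA 1.540 110.1  122.6 f -0.09
VAL CG1 N   CA  CB 1.521 110.5    0.0 c1 -0.27
VAL CG2 CG1 CA  CB 1.521 110.5  122.0 f -0.27
LEU CB  N   C   CA 1.530 110.1  122.6 f -0.18
LEU CG  N   CA  CB 1.530 116.3    0.0 c1 -0.09
LEU CD1 CA  CB  CG 1.521 110.7    0.0 c2 -0.27
LEU CD2 CD1 CB  CG 1.521 110.7  122.0 f -0.27
ILE CB  N   C   CA 1.540 110.1  122.6 f -0.09
ILE CG1 N   CA  CB 1.530 110.4    0.0 c1 -0.18
ILE CG2 CG1 CA  CB 1.521 110.5 -122.0 f -0.27
ILE CD1 CA  CB  CG1 1.513 113.8   0.0 c2 -0.27
ASP CB  N   C   CA 1.530 110.1  122.6 f -0.28
ASP CG  N   CA  CB 1.516 112.6    0.0 c1  0.62
ASP OD1 CA  CB  CG 1.249 118.4    0.0 c2 -0.76
ASP OD2 OD1 CB  CG 1.249 118.4  180.0 f -0.76
ASN CB  N   C   CA 1.530 110.1  122.6 f -0.18
ASN CG  N   CA  CB 1.516 112.6    0.0 c1  0.55
ASN OD1 CA  CB  CG 1.231 120.8    0.0 c2 -0.55
ASN ND2 OD1 CB  CG 1.328 116.4  180.0 f -0.62
GLU CB  N   C   CA 1.530 110.1  122.6 f -0.18
GLU CG  N   CA  CB 1.530 114.0    0.0 c1 -0.28
GLU CD  CA  CB  CG 1.516 112.6    0.0 c2  0.62
GLU OE1 CB  CG  CD 1.249 118.4    0.0 c3 -0.76
GLU OE2 OE1 CG  CD 1.249 118.4  180.0 f -0.76
GLN CB  N   C   CA 1.530 110.1  122.6 f -0.18
GLN CG  N   CA  CB 1.530 114.0    0.0 c1 -0.18
GLN CD  CA  CB  CG 1.516 112.6    0.0 c2  0.55
GLN OE1 CB  CG  CD 1.231 120.8    0.0 c3 -0.55
GLN NE2 OE1 CG  CD 1.328 116.4  180.0 f -0.62
MET CB  N   C   CA 1.530 110.1  122.6 f -0.18
MET CG  N   CA  CB 1.530 114.0    0.0 c1 -0.14
MET SD  CA  CB  CG 1.807 112.7    0.0 c2 -0.09
MET CE  CB  CG  SD 1.789 100.9    0.0 c3 -0.22
LYS CB  N   C   CA 1.530 110.1  122.6 f -0.18
LYS CG  N   CA  CB 1.530 114.0    0.0 c1 -0.18
LYS CD  CA  CB  CG 1.530 111.3    0.0 c2 -0.18
LYS CE  CB  CG  CD 1.530 111.3    0.0 c3  0.21
LYS NZ  CG  CD  CE 1.489 112.0    0.0 c4 -0.30
ARG CB  N   C   CA 1.530 110.1  122.6 f -0.18
ARG CG  N   CA  CB 1.530 114.0    0.0 c1 -0.18
ARG CD  CA  CB  CG 1.530 111.3    0.0 c2  0.20
ARG NE  CB  CG  CD 1.461 112.0    0.0 c3 -0.70
ARG CZ  CG  CD  NE 1.329 124.2    0.0 c4  0.64
ARG NH1 CD  NE  CZ 1.326 120.0    0.0 f -0.80
ARG NH2 NH1 NE  CZ 1.326 120.0  180.0 f -0.80
HIS CB  N   C   CA 1.530 110.1  122.6 f -0.09
HIS CG  N   CA  CB 1.504 113.8    0.0 c1 -0.05
HIS ND1 CA  CB  CG 1.378 122.7    0.0 c2 -0.36
HIS CD2 ND1 CB  CG 1.356 131.0  180.0 f  0.10
HIS CE1 CD2 CG  ND1 1.321 107.5   0.0 f  0.25
HIS NE2 ND1 CG  CD2 1.374 107.0   0.0 f -0.70
PHE CB  N   C   CA 1.530 110.1  122.6 f -0.18
PHE CG  N   CA  CB 1.509 113.8    0.0 c1  0.00
PHE CD1 CA  CB  CG 1.390 120.6    0.0 c2 -0.115
PHE CD2 CD1 CB  CG 1.390 120.6  180.0 f -0.115
PHE CE1 CD2 CG  CD1 1.390 120.0   0.0 f -0.115
PHE CE2 CD1 CG  CD2 1.390 120.0   0.0 f -0.115
PHE CZ  CG  CD1 CE1 1.390 120.0   0.0 f -0.115
TYR CB  N   C   CA 1.530 110.1  122.6 f -0.18
TYR CG  N   CA  CB 1.509 113.8    0.0 c1  0.00
TYR CD1 CA  CB  CG 1.390 120.6    0.0 c2 -0.115
TYR CD2 CD1 CB  CG 1.390 120.6  180.0 f -0.115
TYR CE1 CD2 CG  CD1 1.390 120.0   0.0 f -0.115
TYR CE2 CD1 CG  CD2 1.390 120.0   0.0 f -0.115
TYR CZ  CG  CD1 CE1 1.390 120.0   0.0 f  0.11
TYR OH  CD1 CE1 CZ  1.376 120.0 180.0 f -0.54
TRP CB  N   C   CA 1.530 110.1  122.6 f -0.18
TRP CG  N   CA  CB 1.510 113.6    0.0 c1 -0.03
TRP CD1 CA  CB  CG 1.365 126.9    0.0 c2  0.035
TRP CD2 CD1 CB  CG 1.433 126.6  180.0 f -0.02
TRP NE1 CD2 CG  CD1 1.374 110.2   0.0 f -0.61
TRP CE2 CD1 CG  CD2 1.409 107.2   0.0 f  0.13
TRP CE3 CE2 CG  CD2 1.398 133.9 180.0 f -0.115
TRP CZ2 CG  CD2 CE2 1.394 122.4 180.0 f -0.115
TRP CZ3 CE2 CD2 CE3 1.382 118.6   0.0 f -0.115
TRP CH2 CD2 CE2 CZ2 1.368 117.5   0.0 f -0.115
PRO CB  N   C   CA 1.530 103.2  115.0 f -0.18
PRO CG  N   CA  CB 1.492 104.5  -26.0 f -0.18
PRO CD  CA  CB  CG 1.503 106.1   37.0 f  0.00
"

# Hydrogen placement rows: res hname ref1 ref2 ref3 length angle torsion
# rot(atable) charge.  Backbone amide H (HN) is placed in code because it
# needs the preceding residue's carbonyl carbon.
.HYDROGEN_TOPOLOGY <- "
GLY HA2 N   C   CA  1.080 109.0  122.6 f 0.09
GLY HA3 N   C   CA  1.080 109.0 -118.0 f 0.09
ALA HB1 N   CA  CB  1.090 109.5   60.0 f 0.09
ALA HB2 N   CA  CB  1.090 109.5  180.0 f 0.09
ALA HB3 N   CA  CB  1.090 109.5  -60.0 f 0.09
SER HB2 OG  CA  CB  1.090 109.4  120.0 f 0.09
SER HB3 OG  CA  CB  1.090 109.4 -120.0 f 0.09
SER HG1 CA  CB  OG  0.960 106.0  180.0 r 0.43
THR HB  OG1 CA  CB  1.090 109.4  119.0 f 0.09
THR HG1 CA  CB  OG1 0.960 106.0  180.0 r 0.43
THR HG21 CA CB  CG2 1.090 110.5   60.0 f 0.09
THR HG22 CA CB  CG2 1.090 110.5  180.0 f 0.09
THR HG23 CA CB  CG2 1.090 110.5  -60.0 f 0.09
CYS HB2 SG  CA  CB  1.090 109.4  120.0 f 0.09
CYS HB3 SG  CA  CB  1.090 109.4 -120.0 f 0.09
CYS HG1 CA  CB  SG  1.340  96.0  180.0 f 0.16
VAL HB  CG1 CA  CB  1.090 109.4  119.0 f 0.09
VAL HG11 CA CB  CG1 1.090 110.5   60.0 f 0.09
VAL HG12 CA CB  CG1 1.090 110.5  180.0 f 0.09
VAL HG13 CA CB  CG1 1.090 110.5  -60.0 f 0.09
VAL HG21 CA CB  CG2 1.090 110.5   60.0 f 0.09
VAL HG22 CA CB  CG2 1.090 110.5  180.0 f 0.09
VAL HG23 CA CB  CG2 1.090 110.5  -60.0 f 0.09
LEU HB2 CG  CA  CB  1.090 109.4  120.0 f 0.09
LEU HB3 CG  CA  CB  1.090 109.4 -120.0 f 0.09
LEU HG  CD1 CB  CG  1.090 109.4  119.0 f 0.09
LEU HD11 CB CG  CD1 1.090 110.5   60.0 f 0.09
LEU HD12 CB CG  CD1 1.090 110.5  180.0 f 0.09
LEU HD13 CB CG  CD1 1.090 110.5  -60.0 f 0.09
LEU HD21 CB CG  CD2 1.090 110.5   60.0 f 0.09
LEU HD22 CB CG  CD2 1.090 110.5  180.0 f 0.09
LEU HD23 CB CG  CD2 1.090 110.5  -60.0 f 0.09
ILE HB  CG1 CA  CB  1.090 109.4  119.0 f 0.09
ILE HG12 CD1 CB CG1 1.090 109.4  120.0 f 0.09
ILE HG13 CD1 CB CG1 1.090 109.4 -120.0 f 0.09
ILE HG21 CA CB  CG2 1.090 110.5   60.0 f 0.09
ILE HG22 CA CB  CG2 1.090 110.5  180.0 f 0.09
ILE HG23 CA CB  CG2 1.090 110.5  -60.0 f 0.09
ILE HD11 CB CG1 CD1 1.090 110.5   60.0 f 0.09
ILE HD12 CB CG1 CD1 1.090 110.5  180.0 f 0.09
ILE HD13 CB CG1 CD1 1.090 110.5  -60.0 f 0.09
ASP HB2 CG  CA  CB  1.090 109.4  120.0 f 0.09
ASP HB3 CG  CA  CB  1.090 109.4 -120.0 f 0.09
ASN HB2 CG  CA  CB  1.090 109.4  120.0 f 0.09
ASN HB3 CG  CA  CB  1.090 109.4 -120.0 f 0.09
ASN HD21 OD1 CG ND2 1.000 120.0  180.0 f 0.31
ASN HD22 OD1 CG ND2 1.000 120.0    0.0 f 0.31
GLU HB2 CG  CA  CB  1.090 109.4  120.0 f 0.09
GLU HB3 CG  CA  CB  1.090 109.4 -120.0 f 0.09
GLU HG2 CD  CB  CG  1.090 109.4  120.0 f 0.09
GLU HG3 CD  CB  CG  1.090 109.4 -120.0 f 0.09
GLN HB2 CG  CA  CB  1.090 109.4  120.0 f 0.09
GLN HB3 CG  CA  CB  1.090 109.4 -120.0 f 0.09
GLN HG2 CD  CB  CG  1.090 109.4  120.0 f 0.09
GLN HG3 CD  CB  CG  1.090 109.4 -120.0 f 0.09
GLN HE21 OE1 CD NE2 1.000 120.0  180.0 f 0.31
GLN HE22 OE1 CD NE2 1.000 120.0    0.0 f 0.31
MET HB2 CG  CA  CB  1.090 109.4  120.0 f 0.09
MET HB3 CG  CA  CB  1.090 109.4 -120.0 f 0.09
MET HG2 SD  CB  CG  1.090 109.4  120.0 f 0.09
MET HG3 SD  CB  CG  1.090 109.4 -120.0 f 0.09
MET HE1 CG  SD  CE  1.090 110.5   60.0 f 0.09
MET HE2 CG  SD  CE  1.090 110.5  180.0 f 0.09
MET HE3 CG  SD  CE  1.090 110.5  -60.0 f 0.09
LYS HB2 CG  CA  CB  1.090 109.4  120.0 f 0.09
LYS HB3 CG  CA  CB  1.090 109.4 -120.0 f 0.09
LYS HG2 CD  CB  CG  1.090 109.4  120.0 f 0.09
LYS HG3 CD  CB  CG  1.090 109.4 -120.0 f 0.09
LYS HD2 CE  CG  CD  1.090 109.4  120.0 f 0.09
LYS HD3 CE  CG  CD  1.090 109.4 -120.0 f 0.09
LYS HE2 NZ  CD  CE  1.090 109.4  120.0 f 0.09
LYS HE3 NZ  CD  CE  1.090 109.4 -120.0 f 0.09
LYS HZ1 CD  CE  NZ  1.040 110.0   60.0 f 0.33
LYS HZ2 CD  CE  NZ  1.040 110.0  180.0 f 0.33
LYS HZ3 CD  CE  NZ  1.040 110.0  -60.0 f 0.33
ARG HB2 CG  CA  CB  1.090 109.4  120.0 f 0.09
ARG HB3 CG  CA  CB  1.090 109.4 -120.0 f 0.09
ARG HG2 CD  CB  CG  1.090 109.4  120.0 f 0.09
ARG HG3 CD  CB  CG  1.090 109.4 -120.0 f 0.09
ARG HD2 NE  CG  CD  1.090 109.4  120.0 f 0.09
ARG HD3 NE  CG  CD  1.090 109.4 -120.0 f 0.09
ARG HE  CZ  CD  NE  1.000 118.0  180.0 f 0.44
ARG HH11 NE CZ  NH1 1.000 120.0    0.0 f 0.46
ARG HH12 NE CZ  NH1 1.000 120.0  180.0 f 0.46
ARG HH21 NE CZ  NH2 1.000 120.0    0.0 f 0.46
ARG HH22 NE CZ  NH2 1.000 120.0  180.0 f 0.46
HIS HB2 CG  CA  CB  1.090 109.4  120.0 f 0.09
HIS HB3 CG  CA  CB  1.090 109.4 -120.0 f 0.09
HIS HD1 CE1 CG  ND1 1.000 126.0  180.0 f 0.32
HIS HE1 CG  ND1 CE1 1.083 125.0  180.0 f 0.13
HIS HD2 ND1 CG  CD2 1.083 126.0  180.0 f 0.10
PHE HB2 CG  CA  CB  1.090 109.4  120.0 f 0.09
PHE HB3 CG  CA  CB  1.090 109.4 -120.0 f 0.09
PHE HD1 CB  CG  CD1 1.083 120.0    0.0 f 0.115
PHE HD2 CB  CG  CD2 1.083 120.0    0.0 f 0.115
PHE HE1 CG  CD1 CE1 1.083 120.0  180.0 f 0.115
PHE HE2 CG  CD2 CE2 1.083 120.0  180.0 f 0.115
PHE HZ  CD1 CE1 CZ  1.083 120.0  180.0 f 0.115
TYR HB2 CG  CA  CB  1.090 109.4  120.0 f 0.09
TYR HB3 CG  CA  CB  1.090 109.4 -120.0 f 0.09
TYR HD1 CB  CG  CD1 1.083 120.0    0.0 f 0.115
TYR HD2 CB  CG  CD2 1.083 120.0    0.0 f 0.115
TYR HE1 CG  CD1 CE1 1.083 120.0  180.0 f 0.115
TYR HE2 CG  CD2 CE2 1.083 120.0  180.0 f 0.115
TYR HH  CE1 CZ  OH  0.960 108.0  180.0 r 0.43
TRP HB2 CG  CA  CB  1.090 109.4  120.0 f 0.09
TRP HB3 CG  CA  CB  1.090 109.4 -120.0 f 0.09
TRP HD1 CB  CG  CD1 1.083 125.0    0.0 f 0.115
TRP HE1 CG  CD1 NE1 1.000 125.0  180.0 f 0.38
TRP HE3 CG  CD2 CE3 1.083 120.0  180.0 f 0.115
TRP HZ2 CD2 CE2 CZ2 1.083 120.0  180.0 f 0.115
TRP HZ3 CD2 CE3 CZ3 1.083 120.0  180.0 f 0.115
TRP HH2 CE2 CZ2 CH2 1.083 120.0  180.0 f 0.115
PRO HA  N   C   CA  1.080 109.0 -118.0 f 0.09
"

.tables_env <- new.env(parent = emptyenv())

.read_topo <- function(txt, hydro = FALSE) {
  cn <- c("res", "atom", "r1", "r2", "r3", "len", "ang", "tor",
          if (hydro) "rot" else "type", "charge")
  df <- utils::read.table(text = txt, col.names = cn,
                          stringsAsFactors = FALSE)
  df
}

sidechain_topology <- function() {
  if (is.null(.tables_env$sc))
    .tables_env$sc <- .read_topo(.SIDECHAIN_TOPOLOGY)
  .tables_env$sc
}

hydrogen_topology <- function() {
  if (is.null(.tables_env$hy))
    .tables_env$hy <- .read_topo(.HYDROGEN_TOPOLOGY, hydro = TRUE)
  .tables_env$hy
}

# backbone ideal values shared by all residue types
.BB <- list(
  n_ca = 1.458, ca_c = 1.525, c_o = 1.231, c_n = 1.329,
  ang_n_ca_c = 111.0, ang_ca_c_n = 117.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 121.0, omega = 180.0,
  q_n = -0.47, q_hn = 0.31, q_ca = 0.07, q_ha = 0.09, q_c = 0.51, q_o = -0.51,
  len_n_h = 0.997, ang_ca_n_h = 119.0, len_ca_ha = 1.080
)

#' Amino-acid chi torsion definitions
#'
#' @param resname three-letter residue name.
#' @return a list of character 4-vectors of atom names (one per chi angle,
#'   possibly empty).
#' @export
chi_definitions <- function(resname) {
  sc <- sidechain_topology()
  rows <- sc[sc$res == resname & grepl("^c", sc$type), , drop = FALSE]
  if (nrow(rows) == 0L) return(list())
  rows <- rows[order(rows$type), , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i)
    c(rows$r1[i], rows$r2[i], rows$r3[i], rows$atom[i]))
}

#' Number of side-chain chi angles of a residue type
#' @param resname three-letter residue name.
#' @return integer count.
#' @export
n_chi <- function(resname) length(chi_definitions(resname))

#' Element symbol from a PDB atom name
#' @param name PDB atom name(s).
#' @return element symbol(s).
#' @export
element_of <- function(name) {
  stripped <- sub("^[0-9]+", "", name)
  ifelse(substr(stripped, 1, 1) == "H", "H", substr(stripped, 1, 1))
}

#' van der Waals radius by element
#' @param element element symbol(s).
#' @return radius in Angstrom.
#' @export
vdw_radius <- function(element) {
  # hydrogens get a reduced radius so hydrogen-bonded H...acceptor contacts
  # (1.8-2.0 A) are not penalized by the Lennard-Jones term
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 0.60, P = 1.80)
  out <- unname(r[element])
  out[is.na(out)] <- 1.70
  out
}

# Build the heavy atoms of one residue at ideal geometry.
#
# bb: 3x3 matrix with rows N, CA, C (already placed). chi: numeric vector of
# side-chain torsions (recycled/truncated to the residue's chi count).
# Returns a data.frame: atom, x, y, z, charge.
build_residue_atoms <- function(resname, bb, chi = NULL, psi_o = 135) {
  sc <- sidechain_topology()
  rows <- sc[sc$res == resname, , drop = FALSE]
  nm <- c("N", "CA", "C")
  coords <- bb
  charges <- c(.BB$q_n, .BB$q_ca, .BB$q_c)
  nchi <- sum(grepl("^c", rows$type))
  if (is.null(chi)) chi <- rep(180, nchi)
  if (nchi > 0) chi <- rep_len(chi, nchi)
  if (nrow(rows) > 0) {
    for (i in seq_len(nrow(rows))) {
      tor <- rows$tor[i]
      if (grepl("^c", rows$type[i]))
        tor <- chi[as.integer(sub("c", "", rows$type[i]))]
      idx <- match(c(rows$r1[i], rows$r2[i], rows$r3[i]), nm)
      p <- internal_to_cartesian(coords[idx[1], ], coords[idx[2], ],
                                 coords[idx[3], ], rows$len[i], rows$ang[i], tor)
      coords <- rbind(coords, p)
      nm <- c(nm, rows$atom[i])
      charges <- c(charges, rows$charge[i])
    }
  }
  # carbonyl O (torsion depends on psi; default points "helix-like")
  o <- internal_to_cartesian(coords[1, ], coords[2, ], coords[3, ],
                             .BB$c_o, .BB$ang_ca_c_o, psi_o)
  coords <- rbind(coords, o)
  nm <- c(nm, "O")
  charges <- c(charges, .BB$q_o)
  rownames(coords) <- NULL
  data.frame(atom = nm, x = coords[, 1], y = coords[, 2], z = coords[, 3],
             charge = charges, stringsAsFactors = FALSE)
}

# Ideal isolated-residue template (memoized), used to measure any internal
# coordinate needed by the loop builder.
residue_template <- function(resname, chi = NULL) {
  key <- paste0(resname, ":", paste(round(chi %||% numeric(0), 3), collapse = ","))
  if (!is.null(.tables_env[[key]])) return(.tables_env[[key]])
  n <- c(1.458, 0, 0)
  ca <- c(0, 0, 0)
  # C in the xy-plane so that angle(N, CA, C) is ideal
  cc <- 1.525 * c(cos(.BB$ang_n_ca_c * pi / 180), sin(.BB$ang_n_ca_c * pi / 180), 0)
  bb <- rbind(n, ca, cc)
  tpl <- build_residue_atoms(resname, bb, chi = chi)
  .tables_env[[key]] <- tpl
  tpl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# measure an internal coordinate (length/angle/torsion) between named atoms
# of a template data.frame
template_xyz <- function(tpl, atoms) {
  idx <- match(atoms, tpl$atom)
  if (anyNA(idx))
    stop("template lacks atom(s): ", paste(atoms[is.na(idx)], collapse = ", "),
         call. = FALSE)
  as.matrix(tpl[idx, c("x", "y", "z")])
}

template_ic <- function(tpl, a, b, c, d = NULL) {
  if (is.null(d)) {
    xyz <- template_xyz(tpl, c(a, b, c))
    list(len = measure("distance", xyz[2, ], xyz[3, ]),
         ang = measure("angle", xyz[1, ], xyz[2, ], xyz[3, ]))
  } else {
    xyz <- template_xyz(tpl, c(a, b, c, d))
    list(len = measure("distance", xyz[3, ], xyz[4, ]),
         ang = measure("angle", xyz[2, ], xyz[3, ], xyz[4, ]),
         tor = measure("dihedral", xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ]))
  }
}
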