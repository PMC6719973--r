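# Internal 3D geometry helpers: NeRF atom placement, angles, dihedrals,
# and an ideal extended backbone builder for the synthetic generator.

#' @keywords internal
vcross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' @keywords internal
vnorm <- function(u) sqrt(sum(u * u))

#' @keywords internal
vunit <- function(u) {
  n <- vnorm(u)
  if (n < 1e-12) stop("zero-length vector")
  u / n
}

# Angle a-b-c in degrees.
#' @keywords internal
angle3 <- function(a, b, c) {
  u <- vunit(a - b); v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Signed dihedral a-b-c-d in degrees, IUPAC convention (validated against
# measured phi/psi of deposited protein structures: beta-strand phi < 0).
#' @keywords internal
dihedral4 <- function(a, b, c, d) {
  b0 <- a - b
  b1 <- vunit(c - b)
  b2 <- d - c
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  atan2(sum(vcross(b1, v) * w), sum(v * w)) * 180 / pi
}

# NeRF placement: new atom D bonded to p with |p-D| = bond, angle(b,p,D) =
# angle (deg) and dihedral(a,b,p,D) = dihedral (deg).
#' @keywords internal
place_atom <- function(a, b, p, bond, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  bc <- vunit(p - b)
  n <- vcross(b - a, bc)
  if (vnorm(n) < 1e-10) {
    # colinear reference frame: pick any perpendicular
    aux <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- vcross(aux, bc)
  }
  n <- vunit(n)
  m <- vcross(n, bc)
  # oriented so that dihedral4(a, b, p, new) == dihedral
  d2 <- c(-bond * cos(th),
          bond * sin(th) * cos(ph),
          bond * sin(th) * sin(ph))
  p + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Ideal backbone internal coordinates (Engh-Huber-like).
#' @keywords internal
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8)

# Build an ideal extended backbone (N, CA, C, O per residue) for n residues.
# phi/psi default to an antiparallel beta conformation; omega is trans.
# Returns a list of per-residue named coordinate lists.
#' @keywords internal
build_ideal_backbone <- function(n, phi = -139, psi = 135, omega = 180) {
  g <- BB_GEOM
  res <- vector("list", n)
  # first residue in the xy-plane
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  th <- g$ang_n_ca_c * pi / 180
  C <- CA + c(-g$ca_c * cos(th), g$ca_c * sin(th), 0)
  for (i in seq_len(n)) {
    O <- place_atom(N, CA, C, g$c_o, g$ang_ca_c_o, psi + 180)
    res[[i]] <- list(N = N, CA = CA, C = C, O = O)
    if (i == n) break
    Nn <- place_atom(N, CA, C, g$c_n, g$ang_ca_c_n, psi)
    CAn <- place_atom(CA, C, Nn, g$n_ca, g$ang_c_n_ca, omega)
    Cn <- place_atom(C, Nn, CAn, g$ca_c, g$ang_n_ca_c, phi)
    N <- Nn; CA <- CAn; C <- Cn
  }
  res
}

# CB placed from the backbone frame: angle(N, CA, CB) = 110.5 deg and the
# L-amino-acid improper dihedral(C, N, CA, CB) = -122.6 deg (matches the
# sign measured on deposited L-protein structures and CCD ideal templates
# under the IUPAC dihedral convention).
#' @keywords internal
place_cb <- function(N, C, CA) {
  place_atom(C, N, CA, 1.530, 110.5, -122.6)
}
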