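# Poly-Gly scaffold construction and fixed-backbone side-chain placement.
#
# Side chains are rebuilt from ideal internal geometry (SIDECHAIN_TOPOLOGY)
# by NeRF forward kinematics at discrete chi angles; the backbone is never
# touched, so backbone coordinates stay bit-identical to the template
# through any chain of substitutions.

#' Reduce the bound peptide to a poly-Gly scaffold
#'
#' Every peptide residue becomes GLY: side-chain atoms are removed and the
#' main-chain (N, CA, C, O) coordinates are preserved bit-identically.
#' Receptor chains are untouched. Idempotent.
#'
#' @param structure a [complex_structure()].
#' @return a new `complex_structure` whose peptide is (Gly)_L.
#' @export
#' @examples
#' cplx <- make_toy_complex(pocket_spec(n_positions = 4, seed = 1))
#' peptide_sequence(build_gly_scaffold(cplx))
build_gly_scaffold <- function(structure) {
  validate_complex(structure)
  atoms <- structure$atoms
  pep <- atoms$chain == structure$peptide_chain
  keep <- !pep | atoms$atom %in% c("N", "CA", "C", "O")
  atoms <- atoms[keep, , drop = FALSE]
  atoms$resname[atoms$chain == structure$peptide_chain] <- "GLY"
  rownames(atoms) <- NULL
  out <- complex_structure(atoms, structure$peptide_chain,
                           source = structure$source)
  attr(out, "substitutions") <- list()
  out
}

#' Enumerate grid rotamers of a residue type
#'
#' Deterministic, ordered backbone-independent rotamer set: each chi
#' dihedral takes the values of `grid` (default -60, 60, 180 degrees), fully
#' crossed, so a residue with k chi angles yields `length(grid)^k` rotamers.
#' Gly and Ala have exactly one empty rotamer.
#'
#' @param code 3-letter residue code.
#' @param grid chi values in degrees.
#' @return object of class `rotamer_set`: list with `code` and `chis`
#'   (matrix, one row per rotamer).
#' @export
#' @examples
#' nrow(enumerate_rotamers("LYS")$chis)  # 81
enumerate_rotamers <- function(code, grid = c(-60, 60, 180)) {
  code <- toupper(code)
  k <- n_chi(code)
  if (k == 0L) {
    chis <- matrix(numeric(0), nrow = 1, ncol = 0)
  } else {
    # first chi varies slowest: stable, readable ordering
    g <- rev(expand.grid(rev(replicate(k, grid, simplify = FALSE))))
    chis <- as.matrix(g)
    dimnames(chis) <- list(NULL, paste0("chi", seq_len(k)))
  }
  structure(list(code = code, chis = chis), class = "rotamer_set")
}

#' @export
print.rotamer_set <- function(x, ...) {
  cat("<rotamer_set> ", x$code, ": ", nrow(x$chis), " rotamer(s), ",
      ncol(x$chis), " chi angle(s)\n", sep = "")
  invisible(x)
}

# Build the heavy side-chain atoms of `code` on the backbone frame
# (N, CA, C coordinates) at the given chi vector. Returns a data.frame of
# atom/element/x/y/z rows (0-row for GLY).
#' @keywords internal
build_sidechain_atoms <- function(code, N, CA, C, chis) {
  code <- toupper(code)
  if (code == "GLY")
    return(data.frame(atom = character(), element = character(),
                      x = double(), y = double(), z = double(),
                      stringsAsFactors = FALSE))
  if (!code %in% names(SIDECHAIN_TOPOLOGY))
    stop("unknown or unsupported residue code: ", code)
  if (code == "PRO")
    stop("PRO cannot be built on a fixed scaffold backbone")
  k <- n_chi(code)
  if (length(chis) != k)
    stop(code, " needs ", k, " chi angle(s), got ", length(chis))
  pos <- list(N = N, CA = CA, C = C, CB = place_cb(N, C, CA))
  topo <- SIDECHAIN_TOPOLOGY[[code]]
  if (!is.null(topo)) {
    for (i in seq_len(nrow(topo))) {
      r <- topo[i, ]
      dih <- if (r$chi > 0L) chis[r$chi] + r$offset else r$offset
      pos[[r$atom]] <- place_atom(pos[[r$a]], pos[[r$b]], pos[[r$p]],
                                  r$bond, r$angle, dih)
    }
  }
  nm <- setdiff(names(pos), c("N", "CA", "C"))
  el <- c(CB = "C", if (!is.null(topo)) stats::setNames(topo$element, topo$atom))
  xyz <- do.call(rbind, pos[nm])
  data.frame(atom = nm, element = unname(el[nm]),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Place a side chain on the scaffold at a fixed backbone position
#'
#' Replaces the residue at `position` of the peptide with `code`, building
#' its side chain from ideal internal geometry at the supplied chi angles.
#' Backbone atoms are reused untouched; any previous side-chain atoms at the
#' position are removed first (so placements are replace-not-stack).
#' Placing GLY is the identity on atoms.
#'
#' @param structure a `complex_structure` (typically a scaffold from
#'   [build_gly_scaffold()]).
#' @param position 1-based peptide position.
#' @param code 3-letter residue code (PRO unsupported).
#' @param chis numeric chi vector, length [n_chi()] of `code`; for
#'   convenience a 1-row matrix row of a `rotamer_set` is accepted.
#' @return new `complex_structure` with the substitution applied and an
#'   updated `substitutions` attribute (named list position -> code/chis).
#' @export
place_sidechain <- function(structure, position, code, chis = numeric(0)) {
  code <- toupper(code)
  pos_all <- peptide_positions(structure)
  if (length(position) != 1 || !position %in% pos_all)
    stop("position must be one of 1..", length(pos_all))
  chis <- as.numeric(chis)
  atoms <- structure$atoms
  pep <- atoms$chain == structure$peptide_chain
  here <- pep & atoms$resno == position
  bb <- atoms[here & atoms$atom %in% c("N", "CA", "C", "O"), , drop = FALSE]
  getx <- function(nm) {
    i <- which(bb$atom == nm)
    c(bb$x[i], bb$y[i], bb$z[i])
  }
  sc <- build_sidechain_atoms(code, getx("N"), getx("CA"), getx("C"), chis)
  atoms <- atoms[!here | atoms$atom %in% c("N", "CA", "C", "O"), ,
                 drop = FALSE]
  atoms$resname[atoms$chain == structure$peptide_chain &
                  atoms$resno == position] <- code
  if (nrow(sc)) {
    new_rows <- data.frame(chain = structure$peptide_chain,
                           resno = position, resname = code,
                           atom = sc$atom, element = sc$element,
                           x = sc$x, y = sc$y, z = sc$z, occupancy = 1,
                           stringsAsFactors = FALSE)
    common <- intersect(names(atoms), names(new_rows))
    extra <- setdiff(names(atoms), names(new_rows))
    for (e in extra) new_rows[[e]] <- NA
    atoms <- rbind(atoms[, c(common, extra)], new_rows[, c(common, extra)])
  }
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  out <- complex_structure(atoms, structure$peptide_chain,
                           source = structure$source)
  subs <- attr(structure, "substitutions")
  if (is.null(subs)) subs <- list()
  subs[[as.character(position)]] <- list(code = code, chis = chis)
  attr(out, "substitutions") <- subs
  out
}

# Pairwise vdW overlap matrix between two flagged atom tables. Pairs capable
# of hydrogen bonding (donor/acceptor or opposite formal charges) use a
# reduced contact sum (HB_CONTACT_SUM) instead of the vdW sum: H-bonded
# heavy atoms legitimately approach to ~2.6-3.0 A, well below vdW contact.
#' @keywords internal
HB_CONTACT_SUM <- 2.5

#' @keywords internal
pair_overlap <- function(a, b) {
  d <- cross_dist(coords(a), coords(b))
  vs <- outer(vdw_radius(a$element), vdw_radius(b$element), "+")
  if (!is.null(a$donor) && !is.null(b$donor)) {
    hb <- outer(a$donor, b$acceptor, "&") |
      outer(a$acceptor, b$donor, "&") |
      (outer(a$charge, b$charge, "*") < 0L)
    vs[hb] <- HB_CONTACT_SUM
  }
  vs - d
}

#' Check a substituted side chain for steric clashes
#'
#' A placement is rejected if any side-chain atom of the residue at
#' `position` lies closer than (sum of van der Waals radii - `tolerance`) to
#' any receptor heavy atom or to any atom of another peptide residue.
#' Covalently constrained near-neighbours (the CB's 1-4 partners: previous C,
#' next N) are exempt. An infinite tolerance accepts everything.
#'
#' @param structure a `complex_structure` with the substitution applied.
#' @param position 1-based peptide position whose side chain is tested.
#' @param tolerance allowed vdW overlap in Angstrom (default 0.4).
#' @return list with `accepted` (flag) and `worst_overlap` (largest overlap
#'   in Angstrom beyond tolerance-free contact; 0 if none).
#' @export
clash_check <- function(structure, position, tolerance = 0.4) {
  atoms <- structure$atoms
  pep <- atoms$chain == structure$peptide_chain
  sc <- atoms[pep & atoms$resno == position &
                !atoms$atom %in% c("N", "CA", "C", "O"), , drop = FALSE]
  if (nrow(sc) == 0 || !is.finite(tolerance) && tolerance > 0)
    return(list(accepted = TRUE, worst_overlap = 0))
  others <- atoms[!(pep & atoms$resno == position), , drop = FALSE]
  overlap <- pair_overlap(sc, others)
  # CB is 3 bonds from the previous C and the next N; allow those contacts
  excl <- outer(sc$atom == "CB",
                pep[!(pep & atoms$resno == position)] &
                  ((others$resno == position - 1 & others$atom == "C") |
                     (others$resno == position + 1 & others$atom == "N")),
                "&")
  overlap[excl] <- -Inf
  worst <- max(overlap)
  list(accepted = worst < tolerance | !is.finite(tolerance),
       worst_overlap = max(0, worst))
}
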