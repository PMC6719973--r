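# The five-term empirical binding free-energy function.
#
# Sign convention: favourable contributions are negative free energies;
# the affinity score is -coef(T) * dG_total, so tighter binders score higher.
#
# All geometry is heavy-atom only. Polar-hydrogen direction is idealized at
# the donor from its antecedent atom (POLAR_GEOM); probe pseudo-atoms without
# an antecedent are treated as orientationally ideal. Surface areas use a
# rolling-probe (Shrake-Rupley) method on a deterministic spiral point set.

# piecewise-linear penalty: 1 within tol, linear to 0 at max
#' @keywords internal
pw_linear <- function(dev, tol, maxdev) {
  f <- ifelse(dev <= tol, 1,
              ifelse(dev >= maxdev, 0, 1 - (dev - tol) / (maxdev - tol)))
  pmax(0, pmin(1, f))
}

# Idealized donor-H deviation angle for a donor atom row: the deviation of
# angle(antecedent, donor, acceptor) from the donor's ideal value. Returns 0
# (ideal) when the donor has no tabulated antecedent (probe pseudo-atoms).
#' @keywords internal
donor_angle_dev <- function(atoms, donor_row, acc_pos) {
  res <- atoms$resname[donor_row]
  nm <- atoms$atom[donor_row]
  pg <- POLAR_GEOM[(POLAR_GEOM$resname == res | POLAR_GEOM$resname == "*") &
                     POLAR_GEOM$atom == nm, , drop = FALSE]
  if (nrow(pg) == 0) return(0)
  pg <- pg[1, ]
  par <- which(atoms$chain == atoms$chain[donor_row] &
                 atoms$resno == atoms$resno[donor_row] &
                 atoms$atom == pg$parent)
  if (!length(par)) return(0)
  d <- c(atoms$x[donor_row], atoms$y[donor_row], atoms$z[donor_row])
  p <- c(atoms$x[par[1]], atoms$y[par[1]], atoms$z[par[1]])
  abs(angle3(p, d, acc_pos) - pg$ideal)
}

# Enumerate scored polar contacts between peptide and pocket polar atoms.
# One row per atom pair; orientation (who donates) picked to maximize f.
#' @keywords internal
polar_contacts <- function(pocket, structure, model) {
  atoms <- structure$atoms
  pep_idx <- which(atoms$chain == structure$peptide_chain &
                     (atoms$donor | atoms$acceptor))
  poc <- pocket$atoms
  poc_idx <- which(poc$donor | poc$acceptor)
  out <- data.frame(pep_atom = character(), pep_resno = integer(),
                    poc_atom = character(), poc_resno = integer(),
                    type = character(), R = double(), f = double(),
                    energy = double(), pep_row = integer(),
                    stringsAsFactors = FALSE)
  if (!length(pep_idx) || !length(poc_idx)) return(out)
  pxyz <- coords(atoms[pep_idx, , drop = FALSE])
  qxyz <- coords(poc[poc_idx, , drop = FALSE])
  d <- cross_dist(pxyz, qxyz)
  reach <- model$R_ideal + model$dR_max
  hits <- which(d <= reach, arr.ind = TRUE)
  if (!nrow(hits)) return(out)
  rows <- vector("list", nrow(hits))
  for (h in seq_len(nrow(hits))) {
    i <- pep_idx[hits[h, 1]]
    j <- poc_idx[hits[h, 2]]
    R <- d[hits[h, 1], hits[h, 2]]
    fR <- pw_linear(abs(R - model$R_ideal), model$dR_tol, model$dR_max)
    ionic <- atoms$charge[i] * poc$charge[j] < 0L
    ppos <- c(atoms$x[i], atoms$y[i], atoms$z[i])
    qpos <- c(poc$x[j], poc$y[j], poc$z[j])
    if (ionic) {
      # ionic pairs are scored on distance only
      f <- fR
      w <- model$w_ionic
      type <- "ionic"
    } else {
      f <- -Inf
      if (atoms$donor[i] && poc$acceptor[j]) {
        dA <- donor_angle_dev(atoms, i, qpos)
        f <- max(f, fR * pw_linear(dA, model$dA_tol, model$dA_max))
      }
      if (atoms$acceptor[i] && poc$donor[j]) {
        dA <- donor_angle_dev(poc, j, ppos)
        f <- max(f, fR * pw_linear(dA, model$dA_tol, model$dA_max))
      }
      if (!is.finite(f)) next
      w <- model$w_hbond
      type <- "hbond"
    }
    if (f <= 0) next
    rows[[h]] <- data.frame(
      pep_atom = atoms$atom[i], pep_resno = atoms$resno[i],
      poc_atom = poc$atom[j], poc_resno = poc$resno[j],
      type = type, R = R, f = f, energy = w * f, pep_row = i,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) do.call(rbind, rows) else out
}

#' Polar interaction term
#'
#' Sum over peptide-pocket donor-acceptor pairs of `weight * f(dR) * f(dA)`;
#' hydrogen bonds and ionic pairs (opposite formal charges) carry separate
#' weights, and ionic pairs are scored on distance only. `f` is 1 at ideal
#' geometry and falls linearly to 0 at the model's outer knots.
#'
#' @param pocket a [extract_pocket()] result (or any receptor subset pocket).
#' @param structure the `complex_structure` holding the (mutated) peptide.
#' @param model a [score_model()].
#' @return list: `dG` (kcal/mol), `contacts` (one row per scored pair),
#'   `n_hbonds`, `n_ionic`.
#' @export
polar_term <- function(pocket, structure, model = score_model()) {
  ct <- polar_contacts(pocket, structure, model)
  list(dG = sum(ct$energy), contacts = ct,
       n_hbonds = sum(ct$type == "hbond"),
       n_ionic = sum(ct$type == "ionic"))
}

# ring centroids of complete aromatic rings in an atom table
#' @keywords internal
RING_RESIDUES <- c("PHE", "TYR", "TRP", "HIS", "ARO")

#' @keywords internal
ring_centroids <- function(atoms) {
  sel <- which(atoms$resname %in% RING_RESIDUES)
  if (!length(sel)) return(matrix(numeric(0), ncol = 3))
  sub <- atoms[sel, , drop = FALSE]
  cents <- lapply(split(seq_len(nrow(sub)),
                        paste(sub$chain, sub$resno)), function(ix) {
    res <- sub$resname[ix[1]]
    fl <- CHEM_FLAGS[[res]]
    if (is.null(fl)) fl <- PSEUDO_CHEM[[res]]
    hit <- ix[match(fl$ring, sub$atom[ix])]
    if (anyNA(hit)) return(NULL)
    c(mean(sub$x[hit]), mean(sub$y[hit]), mean(sub$z[hit]))
  })
  cents <- cents[!vapply(cents, is.null, logical(1))]
  if (!length(cents)) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, cents)
}

#' @keywords internal
sasa_atoms <- function(context_atoms, query_rows, model) {
  if (!length(query_rows)) return(numeric(0))
  .sasa_cpp(coords(context_atoms), vdw_radius(context_atoms$element),
            as.integer(query_rows), model$probe, model$n_sphere_points)
}

# Rigid-body invariance: surface areas are evaluated on a fixed point set,
# so all SASA work happens in a canonical body frame anchored on the first
# peptide residue's backbone (origin CA, x along CA->C, xy-plane through N).
#' @keywords internal
canonical_xyz <- function(structure, atoms) {
  pep <- peptide_atoms(structure)
  r1 <- pep[pep$resno == min(pep$resno), , drop = FALSE]
  g <- function(nm) {
    i <- which(r1$atom == nm)[1]
    c(r1$x[i], r1$y[i], r1$z[i])
  }
  o <- g("CA")
  e1 <- vunit(g("C") - o)
  v <- g("N") - o
  e2 <- vunit(v - sum(v * e1) * e1)
  e3 <- vcross(e1, e2)
  xyz <- sweep(coords(atoms), 2, o, `-`)
  out <- atoms
  out$x <- as.vector(xyz %*% e1)
  out$y <- as.vector(xyz %*% e2)
  out$z <- as.vector(xyz %*% e3)
  out
}

#' Apolar interaction term
#'
#' `w_lipo` times the lipophilic contact area (surface area of peptide
#' lipophilic atoms buried by pocket lipophilic atoms, A^2) plus
#' `w_aromatic` times the number of peptide-pocket aromatic ring pairs with
#' centroid distance below the model cutoff.
#'
#' @inheritParams polar_term
#' @return list: `dG` (kcal/mol), `lipo_area` (A^2), `n_aromatic`.
#' @export
apolar_term <- function(pocket, structure, model = score_model()) {
  pep <- canonical_xyz(structure, peptide_atoms(structure))
  q <- which(pep$lipophilic)
  area <- 0
  if (length(q)) {
    poc_lipo <- pocket$atoms[pocket$atoms$lipophilic, , drop = FALSE]
    if (nrow(poc_lipo)) {
      poc_lipo <- canonical_xyz(structure, poc_lipo)
      free <- sasa_atoms(pep, q, model)
      ctx <- rbind(pep[, c("element", "x", "y", "z")],
                   poc_lipo[, c("element", "x", "y", "z")])
      bound <- sasa_atoms(ctx, q, model)
      area <- sum(pmax(0, free - bound))
    }
  }
  n_arom <- 0L
  pr <- ring_centroids(peptide_atoms(structure))
  qr <- ring_centroids(pocket$atoms)
  if (nrow(pr) && nrow(qr))
    n_arom <- sum(cross_dist(pr, qr) < model$aromatic_cutoff)
  list(dG = model$w_lipo * area + model$w_aromatic * n_arom,
       lipo_area = area, n_aromatic = n_arom)
}

#' Desolvation term
#'
#' `w_solv` times the surface area of peptide polar atoms buried by the
#' pocket without a compensating hydrogen-bond partner: an atom taking part
#' in any polar contact with `f > 0` contributes nothing.
#'
#' @inheritParams polar_term
#' @param compensated_rows internal override: atom-table row indices of
#'   peptide polar atoms already satisfied by a polar contact (recomputed
#'   from [polar_term()] when NULL).
#' @return list: `dG` (kcal/mol), `buried_area` (A^2).
#' @export
solv_term <- function(pocket, structure, model = score_model(),
                      compensated_rows = NULL) {
  atoms <- structure$atoms
  if (is.null(compensated_rows))
    compensated_rows <- unique(polar_contacts(pocket, structure, model)$pep_row)
  pep_rows <- which(atoms$chain == structure$peptide_chain)
  pep <- canonical_xyz(structure, atoms[pep_rows, , drop = FALSE])
  polar <- which((pep$donor | pep$acceptor) &
                   !(pep_rows %in% compensated_rows))
  if (!length(polar) || nrow(pocket$atoms) == 0)
    return(list(dG = 0, buried_area = 0))
  poc <- canonical_xyz(structure, pocket$atoms)
  free <- sasa_atoms(pep, polar, model)
  ctx <- rbind(pep[, c("element", "x", "y", "z")],
               poc[, c("element", "x", "y", "z")])
  bound <- sasa_atoms(ctx, polar, model)
  buried <- sum(pmax(0, free - bound))
  list(dG = model$w_solv * buried, buried_area = buried)
}

#' Flexibility term
#'
#' `w_rot` times the total count of side-chain rotatable bonds (chi
#' dihedrals) over the peptide's residues; the backbone is frozen by
#' construction and contributes nothing. A poly-Gly scaffold scores 0.
#'
#' @param structure the `complex_structure` holding the (mutated) peptide.
#' @param model a [score_model()].
#' @return list: `dG` (kcal/mol), `n_rotatable`.
#' @export
flexi_term <- function(structure, model = score_model()) {
  pep <- peptide_atoms(structure)
  codes <- pep$resname[!duplicated(pep$resno)]
  n <- sum(n_chi(codes))
  list(dG = model$w_rot * n, n_rotatable = n)
}

#' Score a peptide-receptor complex
#'
#' Computes the five-term empirical binding free energy
#' `dG = dG0 + dG_polar + dG_apolar + dG_solv + dG_flexi` (exact sum) and
#' attaches the affinity score and Ki conversion.
#'
#' @param structure a `complex_structure`.
#' @param model a [score_model()].
#' @param pocket receptor pocket to score against; defaults to the full
#'   receptor (distance cutoffs inside the terms make this equivalent to any
#'   sufficiently generous pocket).
#' @return object of class `energy_breakdown`: dG0, dG_polar, dG_apolar,
#'   dG_solv, dG_flexi, dG_total (kcal/mol), ludi_score, ki (mol/L),
#'   n_hbonds, n_ionic, n_aromatic, n_rotatable, lipo_area, buried_area,
#'   contacts.
#' @export
#' @examples
#' cplx <- make_toy_complex(pocket_spec(n_positions = 4, seed = 1))
#' score_complex(build_gly_scaffold(cplx))
score_complex <- function(structure, model = score_model(), pocket = NULL) {
  if (is.null(pocket))
    pocket <- new_pocket(receptor_atoms(structure), cutoff = Inf)
  pol <- polar_term(pocket, structure, model)
  apol <- apolar_term(pocket, structure, model)
  solv <- solv_term(pocket, structure, model,
                    compensated_rows = unique(pol$contacts$pep_row))
  flex <- flexi_term(structure, model)
  total <- model$dG0 + pol$dG + apol$dG + solv$dG + flex$dG
  out <- list(
    dG0 = model$dG0, dG_polar = pol$dG, dG_apolar = apol$dG,
    dG_solv = solv$dG, dG_flexi = flex$dG, dG_total = total,
    ludi_score = dg_to_score(total, model),
    ki = score_to_ki(dg_to_score(total, model), model),
    n_hbonds = pol$n_hbonds, n_ionic = pol$n_ionic,
    n_aromatic = apol$n_aromatic, n_rotatable = flex$n_rotatable,
    lipo_area = apol$lipo_area, buried_area = solv$buried_area,
    contacts = pol$contacts)
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0(
    "<energy_breakdown> dG_total = %.3f kcal/mol (score %.1f)\n",
    "  dG0 %.3f | polar %.3f (%d hb, %d ionic) | apolar %.3f ",
    "(%.1f A^2, %d ring) | solv %.3f (%.1f A^2) | flexi %.3f (%d rot)\n"),
    x$dG_total, x$ludi_score, x$dG0, x$dG_polar, x$n_hbonds, x$n_ionic,
    x$dG_apolar, x$lipo_area, x$n_aromatic, x$dG_solv, x$buried_area,
    x$dG_flexi, x$n_rotatable))
  invisible(x)
}

#' Write an energy breakdown as TSV
#'
#' One row per term plus the total; the polar contact list follows as
#' commented lines.
#'
#' @param breakdown an `energy_breakdown`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_breakdown_tsv <- function(breakdown, path) {
  b <- breakdown
  df <- data.frame(
    term = c("dG0", "dG_polar", "dG_apolar", "dG_solv", "dG_flexi",
             "dG_total", "ludi_score", "ki"),
    value = c(b$dG0, b$dG_polar, b$dG_apolar, b$dG_solv, b$dG_flexi,
              b$dG_total, b$ludi_score, b$ki))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(b$contacts)) {
    writeLines("# contacts", con)
    utils::write.table(b$contacts, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
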