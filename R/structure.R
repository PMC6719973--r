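# Complex structure container and pocket extraction.
#
# A complex is stored as a flat atom table (one row per heavy atom) plus the
# id of the bound peptide chain. The atom table carries the interaction
# chemistry as explicit columns so that downstream scoring never needs bond
# perception: `donor`, `acceptor` (logical), `charge` (-1/0/+1 integer) and
# `lipophilic` (logical), assigned from fixed per-residue tables.

#' @keywords internal
empty_atom_table <- function() {
  data.frame(chain = character(), resno = integer(), resname = character(),
             atom = character(), element = character(),
             x = double(), y = double(), z = double(),
             occupancy = double(), donor = logical(), acceptor = logical(),
             charge = integer(), lipophilic = logical(),
             is_backbone = logical(), stringsAsFactors = FALSE)
}

#' Construct a peptide-receptor complex structure
#'
#' @param atoms atom table (one row per heavy atom) with at least columns
#'   `chain`, `resno`, `resname`, `atom`, `element`, `x`, `y`, `z`.
#' @param peptide_chain chain id of the bound peptide.
#' @param source free-text provenance string.
#' @param annotate re-derive chemistry flags from the packaged per-residue
#'   tables (default TRUE; set FALSE to keep caller-supplied flags).
#' @return object of class `complex_structure`.
#' @export
complex_structure <- function(atoms, peptide_chain, source = "user",
                              annotate = TRUE) {
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (!peptide_chain %in% atoms$chain)
    stop("peptide chain '", peptide_chain, "' not present; available: ",
         paste(sort(unique(atoms$chain)), collapse = ", "))
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (annotate) atoms <- annotate_chemistry(atoms)
  atoms$is_backbone <- atoms$atom %in% c("N", "CA", "C", "O") &
    atoms$resname %in% AA3
  x <- structure(list(atoms = atoms, peptide_chain = peptide_chain,
                      source = source),
                 class = "complex_structure")
  validate_complex(x)
  x
}

#' @keywords internal
validate_complex <- function(x) {
  atoms <- x$atoms
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite atom coordinates")
  pep <- atoms[atoms$chain == x$peptide_chain, ]
  for (rn in unique(pep$resno)) {
    got <- pep$atom[pep$resno == rn]
    miss <- setdiff(c("N", "CA", "C", "O"), got)
    if (length(miss))
      stop("peptide residue ", rn, " (", pep$resname[pep$resno == rn][1],
           ") lacks backbone atom(s): ", paste(miss, collapse = ", "))
  }
  invisible(x)
}

#' @keywords internal
annotate_chemistry <- function(atoms) {
  n <- nrow(atoms)
  atoms$donor <- logical(n)
  atoms$acceptor <- logical(n)
  atoms$charge <- integer(n)
  atoms$lipophilic <- logical(n)
  for (res in unique(atoms$resname)) {
    idx <- which(atoms$resname == res)
    fl <- CHEM_FLAGS[[res]]
    if (is.null(fl)) fl <- PSEUDO_CHEM[[res]]
    if (res %in% AA3) {
      # backbone amide/carbonyl, shared by all standard residues
      atoms$donor[idx][atoms$atom[idx] == "N"] <- TRUE
      atoms$acceptor[idx][atoms$atom[idx] == "O"] <- TRUE
    }
    if (is.null(fl)) next
    atoms$donor[idx][atoms$atom[idx] %in% fl$donor] <- TRUE
    atoms$acceptor[idx][atoms$atom[idx] %in% fl$acceptor] <- TRUE
    atoms$charge[idx][atoms$atom[idx] %in% fl$charge_pos] <- 1L
    atoms$charge[idx][atoms$atom[idx] %in% fl$charge_neg] <- -1L
    atoms$lipophilic[idx][atoms$atom[idx] %in% fl$lipo] <- TRUE
  }
  atoms
}

#' @export
print.complex_structure <- function(x, ...) {
  pep <- peptide_atoms(x)
  cat("<complex_structure> ", x$source, "\n", sep = "")
  cat("  receptor atoms: ", sum(x$atoms$chain != x$peptide_chain),
      " in chain(s) ",
      paste(setdiff(unique(x$atoms$chain), x$peptide_chain), collapse = ","),
      "\n", sep = "")
  cat("  peptide chain ", x$peptide_chain, ": ", peptide_sequence(x),
      " (", length(unique(pep$resno)), " residues)\n", sep = "")
  invisible(x)
}

#' Peptide atom rows of a complex
#' @param x a `complex_structure`.
#' @return atom table subset.
#' @export
peptide_atoms <- function(x) {
  x$atoms[x$atoms$chain == x$peptide_chain, , drop = FALSE]
}

#' @keywords internal
receptor_atoms <- function(x) {
  x$atoms[x$atoms$chain != x$peptide_chain, , drop = FALSE]
}

#' Peptide sequence of a complex
#'
#' One-letter sequence of the bound peptide, in residue-number order
#' (positions are 1-based along the chain).
#'
#' @param x a `complex_structure`.
#' @return character scalar.
#' @export
peptide_sequence <- function(x) {
  pep <- peptide_atoms(x)
  ord <- order(pep$resno)
  codes <- pep$resname[ord][!duplicated(pep$resno[ord])]
  codes_to_seq1(codes)
}

#' @keywords internal
peptide_positions <- function(x) {
  sort(unique(peptide_atoms(x)$resno))
}

#' @keywords internal
coords <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

# Minimum pairwise cross-distances between two coordinate sets.
#' @keywords internal
cross_dist <- function(a, b) {
  # |a_i - b_j| matrix, small-n use only
  da <- outer(a[, 1], b[, 1], "-")^2 +
    outer(a[, 2], b[, 2], "-")^2 +
    outer(a[, 3], b[, 3], "-")^2
  sqrt(da)
}

#' Extract the receptor pocket around the bound peptide
#'
#' The pocket is exactly the set of receptor residues having at least one
#' atom within `cutoff` of any peptide atom. Interaction sites are the
#' flagged atoms (donor, acceptor, charged, lipophilic, aromatic-ring member)
#' of those residues.
#'
#' @param structure a `complex_structure`.
#' @param cutoff contact distance in Angstrom (default 4.5).
#' @return object of class `receptor_pocket`: list with `residues` (data
#'   frame chain/resno/resname), `atoms` (atom table of pocket residues) and
#'   `sites` (flagged subset with a `site_type` label).
#' @export
extract_pocket <- function(structure, cutoff = 4.5) {
  stopifnot(cutoff > 0)
  rec <- receptor_atoms(structure)
  pep <- peptide_atoms(structure)
  if (nrow(rec) == 0 || nrow(pep) == 0) {
    warning("empty pocket: no receptor atoms within ", cutoff, " A")
    return(new_pocket(rec[0, ], cutoff))
  }
  d <- cross_dist(coords(rec), coords(pep))
  near <- apply(d, 1, min) <= cutoff
  key <- paste(rec$chain, rec$resno)
  keep <- key %in% unique(key[near])
  pocket_atoms <- rec[keep, , drop = FALSE]
  if (nrow(pocket_atoms) == 0)
    warning("empty pocket: no receptor atoms within ", cutoff, " A")
  new_pocket(pocket_atoms, cutoff)
}

#' @keywords internal
new_pocket <- function(atoms, cutoff) {
  residues <- unique(atoms[, c("chain", "resno", "resname"), drop = FALSE])
  rownames(residues) <- NULL
  flagged <- atoms$donor | atoms$acceptor | atoms$charge != 0L |
    atoms$lipophilic
  sites <- atoms[flagged, , drop = FALSE]
  if (nrow(sites)) {
    sites$site_type <- ifelse(sites$charge > 0L, "charged+",
                       ifelse(sites$charge < 0L, "charged-",
                       ifelse(sites$donor & sites$acceptor, "donor/acceptor",
                       ifelse(sites$donor, "donor",
                       ifelse(sites$acceptor, "acceptor", "lipophilic")))))
  } else sites$site_type <- character(0)
  structure(list(residues = residues, atoms = atoms, sites = sites,
                 cutoff = cutoff),
            class = "receptor_pocket")
}

#' @export
print.receptor_pocket <- function(x, ...) {
  cat("<receptor_pocket> ", nrow(x$residues), " residues, ",
      nrow(x$sites), " interaction sites (cutoff ", x$cutoff, " A)\n",
      sep = "")
  invisible(x)
}

#' Pocket interaction sites contacting one peptide position
#'
#' Flagged receptor-site atoms within `cutoff` of any atom of the peptide
#' residue at `position`. Positions with no contacts are the natural frozen
#' positions of a screen (terminal residues that do not touch the receptor).
#'
#' @param structure a `complex_structure`.
#' @param position 1-based peptide position.
#' @param cutoff contact distance in Angstrom (default 4.5).
#' @return data frame of contacting site atoms (possibly 0-row).
#' @export
peptide_position_contacts <- function(structure, position, cutoff = 4.5) {
  pos <- peptide_positions(structure)
  if (length(position) != 1 || !position %in% pos)
    stop("position must be one of 1..", length(pos))
  if (cutoff <= 0) {
    empty <- new_pocket(receptor_atoms(structure)[0, , drop = FALSE], cutoff)
    return(empty$sites)
  }
  pocket <- extract_pocket_quiet(structure, cutoff)
  sites <- pocket$sites
  if (nrow(sites) == 0) return(sites[0, , drop = FALSE])
  res <- peptide_atoms(structure)
  res <- res[res$resno == position, , drop = FALSE]
  d <- cross_dist(coords(sites), coords(res))
  sites[apply(d, 1, min) <= cutoff, , drop = FALSE]
}

#' @keywords internal
extract_pocket_quiet <- function(structure, cutoff) {
  suppressWarnings(extract_pocket(structure, cutoff))
}

#' @keywords internal
rigid_transform <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  xyz <- coords(structure$atoms) %*% t(R)
  structure$atoms$x <- xyz[, 1] + t[1]
  structure$atoms$y <- xyz[, 2] + t[2]
  structure$atoms$z <- xyz[, 3] + t[3]
  structure
}

#' @keywords internal
rotation_matrix <- function(axis, theta_deg) {
  u <- vunit(axis); th <- theta_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
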