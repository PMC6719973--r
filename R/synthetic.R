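# Seeded generator of toy pocket-peptide complexes with planted, analytically
# known interactions.
#
# The receptor is a cloud of disconnected single-site pseudo-residues, not a
# folded protein: probes (donor/acceptor/charged/lipophilic/aromatic) are
# planted at ideal interaction geometry for the intended optimum residue's
# anchor rotamer, so ground truth is provable rather than plausible. An
# adversary sweep then walks every other alphabet residue's grid rotamers and
# drops inert blocker atoms wherever a competitor would tie or beat the
# intended residue, carving a snug pocket with a unique optimum. Positional
# noise (isotropic Gaussian on the pocket atoms) is applied last.

# complementary-site recipes per intended residue
#' @keywords internal
INTENDED_SITE <- list(
  SER = list(kind = "polar", key = "OG",  probe = "ACC"),
  THR = list(kind = "polar", key = "OG1", probe = "ACC"),
  TYR = list(kind = "polar", key = "OH",  probe = "ACC"),
  TRP = list(kind = "polar", key = "NE1", probe = "ACC"),
  ASN = list(kind = "polar", key = "ND2", probe = "ACC"),
  GLN = list(kind = "polar", key = "NE2", probe = "ACC"),
  HIS = list(kind = "polar", key = "NE2", probe = "ACC"),
  LYS = list(kind = "polar", key = "NZ",  probe = "ANI"),
  ARG = list(kind = "polar", key = "NH1", probe = "ANI"),
  ASP = list(kind = "polar", key = "OD1", probe = "CAT"),
  GLU = list(kind = "polar", key = "OE1", probe = "CAT"),
  ALA = list(kind = "lipo", outer = "CB"),
  VAL = list(kind = "lipo", outer = c("CG1", "CG2")),
  LEU = list(kind = "lipo", outer = c("CD1", "CD2")),
  ILE = list(kind = "lipo", outer = c("CD1", "CG2")),
  MET = list(kind = "lipo", outer = c("CE", "SD")),
  PHE = list(kind = "lipo", outer = c("CE1", "CE2", "CZ"))
)

#' @keywords internal
PROBE_SITE_TYPE <- c(ACC = "acceptor", DNR = "donor", ANI = "charged-",
                     CAT = "charged+", LIP = "lipophilic",
                     ARO = "lipophilic")

#' Specification of a synthetic planted pocket
#'
#' Describes a toy complex: peptide length, the original (template) sequence,
#' which positions carry a planted interaction site and which residue is
#' intended to win there, plus seed and positional noise.
#'
#' @param n_positions peptide length (the classic template is a 14-mer).
#' @param planted named list: position -> intended 1- or 3-letter residue
#'   code, or a list `list(residue =, type =)` to force a site type
#'   (`"aromatic"` plants a stacked ring probe for PHE/TYR/TRP/HIS).
#' @param original template 1-letter sequence (default all-Gly); positions
#'   without a planted site keep their original residue as expected winner.
#' @param seed RNG seed controlling anchor rotamers, probe azimuths and
#'   noise.
#' @param noise isotropic Gaussian jitter sigma (A) applied to pocket atom
#'   positions.
#' @return object of class `pocket_spec`.
#' @export
#' @examples
#' sp <- pocket_spec(n_positions = 6, planted = list(`3` = "SER"), seed = 1)
#' planted_optimum(sp)
pocket_spec <- function(n_positions = 14, planted = list(),
                        original = strrep("G", n_positions), seed = 1,
                        noise = 0) {
  stopifnot(n_positions >= 1, noise >= 0, nchar(original) == n_positions)
  norm <- list()
  for (key in names(planted)) {
    p <- as.integer(key)
    if (is.na(p) || p < 1 || p > n_positions)
      stop("planted position out of range: ", key)
    ent <- planted[[key]]
    if (!is.list(ent)) ent <- list(residue = ent)
    code <- toupper(ent$residue)
    if (nchar(code) == 1) code <- AA1_TO_3[[code]]
    site <- INTENDED_SITE[[code]]
    ring <- CHEM_FLAGS[[code]]$ring
    type <- ent$type
    if (is.null(type)) {
      if (is.null(site)) stop("no site recipe for intended residue ", code)
      type <- if (site$kind == "polar") PROBE_SITE_TYPE[[site$probe]]
              else "lipophilic"
    } else {
      ok <- (type == "aromatic" && !is.null(ring)) ||
        (type == "lipophilic" && !is.null(site) && site$kind == "lipo") ||
        (!is.null(site) && site$kind == "polar" &&
           type == PROBE_SITE_TYPE[[site$probe]])
      if (!ok)
        stop("site type '", type, "' incompatible with intended residue ",
             code)
    }
    norm[[key]] <- list(residue = code, type = type)
  }
  x <- list(n_positions = as.integer(n_positions), planted_sites = norm,
            original = toupper(original), seed = as.integer(seed),
            noise = noise)
  class(x) <- "pocket_spec"
  x
}

#' @export
print.pocket_spec <- function(x, ...) {
  cat("<pocket_spec> L=", x$n_positions, " seed=", x$seed, " noise=",
      x$noise, " A\n  optimum: ", planted_optimum(x), "\n", sep = "")
  invisible(x)
}

#' Ground-truth optimal sequence of a planted pocket
#'
#' The expected stage-2 winner: the intended residue at every planted
#' position, the original residue elsewhere.
#'
#' @param spec a [pocket_spec()].
#' @return 1-letter sequence string.
#' @export
planted_optimum <- function(spec) {
  letters1 <- strsplit(spec$original, "")[[1]]
  for (key in names(spec$planted_sites))
    letters1[as.integer(key)] <- AA3_TO_1[[spec$planted_sites[[key]]$residue]]
  paste(letters1, collapse = "")
}

# direction fan at a fixed cone angle around the bond antecedent->atom
#' @keywords internal
cone_directions <- function(atom, parent, cone_deg, n = 12, az0 = 0) {
  u <- vunit(parent - atom)                 # points back along the bond
  aux <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- vunit(vcross(u, aux))
  e2 <- vcross(u, e1)
  az <- az0 + seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  t(vapply(az, function(a)
    cos(cone_deg * pi / 180) * u +
      sin(cone_deg * pi / 180) * (cos(a) * e1 + sin(a) * e2),
    numeric(3)))
}

#' @keywords internal
new_receptor_rows <- function(resno, resname, atoms, elements, xyz) {
  data.frame(chain = rep("R", length(atoms)), resno = resno,
             resname = resname, atom = atoms, element = elements,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = rep(1, length(atoms)), stringsAsFactors = FALSE)
}

# net interaction benefit (kcal/mol, lower = better) of one placed side
# chain against nearby probe atoms: polar + apolar + rotatable-bond penalty.
# Computed on a one-residue mini complex with the package's own terms.
#' @keywords internal
mini_net <- function(code, bb_rows, sc, probes, model) {
  pep <- bb_rows
  pep$resname <- code
  if (nrow(sc)) {
    add <- data.frame(chain = pep$chain[1], resno = pep$resno[1],
                      resname = code, atom = sc$atom, element = sc$element,
                      x = sc$x, y = sc$y, z = sc$z, occupancy = 1,
                      stringsAsFactors = FALSE)
    pep <- rbind(pep[, names(add)], add)
  }
  cpx <- complex_structure(rbind(pep, probes[, names(pep)]), pep$chain[1],
                           source = "mini", annotate = TRUE)
  pk <- new_pocket(receptor_atoms(cpx), Inf)
  pol <- polar_term(pk, cpx, model)
  apol <- apolar_term(pk, cpx, model)
  list(inter = pol$dG + apol$dG, flexi = model$w_rot * n_chi(code))
}

# cheap optimistic upper bound on a competitor rotamer's benefit: distances
# padded by the jitter allowance, donor angles treated as ideal, lipophilic
# burial credited generously per contact pair. Used only to decide where the
# sweep must drop blockers; over-blocking is safe, under-blocking is not.
#' @keywords internal
optimistic_net <- function(code, sc, probes, model, pad = 0.6) {
  fl <- CHEM_FLAGS[[code]]
  inter <- 0
  pol_idx <- which(probes$donor | probes$acceptor)
  if (length(pol_idx) && nrow(sc)) {
    sc_pol <- sc$atom %in% c(fl$donor, fl$acceptor)
    if (any(sc_pol)) {
      d <- cross_dist(coords(sc[sc_pol, , drop = FALSE]),
                      coords(probes[pol_idx, , drop = FALSE]))
      dev <- pmax(0, abs(d - model$R_ideal) - pad)
      f <- pw_linear(dev, model$dR_tol, model$dR_max)
      chg <- ifelse(sc$atom[sc_pol] %in% fl$charge_pos, 1L,
                    ifelse(sc$atom[sc_pol] %in% fl$charge_neg, -1L, 0L))
      ionic <- outer(chg, probes$charge[pol_idx], `*`) < 0L
      w <- ifelse(ionic, model$w_ionic, model$w_hbond)
      inter <- inter + sum(w * f)
    }
  }
  lip_idx <- which(probes$lipophilic)
  if (length(lip_idx) && nrow(sc)) {
    sc_lip <- sc$atom %in% fl$lipo
    if (any(sc_lip)) {
      d <- cross_dist(coords(sc[sc_lip, , drop = FALSE]),
                      coords(probes[lip_idx, , drop = FALSE]))
      # ~15 A^2 credited per close lipophilic contact pair, 40 A^2 cap/atom
      a <- pmin(40, rowSums(15 * (d < 5.5 + pad)))
      inter <- inter + model$w_lipo * sum(a)
    }
  }
  inter + model$w_rot * n_chi(code)
}

#' Generate a toy planted-pocket complex
#'
#' Builds an ideal extended backbone for the template peptide (backbone atoms
#' only; residue names carry the original sequence), then for every planted
#' position: picks a clash-free anchor rotamer of the intended residue,
#' plants complementary probe pseudo-residues at ideal interaction geometry
#' (polar probes at the ideal H-bond distance and donor angle; lipophilic
#' cage probes at van der Waals contact; aromatic ring probes stacked above
#' the ring plane), and finally sweeps all competitor residues' grid
#' rotamers, dropping inert blocker atoms wherever a competitor would come
#' within `margin` kcal/mol of the intended residue's net benefit.
#' Deterministic given the spec's seed; pocket atoms are jittered by the
#' spec's noise sigma at the end.
#'
#' @param spec a [pocket_spec()].
#' @param model scoring model used for the adversary sweep margins.
#' @param margin adversary margin, kcal/mol: competitors within this of the
#'   intended net benefit are sterically excluded.
#' @param alphabet competitor alphabet for the sweep.
#' @return a [complex_structure()] with attributes `spec`, `optimum` and
#'   `anchors` (chosen rotamer per planted position).
#' @export
make_toy_complex <- function(spec, model = score_model(), margin = 0.25,
                             alphabet = default_alphabet()) {
  stopifnot(inherits(spec, "pocket_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)

  n <- spec$n_positions
  bb <- build_ideal_backbone(n)
  codes <- seq1_to_codes(spec$original)
  pep_rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    xyz <- do.call(rbind, bb[[i]])
    data.frame(chain = "P", resno = i, resname = codes[i],
               atom = rownames(xyz), element = substr(rownames(xyz), 1, 1),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1,
               stringsAsFactors = FALSE)
  }))
  bb_xyz <- coords(pep_rows)
  bb_vdw <- vdw_radius(pep_rows$element)

  rec <- new_receptor_rows(integer(0), character(0), character(0),
                           character(0), matrix(numeric(0), ncol = 3))
  resno_next <- 1L
  planted_pos <- sort(as.integer(names(spec$planted_sites)))
  anchors <- list()

  frame_of <- function(p) {
    r <- bb[[p]]
    list(N = r$N, CA = r$CA, C = r$C)
  }
  anchor_atoms_xyz <- function() {
    if (!length(anchors)) return(NULL)
    do.call(rbind, lapply(anchors, function(a)
      if (nrow(a$sc)) coords(a$sc) else NULL))
  }

  # --- phase A0: choose all anchor rotamers first --------------------------
  pep_annot <- annotate_chemistry(pep_rows)
  anchor_blocks <- function() {
    bl <- lapply(anchors, function(a) a$block)
    bl <- bl[vapply(bl, nrow, integer(1)) > 0]
    if (length(bl)) do.call(rbind, bl) else NULL
  }
  for (p in planted_pos) {
    ent <- spec$planted_sites[[as.character(p)]]
    code <- ent$residue
    fr <- frame_of(p)
    rs <- enumerate_rotamers(code)
    env <- rbind(pep_annot[pep_annot$resno != p, , drop = FALSE],
                 anchor_blocks())
    cb14 <- env$chain == "P" &
      ((env$resno == p - 1 & env$atom == "C") |
         (env$resno == p + 1 & env$atom == "N"))
    feasible <- integer(0)
    blk_list <- vector("list", nrow(rs$chis))
    for (r in seq_len(nrow(rs$chis))) {
      sc <- build_sidechain_atoms(code, fr$N, fr$CA, fr$C, rs$chis[r, ])
      block <- annotate_block(sc, "P", p, code)
      blk_list[[r]] <- list(sc = sc, block = block)
      if (!nrow(sc)) { feasible <- c(feasible, r); next }
      ov <- pair_overlap(block, env)
      ov[block$atom == "CB", cb14] <- -Inf
      if (max(ov) < model$clash_tolerance) feasible <- c(feasible, r)
    }
    if (!length(feasible))
      stop("no clash-free anchor rotamer for ", code, " at position ", p)
    r_anchor <- feasible[sample.int(length(feasible), 1)]
    anchors[[as.character(p)]] <- list(code = code, rotamer = r_anchor,
                                       chis = rs$chis[r_anchor, ],
                                       sc = blk_list[[r_anchor]]$sc,
                                       block = blk_list[[r_anchor]]$block)
  }

  # --- phase A1: plant probes, keeping clear of every anchor ---------------
  for (p in planted_pos) {
    ent <- spec$planted_sites[[as.character(p)]]
    code <- ent$residue
    fr <- frame_of(p)
    sc <- anchors[[as.character(p)]]$sc

    getp <- function(nm) {
      i <- which(sc$atom == nm)
      c(sc$x[i], sc$y[i], sc$z[i])
    }
    other_anchors <- do.call(rbind, c(list(matrix(numeric(0), ncol = 3)),
      lapply(anchors[setdiff(names(anchors), as.character(p))],
             function(a) if (nrow(a$sc)) coords(a$sc) else NULL)))
    protected <- rbind(bb_xyz, other_anchors,
                       if (nrow(rec)) coords(rec))

    if (ent$type == "aromatic") {
      ring <- CHEM_FLAGS[[code]]$ring
      rx <- coords(sc[match(ring, sc$atom), , drop = FALSE])
      cen <- colMeans(rx)
      nv <- vunit(vcross(rx[2, ] - rx[1, ], rx[3, ] - rx[1, ]))
      if (sum((cen + nv - fr$CA)^2) < sum((cen - nv - fr$CA)^2)) nv <- -nv
      c2 <- cen + 4.0 * nv
      e1 <- vunit(rx[1, ] - cen); e2 <- vcross(nv, e1)
      az <- seq(0, 2 * pi, length.out = 7)[-7]
      ringxyz <- t(vapply(az, function(a)
        c2 + 1.39 * (cos(a) * e1 + sin(a) * e2), numeric(3)))
      rec <- rbind(rec, new_receptor_rows(resno_next, "ARO",
                                          paste0("C", 1:6), rep("C", 6),
                                          ringxyz))
      resno_next <- resno_next + 1L
    } else if (!is.null(INTENDED_SITE[[code]]) &&
               INTENDED_SITE[[code]]$kind == "polar") {
      site <- INTENDED_SITE[[code]]
      key <- site$key
      pg <- POLAR_GEOM[POLAR_GEOM$resname == code & POLAR_GEOM$atom == key, ]
      topo <- SIDECHAIN_TOPOLOGY[[code]]
      parent_nm <- if (nrow(pg)) pg$parent[1] else
        topo$p[topo$atom == key]
      D <- getp(key); A <- getp(parent_nm)
      cone <- if (nrow(pg)) pg$ideal[1] else 120
      dirs <- cone_directions(D, A, cone, n = 12, az0 = stats::runif(1, 0,
                                                                     2 * pi))
      cand <- sweep(dirs * model$R_ideal, 2, D, `+`)
      own_sc <- coords(sc[sc$atom != key, , drop = FALSE])
      # clearance: >= 3.4 from backbone/other anchors/receptor (jitter
      # margin over the vdW floor) and >= 3.2 from the rest of the own
      # side chain
      clearance <- apply(cross_dist(cand, protected), 1, min) - 0.2
      if (nrow(own_sc))
        clearance <- pmin(clearance,
                          apply(cross_dist(cand, own_sc), 1, min))
      ord <- order(-clearance)
      chosen <- ord[clearance[ord] >= 3.4]
      # up to three independent probes per polar site: the intended residue
      # then keeps a deep margin even when jitter degrades individual bonds
      picks <- integer(0)
      for (i in chosen) {
        if (length(picks) == 3) break
        if (!length(picks) ||
            min(cross_dist(cand[i, , drop = FALSE],
                           cand[picks, , drop = FALSE])) >= 2.2)
          picks <- c(picks, i)
      }
      if (!length(picks)) picks <- ord[1]
      el <- if (site$probe %in% c("ACC", "ANI")) "O" else "N"
      at <- if (el == "O") "O1" else "N1"
      for (i in picks) {
        rec <- rbind(rec, new_receptor_rows(resno_next, site$probe, at, el,
                                            cand[i, , drop = FALSE]))
        resno_next <- resno_next + 1L
      }
    } else {
      outer_nms <- INTENDED_SITE[[code]]$outer
      for (nm in outer_nms) {
        t0 <- getp(nm)
        dir <- vunit(t0 - fr$CA)
        pos <- t0 + 3.7 * dir
        own_sc <- sc[sc$atom != nm, , drop = FALSE]
        dmin <- min(c(cross_dist(matrix(pos, 1), protected),
                      if (nrow(own_sc))
                        cross_dist(matrix(pos, 1), coords(own_sc))))
        if (dmin < 3.4) next
        rec <- rbind(rec, new_receptor_rows(resno_next, "LIP", "C1", "C",
                                            matrix(pos, 1)))
        resno_next <- resno_next + 1L
      }
    }
  }

  # --- phase B: adversary sweep --------------------------------------------
  probes <- if (nrow(rec)) annotate_chemistry(rec) else rec
  protected <- rbind(bb_xyz, anchor_atoms_xyz())
  for (p in planted_pos) {
    ent <- spec$planted_sites[[as.character(p)]]
    fr <- frame_of(p)
    own_bb <- pep_rows[pep_rows$resno == p, , drop = FALSE]
    if (!nrow(probes)) next
    near <- probes[.min_dist_cpp(coords(probes),
                                 matrix(fr$CA, 1)) < 14, , drop = FALSE]
    if (!nrow(near)) next
    # pessimistic intended benefit: real scorer, interaction part discounted
    # for the jitter the pocket will receive
    nx <- mini_net(ent$residue, own_bb, anchors[[as.character(p)]]$sc,
                   near, model)
    net_x <- 0.65 * nx$inter + nx$flexi
    for (code in setdiff(alphabet, c("GLY", ent$residue))) {
      rs <- enumerate_rotamers(code)
      env <- rbind(pep_annot[pep_annot$resno != p, , drop = FALSE],
                   if (nrow(rec)) annotate_chemistry(rec))
      cb14 <- env$chain == "P" &
        ((env$resno == p - 1 & env$atom == "C") |
           (env$resno == p + 1 & env$atom == "N"))
      for (r in seq_len(nrow(rs$chis))) {
        sc <- build_sidechain_atoms(code, fr$N, fr$CA, fr$C, rs$chis[r, ])
        if (!nrow(sc)) next
        # quick reach prefilter
        if (min(cross_dist(coords(sc), coords(near))) > 7.5) next
        block <- annotate_block(sc, "P", p, code)
        ov <- pair_overlap(block, env)
        ov[block$atom == "CB", cb14] <- -Inf
        if (max(ov) >= model$clash_tolerance) next  # already infeasible
        net_y <- optimistic_net(code, sc, near, model)
        if (net_y >= net_x + margin) next
        # place a blocker that kills this rotamer without touching the
        # protected set (backbone + anchors)
        # blocker standoff: >= 4.2 A from every protected atom so that the
        # pocket jitter cannot push a blocker into clash range of an anchor
        dprot <- apply(cross_dist(coords(sc), protected), 1, min)
        for (ai in order(-dprot)) {
          if (dprot[ai] < 1.3) break
          a0 <- c(sc$x[ai], sc$y[ai], sc$z[ai])
          jn <- which.min(.min_dist_cpp(protected,
                                        matrix(a0, 1)))
          u <- tryCatch(vunit(a0 - protected[jn, ]),
                        error = function(e) c(0, 0, 1))
          off <- min(2.9, max(0, 4.2 - dprot[ai]))
          blk <- a0 + off * u
          if (min(cross_dist(matrix(blk, 1), protected)) < 4.2) next
          if (nrow(rec) &&
              min(cross_dist(matrix(blk, 1), coords(rec))) < 1.6) next
          rec <- rbind(rec, new_receptor_rows(resno_next, "BLK", "C1", "C",
                                              matrix(blk, 1)))
          resno_next <- resno_next + 1L
          break
        }
      }
    }
  }

  # --- noise and assembly ---------------------------------------------------
  if (spec$noise > 0 && nrow(rec)) {
    rec$x <- rec$x + stats::rnorm(nrow(rec), 0, spec$noise)
    rec$y <- rec$y + stats::rnorm(nrow(rec), 0, spec$noise)
    rec$z <- rec$z + stats::rnorm(nrow(rec), 0, spec$noise)
    # keep jittered pocket atoms off the backbone
    dmin <- .min_dist_cpp(coords(rec), bb_xyz)
    for (i in which(dmin < 2.2)) {
      jn <- which.min(.min_dist_cpp(bb_xyz, coords(rec)[i, , drop = FALSE]))
      u <- vunit(coords(rec)[i, ] - bb_xyz[jn, ])
      newp <- bb_xyz[jn, ] + 2.2 * u
      rec$x[i] <- newp[1]; rec$y[i] <- newp[2]; rec$z[i] <- newp[3]
    }
  }
  atoms <- rbind(pep_rows, rec)
  cpx <- complex_structure(atoms, "P",
                           source = sprintf("synthetic pocket (seed %d)",
                                            spec$seed))
  attr(cpx, "spec") <- spec
  attr(cpx, "optimum") <- planted_optimum(spec)
  attr(cpx, "anchors") <- lapply(anchors, function(a)
    a[c("code", "rotamer", "chis")])
  cpx
}

#' Write the ground-truth sidecar of a synthetic complex
#'
#' Plain-text JSON companion to the PDB written by [write_pdb()]: expected
#' optimum sequence, planted site list, seed and noise.
#'
#' @param complex a toy complex from [make_toy_complex()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(complex, path) {
  spec <- attr(complex, "spec")
  if (is.null(spec)) stop("not a generated toy complex")
  rec <- receptor_atoms(complex)
  jsonlite::write_json(list(
    optimum = attr(complex, "optimum"),
    original = spec$original,
    seed = spec$seed, noise = spec$noise,
    planted = lapply(spec$planted_sites, function(e)
      list(residue = e$residue, type = e$type)),
    pocket_atoms = nrow(rec)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
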