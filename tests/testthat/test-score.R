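# the five-term scoring function and its conversions

m0 <- score_model()

# ideal-geometry H-bond donor fixture: a Ser at position 2 of a tri-Gly
# scaffold with an acceptor probe placed exactly at the ideal distance and
# donor angle from OG; returns the complex and the probe position used
ideal_ser_complex <- function(probe_resname = "ACC", dR = 0, dA = 0,
                              model = m0) {
  sc <- build_gly_scaffold(probe_complex("GGG"))
  mut <- place_sidechain(sc, 2, "SER", -60)
  pep <- peptide_atoms(mut)
  g <- function(nm) unlist(pep[pep$resno == 2 & pep$atom == nm,
                               c("x", "y", "z")])
  dirs <- ns$cone_directions(g("OG"), g("CB"), 109.5 + dA, n = 8,
                             az0 = 0.3)
  # pick the direction farthest from the backbone
  bb <- ns$coords(pep)
  cand <- sweep(dirs * (model$R_ideal + dR), 2, g("OG"), `+`)
  best <- which.max(apply(ns$cross_dist(cand, bb), 1, min))
  probes <- probe_row(probe_resname, cand[best, ])
  atoms <- rbind(mut$atoms[, names(probes)], probes)
  out <- complex_structure(atoms, "P")
  attr(out, "substitutions") <- attr(mut, "substitutions")
  out
}

test_that("one ideal H-bond contributes exactly w_hbond", {
  cpx <- ideal_ser_complex()
  pk <- ns$new_pocket(ns$receptor_atoms(cpx), Inf)
  pol <- polar_term(pk, cpx, m0)
  expect_equal(pol$dG, m0$w_hbond, tolerance = 1e-9)
  expect_equal(pol$n_hbonds, 1L)
})

test_that("polar contacts vanish beyond the distance knot and fade between", {
  far <- ideal_ser_complex(dR = m0$dR_max + 0.05)
  pk <- ns$new_pocket(ns$receptor_atoms(far), Inf)
  expect_equal(polar_term(pk, far, m0)$dG, 0)
  mid <- ideal_ser_complex(dR = (m0$dR_tol + m0$dR_max) / 2)
  pk <- ns$new_pocket(ns$receptor_atoms(mid), Inf)
  f <- polar_term(pk, mid, m0)$contacts$f
  expect_equal(f, 0.5, tolerance = 1e-6)
})

test_that("donor angle penalty applies at the idealized H position", {
  bent <- ideal_ser_complex(dA = 50)  # between dA_tol 30 and dA_max 80
  pk <- ns$new_pocket(ns$receptor_atoms(bent), Inf)
  f <- polar_term(pk, bent, m0)$contacts$f
  expect_equal(f, 1 - (50 - 30) / (80 - 30), tolerance = 1e-3)
})

test_that("two ideal H-bonds plus one ideal ionic pair sum exactly", {
  # brute-force oracle: expected energy assembled pair by pair
  sc <- build_gly_scaffold(probe_complex("GGGGG"))
  cur <- place_sidechain(sc, 2, "SER", -60)
  cur <- place_sidechain(cur, 4, "LYS", c(180, 180, 180, 180))
  pep <- peptide_atoms(cur)
  g <- function(rn, nm) unlist(pep[pep$resno == rn & pep$atom == nm,
                                   c("x", "y", "z")])
  bb <- ns$coords(pep)
  place_probe <- function(key, parent, resname, cone, rid) {
    dirs <- ns$cone_directions(key, parent, cone, n = 10, az0 = 0.8)
    cand <- sweep(dirs * m0$R_ideal, 2, key, `+`)
    best <- which.max(apply(ns$cross_dist(cand, bb), 1, min))
    probe_row(resname, cand[best, ], rid)
  }
  probes <- rbind(
    place_probe(g(2, "OG"), g(2, "CB"), "ACC", 109.5, 1L),
    place_probe(g(1, "N"), g(1, "CA"), "ACC", 120, 2L),
    place_probe(g(4, "NZ"), g(4, "CE"), "ANI", 109.5, 3L))
  atoms <- rbind(cur$atoms[, names(probes)], probes)
  cpx <- complex_structure(atoms, "P")
  pk <- ns$new_pocket(ns$receptor_atoms(cpx), Inf)
  pol <- polar_term(pk, cpx, m0)
  expect_equal(pol$n_hbonds, 2L)
  expect_equal(pol$n_ionic, 1L)
  expect_equal(pol$dG, 2 * m0$w_hbond + m0$w_ionic, tolerance = 1e-9)
})

test_that("apolar term: no lipophilic atoms or separated atoms give zero", {
  # poly-Ser-like chain: Ser has no lipophilic atoms at all
  sc <- build_gly_scaffold(probe_complex("GGG"))
  cur <- place_sidechain(sc, 2, "SER", -60)
  probes <- probe_row("LIP", c(0, 8, 0))
  atoms <- rbind(cur$atoms[, names(probes)], probes)
  cpx <- complex_structure(atoms, "P")
  pk <- ns$new_pocket(ns$receptor_atoms(cpx), Inf)
  ap <- apolar_term(pk, cpx, m0)
  expect_equal(ap$dG, 0)
  expect_equal(ap$lipo_area, 0)
  # a lone ALA CB far (> 2x probe reach) from the pocket atom is also zero
  cur2 <- place_sidechain(sc, 2, "ALA")
  atoms2 <- rbind(cur2$atoms[, names(probes)],
                  probe_row("LIP", c(50, 50, 50)))
  cpx2 <- complex_structure(atoms2, "P")
  pk2 <- ns$new_pocket(ns$receptor_atoms(cpx2), Inf)
  expect_equal(apolar_term(pk2, cpx2, m0)$dG, 0)
})

test_that("stacked ring pair scores w_aromatic plus w_lipo times the area
           measured by the independent surface oracle", {
  sc <- build_gly_scaffold(probe_complex("GGG"))
  cur <- place_sidechain(sc, 2, "PHE", c(-60, 90))
  pep <- peptide_atoms(cur)
  ring_nms <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  rx <- ns$coords(pep[match(ring_nms, pep$atom), ])
  cen <- colMeans(rx)
  nv <- ns$vunit(ns$vcross(rx[2, ] - rx[1, ], rx[3, ] - rx[1, ]))
  ca <- unlist(pep[pep$resno == 2 & pep$atom == "CA", c("x", "y", "z")])
  if (sum((cen + nv - ca)^2) < sum((cen - nv - ca)^2)) nv <- -nv
  c2 <- cen + 4.0 * nv
  e1 <- ns$vunit(rx[1, ] - cen); e2 <- ns$vcross(nv, e1)
  az <- seq(0, 2 * pi, length.out = 7)[-7]
  ringxyz <- t(vapply(az, function(a) c2 + 1.39 * (cos(a) * e1 +
                                                     sin(a) * e2),
                      numeric(3)))
  probes <- ns$new_receptor_rows(1L, "ARO", paste0("C", 1:6), rep("C", 6),
                                 ringxyz)
  atoms <- rbind(cur$atoms[, names(probes)], probes)
  cpx <- complex_structure(atoms, "P")
  pk <- ns$new_pocket(ns$receptor_atoms(cpx), Inf)
  ap <- apolar_term(pk, cpx, m0)
  expect_equal(ap$n_aromatic, 1L)
  # independent latitude-longitude SASA oracle for the buried area
  pepq <- peptide_atoms(cpx)
  q <- which(pepq$lipophilic)
  free <- oracle_sasa(pepq, q, probe = m0$probe)
  ctx <- rbind(pepq, pk$atoms[pk$atoms$lipophilic, names(pepq)])
  bound <- oracle_sasa(ctx, q, probe = m0$probe)
  area_oracle <- sum(pmax(0, free - bound))
  expect_gt(ap$lipo_area, 0)
  expect_equal(ap$lipo_area, area_oracle, tolerance = 0.06)
  expect_equal(ap$dG, m0$w_aromatic + m0$w_lipo * ap$lipo_area,
               tolerance = 1e-9)
})

test_that("desolvation: exposed zero, compensated zero, uncompensated
           matches the numeric surface oracle", {
  # empty pocket: no burial at all
  bare <- probe_complex("GGG")
  pk0 <- ns$new_pocket(ns$receptor_atoms(bare), Inf)
  expect_equal(solv_term(pk0, bare, m0)$dG, 0)
  # ideal H-bond: the buried donor is compensated, contributes nothing
  hb <- ideal_ser_complex()
  pk1 <- ns$new_pocket(ns$receptor_atoms(hb), Inf)
  ct <- polar_term(pk1, hb, m0)$contacts
  og_row <- ct$pep_row[ct$pep_atom == "OG"]
  sv <- solv_term(pk1, hb, m0)
  full <- solv_term(pk1, hb, m0, compensated_rows = integer(0))
  expect_lt(sv$buried_area, full$buried_area)  # OG's burial excluded
  # uncompensated burial: replace the acceptor probe by an inert blocker at
  # the same spot; same geometry, no H-bond, now penalized
  blk <- ideal_ser_complex(probe_resname = "BLK")
  pk2 <- ns$new_pocket(ns$receptor_atoms(blk), Inf)
  expect_equal(polar_term(pk2, blk, m0)$dG, 0)
  sv2 <- solv_term(pk2, blk, m0)
  expect_gt(sv2$buried_area, 0)
  pepq <- peptide_atoms(blk)
  polar_rows <- which(pepq$donor | pepq$acceptor)
  free <- oracle_sasa(pepq, polar_rows, probe = m0$probe)
  ctx <- rbind(pepq, pk2$atoms[, names(pepq)])
  bound <- oracle_sasa(ctx, polar_rows, probe = m0$probe)
  expect_equal(sv2$buried_area, sum(pmax(0, free - bound)),
               tolerance = 0.06)
  expect_equal(sv2$dG, m0$w_solv * sv2$buried_area, tolerance = 1e-9)
})

test_that("flexibility term counts side-chain rotatable bonds", {
  sc <- build_gly_scaffold(probe_complex("GGGG"))
  expect_equal(flexi_term(sc, m0)$dG, 0)
  lys <- place_sidechain(sc, 2, "LYS", c(180, 180, 180, 180))
  expect_equal(flexi_term(lys, m0)$dG, 4 * m0$w_rot, tolerance = 1e-12)
  ala <- place_sidechain(sc, 2, "ALA")
  expect_equal(flexi_term(ala, m0)$dG, 0)
})

test_that("empty pocket + all-Gly peptide collapses to the constant term", {
  bare <- probe_complex("GGGGG")
  b <- score_complex(bare, m0)
  expect_equal(b$dG_total, m0$dG0, tolerance = 1e-12)
  expect_equal(b$ludi_score, dg_to_score(m0$dG0, m0), tolerance = 1e-9)
})

test_that("five terms are exactly additive and the breakdown matches the
           term functions on random complexes", {
  for (seed in 1:10) {
    cpx <- random_probe_complex(seed)
    b <- score_complex(cpx, m0)
    expect_equal(b$dG_total,
                 b$dG0 + b$dG_polar + b$dG_apolar + b$dG_solv + b$dG_flexi,
                 tolerance = 1e-9)
    pk <- ns$new_pocket(ns$receptor_atoms(cpx), Inf)
    expect_equal(b$dG_polar, polar_term(pk, cpx, m0)$dG, tolerance = 1e-9)
    expect_equal(b$dG_apolar, apolar_term(pk, cpx, m0)$dG,
                 tolerance = 1e-9)
    expect_equal(b$dG_flexi, flexi_term(cpx, m0)$dG, tolerance = 1e-12)
  }
})

test_that("rigid-body motion changes no term beyond 1e-6", {
  for (seed in 1:5) {
    cpx <- random_probe_complex(seed + 100)
    moved <- ns$rigid_transform(cpx, ns$rotation_matrix(c(2, -1, 1), 37),
                                c(-4, 9, 2))
    a <- score_complex(cpx, m0)
    b <- score_complex(moved, m0)
    for (term in c("dG0", "dG_polar", "dG_apolar", "dG_solv", "dG_flexi",
                   "dG_total"))
      expect_equal(b[[term]], a[[term]], tolerance = 1e-6)
  }
})

test_that("adding one ideal H-bond shifts dG by exactly w_hbond and raises
           the score; extra rotatable bonds only lower it", {
  base <- ideal_ser_complex(probe_resname = "BLK")  # inert twin
  hb <- ideal_ser_complex(probe_resname = "ACC")    # same geometry, H-bond
  b0 <- score_complex(base, m0)
  b1 <- score_complex(hb, m0)
  # delta = w_hbond plus release of OG's (now compensated) burial penalty
  burial_relief <- b0$dG_solv - b1$dG_solv
  expect_equal(b1$dG_total - b0$dG_total, m0$w_hbond - burial_relief,
               tolerance = 1e-9)
  expect_gt(burial_relief, -1e-12)
  expect_gt(b1$ludi_score, b0$ludi_score)
  # pure H-bond delta with desolvation disabled
  m_nosolv <- score_model(w_solv = 0)
  d <- score_complex(hb, m_nosolv)$dG_total -
    score_complex(base, m_nosolv)$dG_total
  expect_equal(d, m0$w_hbond, tolerance = 1e-9)
  # rotatable bonds: each chi adds exactly +w_rot when nothing else changes
  sc <- build_gly_scaffold(probe_complex("GGGG"))
  s_ala <- score_complex(place_sidechain(sc, 2, "ALA"), m0)
  s_ser <- score_complex(place_sidechain(sc, 2, "SER", 180), m0)
  expect_equal(s_ser$dG_flexi - s_ala$dG_flexi, m0$w_rot,
               tolerance = 1e-12)
  expect_lt(dg_to_score(m0$w_rot, m0), 0)
})

test_that("with all interaction weights zero the score is the dG0 limit", {
  m_null <- score_model(w_hbond = 0, w_ionic = 0, w_lipo = 0,
                        w_aromatic = 0, w_solv = 0, w_rot = 0)
  for (seed in 1:3) {
    cpx <- random_probe_complex(seed + 200)
    expect_equal(score_complex(cpx, m_null)$ludi_score,
                 dg_to_score(m_null$dG0, m_null), tolerance = 1e-9)
  }
})

test_that("score conversions: printed coefficient, fixed points, and the
           thermodynamic round trip", {
  expect_equal(score_coefficient(298), 73.33, tolerance = 0.01)
  expect_equal(dg_to_score(0, m0), 0)
  expect_equal(dg_to_score(-10, m0), 10 * score_coefficient(298),
               tolerance = 1e-9)
  expect_equal(score_to_ki(0), 1)
  expect_equal(score_to_ki(300), 1e-3, tolerance = 1e-12)
  # dG -> score -> Ki reproduces dG = RT ln Ki
  RT <- 1.9872041e-3 * 298
  for (dG in c(-12.3, -1, 0, 0.7, 5)) {
    ki <- score_to_ki(dg_to_score(dG, m0), m0)
    expect_equal(RT * log(ki), dG, tolerance = 1e-9)
  }
})

test_that("score model validates its invariants", {
  expect_error(score_model(w_hbond = 0.5), "<= 0")
  expect_error(score_model(w_rot = -1), ">= 0")
  expect_error(score_model(dR_tol = 0.8, dR_max = 0.6), "tol < max")
  expect_error(score_model(temperature = -5), "temperature")
})
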