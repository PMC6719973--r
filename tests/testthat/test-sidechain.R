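# scaffold construction, rotamer enumeration, side-chain placement, clashes

test_that("poly-Gly scaffold: sequence, bit-identical backbone, idempotent", {
  cpx <- make_toy_complex(pocket_spec(n_positions = 14,
                                      original = "RGISQAVHAAHAEI",
                                      seed = 5))
  sc <- build_gly_scaffold(cpx)
  expect_equal(peptide_sequence(sc), strrep("G", 14))
  bb0 <- peptide_atoms(cpx)
  bb1 <- peptide_atoms(sc)
  m0 <- bb0[bb0$atom %in% c("N", "CA", "C", "O"), ]
  xyz <- function(a) unname(as.matrix(a[order(a$resno, a$atom),
                                        c("x", "y", "z")]))
  expect_identical(xyz(m0), xyz(bb1))
  sc2 <- build_gly_scaffold(sc)
  expect_identical(sc2$atoms, sc$atoms)
})

test_that("rotamer enumeration counts follow grid^n_chi", {
  expect_equal(nrow(enumerate_rotamers("GLY")$chis), 1L)
  expect_equal(ncol(enumerate_rotamers("GLY")$chis), 0L)
  expect_equal(nrow(enumerate_rotamers("ALA")$chis), 1L)
  expect_equal(nrow(enumerate_rotamers("SER")$chis), 3L)
  expect_equal(nrow(enumerate_rotamers("LYS")$chis), 81L)
  expect_equal(nrow(enumerate_rotamers("SER", grid = c(-170, -60, 60,
                                                       170))$chis), 4L)
  for (code in default_alphabet())
    expect_equal(nrow(enumerate_rotamers(code)$chis), 3L^n_chi(code))
  expect_error(enumerate_rotamers("XXX"), "unknown")
})

test_that("ALA placement adds exactly CB at ideal tetrahedral geometry", {
  sc <- build_gly_scaffold(probe_complex("GGG"))
  mut <- place_sidechain(sc, 2, "ALA")
  added <- setdiff(paste(mut$atoms$resno, mut$atoms$atom),
                   paste(sc$atoms$resno, sc$atoms$atom))
  expect_equal(added, "2 CB")
  pep <- peptide_atoms(mut)
  g <- function(nm) unlist(pep[pep$resno == 2 & pep$atom == nm,
                               c("x", "y", "z")])
  expect_equal(sqrt(sum((g("CB") - g("CA"))^2)), 1.53, tolerance = 1e-6)
  expect_equal(ns$angle3(g("N"), g("CA"), g("CB")), 110.5,
               tolerance = 1e-6)
  # L-configuration: negative improper C-N-CA-CB under the IUPAC dihedral
  # convention (the sign measured on deposited L-protein structures)
  expect_equal(ns$dihedral4(g("C"), g("N"), g("CA"), g("CB")), -122.6,
               tolerance = 1e-6)
})

test_that("GLY placement is the identity on atoms", {
  sc <- build_gly_scaffold(probe_complex("GGG"))
  mut <- place_sidechain(sc, 2, "GLY")
  expect_equal(mut$atoms[, c("resname", "atom", "x", "y", "z")],
               sc$atoms[, c("resname", "atom", "x", "y", "z")])
})

test_that("all-trans LYS reach matches independent forward kinematics", {
  # independent oracle: accumulate the N-CA-CB-CG-CD-CE-NZ chain in 2D;
  # with all dihedrals trans the chain is planar, so place each atom in the
  # plane by alternating the supplement of each bond angle.
  lengths <- c(1.458, 1.530, 1.520, 1.520, 1.520, 1.489)   # N-CA..CE-NZ
  angles <- c(110.5, 114.1, 111.3, 111.3, 111.7)           # N-CA-CB..CD-CE-NZ
  pts <- matrix(0, nrow = 7, ncol = 2)
  pts[2, ] <- c(lengths[1], 0)
  dir <- 0
  for (i in 3:7) {
    turn <- pi - angles[i - 2] * pi / 180
    dir <- dir + turn * (-1)^i
    pts[i, ] <- pts[i - 1, ] + lengths[i - 1] * c(cos(dir), sin(dir))
  }
  expected <- sqrt(sum((pts[7, ] - pts[1, ])^2))

  sc <- build_gly_scaffold(probe_complex("GGG"))
  mut <- place_sidechain(sc, 2, "LYS", c(180, 180, 180, 180))
  pep <- peptide_atoms(mut)
  g <- function(nm) unlist(pep[pep$resno == 2 & pep$atom == nm,
                               c("x", "y", "z")])
  expect_equal(sqrt(sum((g("NZ") - g("N"))^2)), expected,
               tolerance = 1e-6)
})

test_that("backbone stays bit-identical through random substitution chains", {
  sc <- build_gly_scaffold(probe_complex("GGGGGG"))
  xyz <- function(a) unname(as.matrix(a[order(a$resno, a$atom),
                                        c("x", "y", "z")]))
  ref <- xyz(peptide_atoms(sc))
  set.seed(42)
  for (rep in 1:5) {
    cur <- sc
    for (step in 1:6) {
      p <- sample(1:6, 1)
      code <- sample(default_alphabet(), 1)
      cur <- place_sidechain(cur, p, code,
                             sample(c(-60, 60, 180), n_chi(code),
                                    replace = TRUE))
    }
    bb <- peptide_atoms(cur)
    bb <- xyz(bb[bb$atom %in% c("N", "CA", "C", "O"), ])
    expect_identical(bb, ref)
  }
})

test_that("placement errors: unknown code, chi mismatch, PRO", {
  sc <- build_gly_scaffold(probe_complex("GGG"))
  expect_error(place_sidechain(sc, 2, "XYZ"), "unknown")
  expect_error(place_sidechain(sc, 2, "LYS", c(180, 180)), "4 chi")
  expect_error(place_sidechain(sc, 2, "PRO"), "PRO")
  expect_error(place_sidechain(sc, 99, "ALA"), "position")
})

test_that("clash detection: open solvent accepted, overlap rejected,
           infinite tolerance always accepts", {
  sc <- build_gly_scaffold(probe_complex("GGG"))
  mut <- place_sidechain(sc, 2, "SER", -60)
  expect_true(clash_check(mut, 2)$accepted)
  # plant a receptor atom 1.0 A from OG: below any vdW floor
  pep <- peptide_atoms(mut)
  og <- unlist(pep[pep$atom == "OG", c("x", "y", "z")])
  bad <- probe_row("LIP", og + c(1, 0, 0))
  atoms <- rbind(mut$atoms[, names(bad)], bad)
  crowded <- complex_structure(atoms, "P")
  attr(crowded, "substitutions") <- attr(mut, "substitutions")
  chk <- clash_check(crowded, 2)
  expect_false(chk$accepted)
  expect_gt(chk$worst_overlap, 1)
  expect_true(clash_check(crowded, 2, tolerance = Inf)$accepted)
})

test_that("placement is deterministic", {
  sc <- build_gly_scaffold(probe_complex("GGGG"))
  a <- place_sidechain(sc, 3, "TRP", c(-60, 90))
  b <- place_sidechain(sc, 3, "TRP", c(-60, 90))
  expect_identical(a$atoms, b$atoms)
})
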