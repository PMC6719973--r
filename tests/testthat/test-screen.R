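# stage-1 scan, candidate selection, library combinatorics, stage-2 ranking

test_that("stage-1 finds the planted donor partner and respects frozen
           positions", {
  sp <- pocket_spec(n_positions = 6, planted = list(`3` = "SER"), seed = 11)
  cpx <- make_toy_complex(sp)
  tab <- stage1_scan(cpx, frozen = c(1, 2, 4, 5, 6))
  expect_setequal(tab$scanned, 3)
  expect_null(tab$entries[["1"]])
  cl <- candidate_lists(tab)
  expect_equal(cl[["3"]]$code[1], "SER")
  # hydroxyl/amide donors outrank pure hydrophobes at a planted acceptor
  hydroph <- match(c("LEU", "ILE", "VAL"), cl[["3"]]$code)
  expect_true(all(is.na(hydroph) |
                    hydroph > match("SER", cl[["3"]]$code)))
})

test_that("with all interaction weights zero no residue beats the baseline", {
  m_null <- score_model(w_hbond = 0, w_ionic = 0, w_lipo = 0,
                        w_aromatic = 0, w_solv = 0, w_rot = 0)
  sp <- pocket_spec(n_positions = 4, planted = list(`2` = "SER"), seed = 2)
  cpx <- make_toy_complex(sp)
  tab <- stage1_scan(cpx, model = m_null, frozen = c(1, 3, 4))
  expect_equal(nrow(candidate_lists(tab)[["2"]]), 0L)
})

test_that("automatic freezing follows pocket contacts", {
  sp <- pocket_spec(n_positions = 6, planted = list(`3` = "SER"), seed = 4)
  cpx <- make_toy_complex(sp)
  tab <- stage1_scan(cpx, alphabet = c("ALA", "SER"))
  # terminal residues have no pocket site within reach and freeze themselves
  expect_true(1 %in% tab$frozen)
  expect_true(6 %in% tab$frozen)
  expect_false(3 %in% tab$frozen)
})

test_that("candidate selection reproduces the packaged manual choice", {
  tab <- fixture_candidate_table()
  rule <- fixture_selection_rule()
  sets <- select_candidates(tab, top_k = rule$top_k, forced = rule$forced,
                            frozen = rule$frozen)
  expect_equal(unname(lengths(sets$sets)),
               c(1, 1, 1, 4, 3, 3, 2, 3, 2, 2, 2, 2, 1, 1))
  expect_equal(library_size(sets), 3456)
  # spot checks against the starred table entries
  expect_setequal(sets$sets[["4"]], c("SER", "PHE", "LEU", "ILE"))
  expect_setequal(sets$sets[["9"]], c("ALA", "GLY"))
  expect_equal(sets$sets[["13"]], "GLU")
})

test_that("selection edge cases: k = 0, forced extras, invalid k", {
  tab <- fixture_candidate_table()
  all_orig <- select_candidates(tab, top_k = 0)
  expect_true(all(lengths(all_orig$sets) == 1))
  expect_equal(library_size(all_orig), 1)
  forced <- select_candidates(tab, top_k = 0,
                              forced = list(`9` = "GLY"))
  expect_setequal(forced$sets[["9"]], c("ALA", "GLY"))
  expect_error(select_candidates(tab, top_k = -1), ">= 0")
})

test_that("library size is the exact product", {
  expect_equal(library_size(c(5, 6, 8, 5, 4, 4, 3, 8, 1, 1, 8, 2, 5, 2)),
               73728000)
  expect_equal(library_size(c(1, 1, 1, 4, 3, 3, 2, 3, 2, 2, 2, 2, 1, 1)),
               3456)
  expect_equal(library_size(rep(1, 14)), 1)
  expect_error(library_size(numeric(0)), "empty")
  expect_error(library_size(c(2, 0)), ">= 1")
})

test_that("stage-2 matches the independent brute-force oracle exactly", {
  set.seed(99)
  for (trial in 1:3) {
    planted <- list(`2` = "SER", `4` = "LYS")
    sp <- pocket_spec(n_positions = 5, planted = planted,
                      seed = 300 + trial)
    cpx <- make_toy_complex(sp)
    pool <- c("ALA", "SER", "THR", "LEU", "ASN", "LYS")
    sets <- candidate_sets(
      sets = list(`2` = sample(pool, 2), `3` = sample(pool, 2),
                  `4` = sample(pool, 2)),
      original = stats::setNames(rep("GLY", 5), 1:5),
      frozen = c(1L, 5L))
    got <- stage2_enumerate(cpx, sets)
    want <- oracle_stage2(cpx, sets)
    expect_equal(got$ranking$sequence, want$sequence)
    expect_equal(got$ranking$score, want$score, tolerance = 1e-9)
  }
})

test_that("stage-2 output is complete, duplicate-free, rank-contiguous and
           insertion-order independent", {
  sp <- pocket_spec(n_positions = 5, planted = list(`3` = "SER"), seed = 31)
  cpx <- make_toy_complex(sp)
  original <- stats::setNames(rep("GLY", 5), 1:5)
  s1 <- candidate_sets(list(`2` = c("ALA", "SER"),
                            `3` = c("SER", "THR", "ALA"),
                            `4` = c("LEU", "ALA")),
                       original, frozen = c(1L, 5L))
  s2 <- candidate_sets(list(`2` = c("SER", "ALA"),
                            `3` = c("ALA", "SER", "THR"),
                            `4` = c("ALA", "LEU")),
                       original, frozen = c(1L, 5L))
  r1 <- stage2_enumerate(cpx, s1)
  r2 <- stage2_enumerate(cpx, s2)
  expect_equal(nrow(r1$ranking), library_size(s1))
  expect_equal(anyDuplicated(r1$ranking$sequence), 0L)
  expect_equal(r1$ranking$rank, seq_len(nrow(r1$ranking)))
  expect_true(all(diff(r1$ranking$score) <= 1e-12))
  expect_identical(r1$ranking, r2$ranking)
  # the original sequence appears exactly once and its rank is reported
  expect_equal(sum(r1$ranking$sequence == r1$original_sequence), 1L)
  expect_equal(r1$ranking$score[r1$ranking$rank == r1$original_rank],
               r1$ranking$score[r1$ranking$sequence ==
                                  r1$original_sequence])
})

test_that("ranked scores equal a fresh rebuild-and-rescore", {
  sp <- pocket_spec(n_positions = 5, planted = list(`3` = "LYS"), seed = 77)
  cpx <- make_toy_complex(sp)
  sets <- candidate_sets(list(`3` = c("LYS", "ARG")),
                         stats::setNames(rep("GLY", 5), 1:5),
                         frozen = c(1L, 2L, 4L, 5L))
  res <- stage2_enumerate(cpx, sets)
  orc <- oracle_stage2(cpx, sets)
  expect_equal(res$ranking$score, orc$score, tolerance = 1e-9)
})

test_that("enumeration cap triggers an instructive error", {
  sp <- pocket_spec(n_positions = 4, seed = 1)
  cpx <- make_toy_complex(sp)
  sets <- candidate_sets(list(`2` = c("ALA", "SER", "THR"),
                              `3` = c("ALA", "SER", "THR")),
                         stats::setNames(rep("GLY", 4), 1:4))
  expect_error(stage2_enumerate(cpx, sets, cap = 4), "tighten")
})

test_that("top_peptides slices, annotates Hamming distance, and warns on
           overlong requests", {
  expect_equal(hamming_distance("RGISQAVHAAHAEI", "RGIFFYVFAAYKEI"), 6L)
  expect_error(hamming_distance("AA", "AAA"), "length")
  sp <- pocket_spec(n_positions = 4, planted = list(`2` = "SER"), seed = 8)
  cpx <- make_toy_complex(sp)
  sets <- candidate_sets(list(`2` = c("SER", "ALA"), `3` = c("ALA")),
                         stats::setNames(rep("GLY", 4), 1:4),
                         frozen = c(1L, 4L))
  res <- stage2_enumerate(cpx, sets)
  top <- top_peptides(res, 1)
  expect_equal(nrow(top), 1L)
  expect_equal(top$rank, 1L)
  expect_true(all(c("sequence", "score", "hamming") %in% names(top)))
  expect_warning(full <- top_peptides(res, 100), "exceeds")
  expect_equal(nrow(full), nrow(res$ranking))
  expect_equal(full$hamming[full$sequence == res$original_sequence], 0L)
})
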