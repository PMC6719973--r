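# Shared fixture builders (all in code, no files) and independent oracles.

ns <- asNamespace("agrescreen")

# bare peptide: ideal extended backbone, residue names from a 1-letter seq
bare_peptide_atoms <- function(seq1, chain = "P") {
  n <- nchar(seq1)
  codes <- ns$seq1_to_codes(seq1)
  bb <- ns$build_ideal_backbone(n)
  do.call(rbind, lapply(seq_len(n), function(i) {
    xyz <- do.call(rbind, bb[[i]])
    data.frame(chain = chain, resno = i, resname = codes[i],
               atom = rownames(xyz), element = substr(rownames(xyz), 1, 1),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1,
               stringsAsFactors = FALSE)
  }))
}

# single receptor pseudo-atom row
probe_row <- function(resname, pos, resno = 1L) {
  el <- switch(resname, ACC = "O", ANI = "O", DNR = "N", CAT = "N", "C")
  at <- if (el == "O") "O1" else if (el == "N") "N1" else "C1"
  data.frame(chain = "R", resno = resno, resname = resname, atom = at,
             element = el, x = pos[1], y = pos[2], z = pos[3],
             occupancy = 1, stringsAsFactors = FALSE)
}

# minimal complex: bare peptide + arbitrary probe rows
probe_complex <- function(seq1 = "GGGG", probes = NULL) {
  atoms <- bare_peptide_atoms(seq1)
  if (!is.null(probes)) atoms <- rbind(atoms, probes)
  complex_structure(atoms, "P", source = "test")
}

# a quick complex with randomly typed, randomly placed probes and one or two
# placed side chains; cheap substrate for additivity / invariance sweeps
random_probe_complex <- function(seed) {
  set.seed(seed)
  L <- 6L
  cpx <- probe_complex(strrep("G", L))
  sc_pos <- sample(2:(L - 1), 2)
  codes <- sample(c("SER", "LYS", "PHE", "ASN", "LEU", "THR", "ASP"), 2)
  for (i in 1:2) {
    k <- n_chi(codes[i])
    cpx <- place_sidechain(cpx, sc_pos[i], codes[i],
                           sample(c(-60, 60, 180), k, replace = TRUE))
  }
  pep <- peptide_atoms(cpx)
  probes <- do.call(rbind, lapply(1:8, function(j) {
    base <- pep[sample.int(nrow(pep), 1), ]
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    pos <- c(base$x, base$y, base$z) + runif(1, 3.2, 6) * dir
    probe_row(sample(c("ACC", "DNR", "ANI", "CAT", "LIP", "BLK"), 1), pos,
              resno = j)
  }))
  atoms <- rbind(cpx$atoms[, names(probes)], probes)
  out <- complex_structure(atoms, "P", source = paste0("random", seed))
  attr(out, "substitutions") <- attr(cpx, "substitutions")
  out
}

# ---- independent oracles ----------------------------------------------------

# independent SASA: latitude-longitude quadrature instead of the golden
# spiral, plain R. Accurate enough on small atom sets for coarse comparison.
oracle_sasa <- function(atoms, query_rows, probe = 1.4, n_lat = 60) {
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  radii <- ns$vdw_radius(atoms$element) + probe
  vapply(query_rows, function(i) {
    Ri <- radii[i]
    lat <- (seq_len(n_lat) - 0.5) / n_lat * pi  # colatitude band centers
    total <- 0
    for (th in lat) {
      n_lon <- max(6L, round(2 * n_lat * sin(th)))
      phi <- (seq_len(n_lon) - 0.5) / n_lon * 2 * pi
      pts <- cbind(sin(th) * cos(phi), sin(th) * sin(phi), rep(cos(th),
                                                               n_lon))
      sp <- sweep(Ri * pts, 2, xyz[i, ], `+`)
      occl <- rep(FALSE, n_lon)
      for (j in seq_len(nrow(xyz))) {
        if (j == i) next
        dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        occl <- occl | dj2 < radii[j]^2
      }
      band_area <- 2 * pi * Ri^2 * (cos(th - pi / (2 * n_lat)) -
                                      cos(th + pi / (2 * n_lat)))
      total <- total + band_area * mean(!occl)
    }
    total
  }, numeric(1))
}

# independent brute-force stage-2 oracle: its own cross product, its own
# greedy left-to-right rotamer choice (same declared rule), assembly via
# place_sidechain, ranking via order(). Shares only the scoring function.
oracle_stage2 <- function(complex, sets, model = score_model()) {
  scaffold <- build_gly_scaffold(complex)
  positions <- sort(unique(peptide_atoms(complex)$resno))
  keys <- as.character(positions)
  # per (position, code): rotamers ranked by single-substitution score
  rank_rotamers <- function(p, code) {
    rs <- enumerate_rotamers(code)
    rows <- list()
    for (r in seq_len(nrow(rs$chis))) {
      s <- place_sidechain(scaffold, p, code, rs$chis[r, ])
      if (!clash_check(s, p, model$clash_tolerance)$accepted) next
      rows[[length(rows) + 1]] <-
        list(r = r, chis = rs$chis[r, ],
             score = score_complex(s, model)$ludi_score)
    }
    if (!length(rows)) return(NULL)
    sc <- vapply(rows, `[[`, numeric(1), "score")
    idx <- vapply(rows, `[[`, numeric(1), "r")
    rows[order(-sc, idx)]
  }
  memo <- list()
  get_ranked <- function(p, code) {
    key <- paste(p, code)
    if (is.null(memo[[key]])) memo[[key]] <<- rank_rotamers(p, code)
    memo[[key]]
  }
  grid_sets <- lapply(sets$sets[keys], sort)
  combos <- do.call(expand.grid,
                    c(rev(grid_sets), stringsAsFactors = FALSE))
  combos <- combos[, rev(seq_along(grid_sets)), drop = FALSE]
  names(combos) <- keys
  n <- nrow(combos)
  seqs <- character(n); scores <- numeric(n)
  for (i in seq_len(n)) {
    built <- scaffold
    placed_atoms <- NULL
    for (j in seq_along(positions)) {
      code <- combos[i, j]
      if (code == "GLY") next
      ranked <- get_ranked(positions[j], code)
      if (is.null(ranked)) {
        # no receptor-feasible rotamer: the residue identity stays in the
        # sequence on a bare backbone (same declared rule as the pipeline)
        atoms <- built$atoms
        atoms$resname[atoms$chain == "P" &
                        atoms$resno == positions[j]] <- code
        built <- complex_structure(atoms, "P", source = built$source)
        next
      }
      pick <- NULL
      for (e in ranked) {
        trial <- place_sidechain(built, positions[j], code, e$chis)
        sc_rows <- trial$atoms[trial$atoms$chain == "P" &
                                 trial$atoms$resno == positions[j] &
                                 !trial$atoms$atom %in%
                                 c("N", "CA", "C", "O"), , drop = FALSE]
        ok <- TRUE
        if (!is.null(placed_atoms) && nrow(sc_rows)) {
          # same declared contact rule as the pipeline, incl. the reduced
          # clash floor for hydrogen-bond-capable pairs
          ok <- max(ns$pair_overlap(sc_rows, placed_atoms)) < 0.4
        }
        if (ok) { pick <- list(trial = trial, sc = sc_rows); break }
      }
      if (is.null(pick)) {
        e <- ranked[[1]]
        trial <- place_sidechain(built, positions[j], code, e$chis)
        sc_rows <- trial$atoms[trial$atoms$chain == "P" &
                                 trial$atoms$resno == positions[j] &
                                 !trial$atoms$atom %in%
                                 c("N", "CA", "C", "O"), , drop = FALSE]
        pick <- list(trial = trial, sc = sc_rows)
      }
      built <- pick$trial
      if (nrow(pick$sc))
        placed_atoms <- rbind(placed_atoms, pick$sc)
    }
    seqs[i] <- ns$codes_to_seq1(unlist(combos[i, ]))
    scores[i] <- score_complex(built, model)$ludi_score
  }
  ord <- order(-scores, seqs)
  data.frame(rank = seq_len(n), sequence = seqs[ord], score = scores[ord],
             stringsAsFactors = FALSE)
}
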