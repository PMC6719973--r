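# Two-stage screen: positional scan against the poly-Gly baseline, candidate
# selection, exhaustive combinatorial enumeration and ranking.
#
# Stage-1 context is the all-Gly scaffold: substitutions are scored one at a
# time, so inter-substitution coupling only enters in stage 2. Stage 2 places
# rotamers greedily per position in left-to-right order (no combinatorial
# rotamer search): at each position the best-scoring receptor-feasible
# rotamer that does not clash with already-placed side chains is used.

# --- rotamer cache -----------------------------------------------------------

# For one scaffold, precompute per (position, code): every grid rotamer's
# side-chain atom block, receptor/backbone feasibility, and its
# single-substitution ludi score on the scaffold. Entries are sorted by
# score (desc), ties by rotamer index (asc, stable).
#' @keywords internal
build_rotamer_cache <- function(scaffold, positions, codes, model,
                                grid = c(-60, 60, 180)) {
  atoms <- scaffold$atoms
  pchain <- scaffold$peptide_chain
  pep <- atoms$chain == pchain
  env_all <- atoms  # receptor + scaffold backbone
  # far-field shortcut: a side chain > FARFIELD from every receptor atom
  # changes no interaction term, so its score is the scaffold's plus the
  # rotatable-bond penalty (exact; see methods vignette)
  FARFIELD <- 8
  rec_xyz <- coords(atoms[!pep, , drop = FALSE])
  pocket <- new_pocket(atoms[!pep, , drop = FALSE], Inf)
  base <- score_complex(scaffold, model, pocket)
  far_score <- function(code)
    dg_to_score(model$dG0 + base$dG_polar + base$dG_apolar + base$dG_solv +
                  (base$dG_flexi + model$w_rot * n_chi(code)), model)
  cache <- list()
  for (p in positions) {
    here <- pep & atoms$resno == p
    bb <- atoms[here, , drop = FALSE]
    getx <- function(nm) {
      i <- which(bb$atom == nm)
      c(bb$x[i], bb$y[i], bb$z[i])
    }
    N <- getx("N"); CA <- getx("CA"); C <- getx("C")
    env <- env_all[!(env_all$chain == pchain & env_all$resno == p), ,
                   drop = FALSE]
    cb_exempt <- env$chain == pchain &
      ((env$resno == p - 1 & env$atom == "C") |
         (env$resno == p + 1 & env$atom == "N"))
    slot <- list()
    for (code in codes) {
      rs <- enumerate_rotamers(code, grid)
      nr <- nrow(rs$chis)
      entries <- vector("list", nr)
      for (r in seq_len(nr)) {
        sc <- build_sidechain_atoms(code, N, CA, C, rs$chis[r, ])
        block <- annotate_block(sc, pchain, p, code)
        feasible <- TRUE
        if (nrow(sc)) {
          ov <- pair_overlap(block, env)
          ov[block$atom == "CB", cb_exempt] <- -Inf
          feasible <- max(ov) < model$clash_tolerance
        }
        if (!feasible) next
        if (nrow(sc) == 0 ||
            min(.min_dist_cpp(coords(sc), rec_xyz)) > FARFIELD) {
          sco <- far_score(code)
        } else {
          sub <- assemble_structure(scaffold, list(block),
                                    stats::setNames(code, p))
          sco <- score_complex(sub, model, pocket)$ludi_score
        }
        entries[[r]] <- list(rotamer = r, chis = rs$chis[r, ],
                             block = block, score = sco)
      }
      entries <- entries[!vapply(entries, is.null, logical(1))]
      if (length(entries)) {
        scores <- vapply(entries, `[[`, numeric(1), "score")
        entries <- entries[order(-scores,
                                 vapply(entries, `[[`, numeric(1), "rotamer"))]
      }
      slot[[code]] <- entries
    }
    cache[[as.character(p)]] <- slot
  }
  cache
}

# annotate a bare side-chain atom data.frame as peptide atom rows
#' @keywords internal
annotate_block <- function(sc, chain, position, code) {
  if (!nrow(sc))
    return(empty_atom_table()[, c("chain", "resno", "resname", "atom",
                                  "element", "x", "y", "z", "occupancy",
                                  "donor", "acceptor", "charge",
                                  "lipophilic")])
  df <- data.frame(chain = chain, resno = position, resname = code,
                   atom = sc$atom, element = sc$element,
                   x = sc$x, y = sc$y, z = sc$z, occupancy = 1,
                   stringsAsFactors = FALSE)
  annotate_chemistry(df)
}

# scaffold + side-chain blocks -> complex_structure (flags kept, 1 validate)
#' @keywords internal
assemble_structure <- function(scaffold, blocks, codes_by_pos) {
  atoms <- scaffold$atoms
  pchain <- scaffold$peptide_chain
  for (p in names(codes_by_pos))
    atoms$resname[atoms$chain == pchain &
                    atoms$resno == as.integer(p)] <- codes_by_pos[[p]]
  blocks <- blocks[vapply(blocks, nrow, integer(1)) > 0]
  if (length(blocks)) {
    bl <- do.call(rbind, blocks)
    common <- intersect(names(atoms), names(bl))
    atoms <- rbind(atoms[, common, drop = FALSE],
                   bl[, common, drop = FALSE])
    atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  complex_structure(atoms, pchain, source = scaffold$source,
                    annotate = FALSE)
}

# --- stage 1 -----------------------------------------------------------------

#' Stage-1 positional scan against the Gly baseline
#'
#' Builds the poly-Gly scaffold, then for each unfrozen position places every
#' alphabet residue one at a time (best feasible grid rotamer by score, all
#' other positions Gly) and records its ludi score. Residues whose best score
#' strictly exceeds the scaffold baseline form the per-position candidate
#' lists, sorted descending (ties alphabetical). Residues for which every
#' rotamer clashes are marked infeasible and excluded.
#'
#' @param complex a [complex_structure()] (template peptide bound to the
#'   receptor).
#' @param model a [score_model()].
#' @param alphabet residue codes to scan (default [default_alphabet()]).
#' @param frozen positions left untouched (kept as the original residue). If
#'   NULL, positions with no pocket site within `freeze_cutoff` of their
#'   backbone are frozen automatically (residues not in contact with the
#'   receptor).
#' @param grid chi grid for [enumerate_rotamers()].
#' @param freeze_cutoff contact distance (A) for the automatic freeze rule;
#'   generous by default because it is measured from backbone atoms.
#' @return object of class `candidate_table`.
#' @export
stage1_scan <- function(complex, model = score_model(),
                        alphabet = default_alphabet(), frozen = NULL,
                        grid = c(-60, 60, 180), freeze_cutoff = 8) {
  positions <- peptide_positions(complex)
  original <- seq1_to_codes(peptide_sequence(complex))
  names(original) <- positions
  if (is.null(frozen)) {
    frozen <- positions[vapply(positions, function(p)
      nrow(peptide_position_contacts(complex, p, freeze_cutoff)) == 0,
      logical(1))]
  }
  stopifnot(all(frozen %in% positions))
  scanned <- setdiff(positions, frozen)
  scaffold <- build_gly_scaffold(complex)
  baseline <- score_complex(scaffold, model)$ludi_score
  alphabet <- sort(toupper(alphabet))
  cache <- build_rotamer_cache(scaffold, scanned, alphabet, model, grid)
  entries <- list()
  for (p in scanned) {
    slot <- cache[[as.character(p)]]
    best <- vapply(alphabet, function(code) {
      e <- slot[[code]]
      if (!length(e)) NA_real_ else e[[1]]$score
    }, numeric(1))
    df <- data.frame(code = alphabet, score = unname(best),
                     feasible = !is.na(best), stringsAsFactors = FALSE)
    entries[[as.character(p)]] <- df[order(-ifelse(is.na(df$score), -Inf,
                                                   df$score), df$code), ]
  }
  out <- list(positions = positions, original = original,
              gly_score = baseline, entries = entries, frozen = frozen,
              scanned = scanned, grid = grid)
  attr(out, "cache") <- cache
  attr(out, "scaffold") <- scaffold
  class(out) <- "candidate_table"
  out
}

#' Per-position candidate lists of a stage-1 scan
#'
#' Residues scoring strictly above the Gly baseline, in descending score
#' order (the shape of a first-screen results table).
#'
#' @param table a `candidate_table` from [stage1_scan()].
#' @return named list (by position) of data frames (code, score).
#' @export
candidate_lists <- function(table) {
  lapply(table$entries, function(df) {
    df <- df[df$feasible & df$score > table$gly_score, , drop = FALSE]
    rownames(df) <- NULL
    df[, c("code", "score")]
  })
}

#' @export
print.candidate_table <- function(x, ...) {
  cat("<candidate_table> baseline (Gly scaffold) score ",
      sprintf("%.1f", x$gly_score), "\n", sep = "")
  cl <- candidate_lists(x)
  for (p in x$positions) {
    key <- as.character(p)
    if (p %in% x$frozen) {
      cat(sprintf("  %2d %s frozen\n", p, x$original[key]))
    } else {
      df <- cl[[key]]
      cat(sprintf("  %2d %s: %s\n", p, x$original[key],
                  if (nrow(df)) paste(df$code, collapse = " ") else "-"))
    }
  }
  invisible(x)
}

# --- candidate selection -----------------------------------------------------

#' Construct per-position candidate sets
#'
#' @param sets named list (position -> character vector of 3-letter codes).
#' @param original named character vector of original codes per position.
#' @param frozen frozen positions (their sets collapse to the original).
#' @return object of class `candidate_sets`.
#' @export
candidate_sets <- function(sets, original, frozen = integer(0)) {
  positions <- as.integer(names(original))
  out <- stats::setNames(vector("list", length(positions)),
                         names(original))
  for (p in positions) {
    key <- as.character(p)
    s <- if (p %in% frozen) character(0) else toupper(sets[[key]])
    s <- unique(c(original[[key]], s))
    out[[key]] <- s
  }
  x <- list(sets = out, original = original, frozen = frozen)
  class(x) <- "candidate_sets"
  x
}

#' @export
print.candidate_sets <- function(x, ...) {
  cat("<candidate_sets> library size ", format(library_size(x),
                                               big.mark = ","), "\n",
      sep = "")
  for (key in names(x$sets))
    cat(sprintf("  %2s: %s%s\n", key, paste(x$sets[[key]], collapse = " "),
                if (as.integer(key) %in% x$frozen) " (frozen)" else ""))
  invisible(x)
}

#' Select stage-2 candidate sets from a stage-1 table
#'
#' Declarative replacement for the manual curation step: per position the
#' set is the top-k residues scoring strictly above the original residue,
#' plus the original itself, plus any forced extras; frozen positions
#' collapse to the original residue.
#'
#' @param table a `candidate_table` from [stage1_scan()] (or a fixture with
#'   the same shape).
#' @param top_k non-negative integer, scalar or named per-position vector.
#' @param forced named list (position -> codes always included, e.g. Gly at
#'   positions with empty candidate lists).
#' @param frozen positions frozen in addition to the table's own.
#' @return a [candidate_sets()] object.
#' @export
select_candidates <- function(table, top_k = 3, forced = list(),
                              frozen = NULL) {
  if (any(top_k < 0)) stop("top_k must be >= 0")
  frozen <- sort(union(table$frozen, frozen))
  sets <- list()
  for (p in table$positions) {
    key <- as.character(p)
    if (p %in% frozen) { sets[[key]] <- character(0); next }
    k <- if (length(top_k) > 1) top_k[[key]] else top_k
    df <- table$entries[[key]]
    orig <- table$original[[key]]
    orig_score <- df$score[df$code == orig][1]
    if (is.na(orig_score)) orig_score <- table$gly_score
    above <- df[df$feasible & !is.na(df$score) & df$score > orig_score, ,
                drop = FALSE]
    above <- above[order(-above$score, above$code), , drop = FALSE]
    sets[[key]] <- c(utils::head(above$code, k),
                     toupper(unlist(forced[[key]])))
  }
  candidate_sets(sets, table$original, frozen)
}

#' Combinatorial library size
#'
#' Exact product of per-position candidate counts.
#'
#' @param x a `candidate_sets` object or a numeric vector of counts.
#' @return numeric scalar (exact integer value).
#' @export
#' @examples
#' library_size(c(5, 6, 8, 5, 4, 4, 3, 8, 1, 1, 8, 2, 5, 2))
library_size <- function(x) {
  counts <- if (inherits(x, "candidate_sets")) lengths(x$sets) else x
  if (!length(counts)) stop("empty candidate sets")
  if (any(counts < 1)) stop("all per-position counts must be >= 1")
  prod(as.numeric(counts))
}

# --- stage 2 -----------------------------------------------------------------

#' Stage-2 exhaustive enumeration and ranking
#'
#' Builds every cross-product sequence of the candidate sets on the poly-Gly
#' scaffold (greedy best feasible rotamer per substituted position, fixed
#' left-to-right order), scores each full complex, and ranks by descending
#' ludi score with deterministic lexicographic tie-break on the 1-letter
#' sequence. A residue with no receptor-feasible rotamer at its position
#' keeps its identity in the sequence (and its rotatable-bond penalty) but
#' is left without side-chain atoms; if every cached rotamer clashes with
#' earlier placements the best receptor-feasible one is used regardless.
#'
#' @param complex a [complex_structure()].
#' @param sets a [candidate_sets()] object.
#' @param model a [score_model()].
#' @param cap refuse to enumerate libraries larger than this (default 1e6).
#' @param grid chi grid for rotamer placement.
#' @return object of class `screen_result`: `ranking` data frame (rank,
#'   sequence, score), `original_sequence`, `original_rank`.
#' @export
stage2_enumerate <- function(complex, sets, model = score_model(),
                             cap = 1e6, grid = c(-60, 60, 180)) {
  n_total <- library_size(sets)
  if (n_total > cap)
    stop("library size ", format(n_total, big.mark = ","),
         " exceeds cap ", format(cap, big.mark = ","),
         "; tighten the candidate sets or raise `cap`")
  scaffold <- build_gly_scaffold(complex)
  positions <- peptide_positions(complex)
  keys <- as.character(positions)
  # canonical in-set order: alphabetical (ranking is order-independent, this
  # just makes the enumeration order reproducible)
  setlist <- lapply(sets$sets[keys], sort)
  codes_needed <- lapply(setlist, unique)
  cache <- build_cache_for_sets(scaffold, positions, codes_needed, model,
                                grid)
  combos <- expand.grid(setlist, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  names(combos) <- keys
  n <- nrow(combos)
  pocket <- new_pocket(receptor_atoms(scaffold), Inf)
  seqs <- character(n)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    codes <- as.character(combos[i, ])
    built <- greedy_build(scaffold, positions, codes, cache,
                          model$clash_tolerance)
    seqs[i] <- codes_to_seq1(codes)
    scores[i] <- score_complex(built, model, pocket)$ludi_score
  }
  ord <- order(-scores, seqs)
  ranking <- data.frame(rank = seq_len(n), sequence = seqs[ord],
                        score = scores[ord], stringsAsFactors = FALSE)
  orig_seq <- peptide_sequence(complex)
  orig_rank <- ranking$rank[ranking$sequence == orig_seq]
  out <- list(ranking = ranking, original_sequence = orig_seq,
              original_rank = if (length(orig_rank)) orig_rank[1]
              else NA_integer_)
  class(out) <- "screen_result"
  out
}

#' @keywords internal
build_cache_for_sets <- function(scaffold, positions, codes_needed, model,
                                 grid) {
  cache <- list()
  for (i in seq_along(positions)) {
    p <- positions[i]
    cache[[as.character(p)]] <-
      build_rotamer_cache(scaffold, p, codes_needed[[i]], model,
                          grid)[[as.character(p)]]
  }
  cache
}

# left-to-right greedy rotamer placement for a full sequence
#' @keywords internal
greedy_build <- function(scaffold, positions, codes, cache,
                         clash_tolerance = 0.4) {
  placed <- list()
  placed_df <- NULL
  for (i in seq_along(positions)) {
    p <- positions[i]
    code <- codes[i]
    if (code == "GLY") next
    entries <- cache[[as.character(p)]][[code]]
    chosen <- NULL
    if (length(entries)) {
      for (e in entries) {
        if (is.null(placed_df) || !nrow(e$block)) { chosen <- e; break }
        if (max(pair_overlap(e$block, placed_df)) < clash_tolerance) {
          chosen <- e; break
        }
      }
      # all rotamers clash with earlier placements: fall back to the best
      # receptor-feasible one (deterministic, documented)
      if (is.null(chosen)) chosen <- entries[[1]]
    } else {
      # no receptor-feasible rotamer at all: leave the backbone bare
      next
    }
    placed[[as.character(p)]] <- chosen$block
    if (nrow(chosen$block))
      placed_df <- rbind(placed_df, chosen$block)
  }
  assemble_structure(scaffold, placed,
                     stats::setNames(codes, positions))
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> ", nrow(x$ranking), " sequences; original ",
      x$original_sequence, " at rank ", x$original_rank, "\n", sep = "")
  print(utils::head(x$ranking, 10), row.names = FALSE)
  invisible(x)
}

#' Top-ranked peptides of a screen
#'
#' First `n` rows of the ranking, annotated with the Hamming distance to the
#' original sequence.
#'
#' @param result a `screen_result`.
#' @param n number of rows (if `n` exceeds the library size the full table
#'   is returned with a warning).
#' @return data frame: rank, sequence, score, hamming.
#' @export
top_peptides <- function(result, n = 10) {
  stopifnot(n >= 1)
  rk <- result$ranking
  if (n > nrow(rk)) {
    warning("n = ", n, " exceeds the ", nrow(rk), " ranked sequences")
    n <- nrow(rk)
  }
  out <- utils::head(rk, n)
  out$hamming <- vapply(out$sequence, hamming_distance,
                        integer(1), result$original_sequence)
  rownames(out) <- NULL
  out
}

#' Hamming distance between two equal-length sequences
#' @param a,b character scalars of equal nchar.
#' @return integer.
#' @export
#' @examples
#' hamming_distance("RGISQAVHAAHAEI", "RGIFFYVFAAYKEI")
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Run the full two-stage screen
#'
#' Convenience wrapper: stage-1 scan, candidate selection, stage-2
#' enumeration.
#'
#' @inheritParams stage1_scan
#' @inheritParams select_candidates
#' @inheritParams stage2_enumerate
#' @return list: `table` (stage 1), `sets`, `result` (stage 2).
#' @export
run_screen <- function(complex, model = score_model(),
                       alphabet = default_alphabet(), frozen = NULL,
                       top_k = 3, forced = list(), cap = 1e6,
                       grid = c(-60, 60, 180)) {
  table <- stage1_scan(complex, model, alphabet, frozen, grid)
  sets <- select_candidates(table, top_k = top_k, forced = forced)
  result <- stage2_enumerate(complex, sets, model, cap = cap, grid = grid)
  list(table = table, sets = sets, result = result)
}
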