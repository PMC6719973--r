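# Minimal PDB v3.3 ATOM-record reader/writer.
#
# Scope is deliberately narrow: ATOM records of protein chains plus the
# generator's pseudo-residues. HETATM records, waters and hydrogens are
# dropped on read; altloc conformers collapse to the highest-occupancy copy.

#' Read a peptide-receptor complex from a PDB file
#'
#' Parses fixed-width ATOM records, drops waters/heteroatoms/hydrogens,
#' collapses alternate locations to the highest-occupancy conformer, and
#' annotates interaction chemistry (donor/acceptor/charge/lipophilic) from
#' the packaged per-residue tables. The peptide chain must be named
#' explicitly; chain naming of deposited MHC structures varies by source, so
#' no auto-detection is attempted.
#'
#' @param path PDB file path.
#' @param peptide_chain chain id of the bound peptide.
#' @return a [complex_structure()].
#' @export
read_pdb <- function(path, peptide_chain) {
  lines <- readLines(path, warn = FALSE)
  rec <- substring(lines, 1, 6)
  lines <- lines[rec == "ATOM  "]
  if (!length(lines)) stop("no ATOM records in ", path)
  fw <- function(from, to) trimws(substring(lines, from, to))
  atoms <- data.frame(
    atom = fw(13, 16),
    altloc = fw(17, 17),
    resname = fw(18, 20),
    chain = fw(22, 22),
    resno = as.integer(fw(23, 26)),
    x = as.numeric(fw(31, 38)),
    y = as.numeric(fw(39, 46)),
    z = as.numeric(fw(47, 54)),
    occupancy = suppressWarnings(as.numeric(fw(55, 60))),
    element = fw(77, 78),
    stringsAsFactors = FALSE)
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  no_el <- atoms$element == ""
  atoms$element[no_el] <- substring(gsub("[0-9']", "", atoms$atom[no_el]), 1, 1)
  atoms <- atoms[atoms$resname != "HOH" & toupper(atoms$element) != "H", ,
                 drop = FALSE]
  # altloc: keep the highest-occupancy conformer (first wins ties)
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  atoms <- atoms[order(key, -atoms$occupancy), , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$atom)), ,
                 drop = FALSE]
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  if (!peptide_chain %in% atoms$chain)
    stop("peptide chain '", peptide_chain, "' not found; available chains: ",
         paste(sort(unique(atoms$chain)), collapse = ", "))
  complex_structure(atoms, peptide_chain, source = basename(path))
}

#' Write a complex structure to a PDB file
#'
#' Emits standard ATOM records (coordinates to 3 decimals) with TER records
#' between chains, so that `read_pdb(write_pdb(x))` round-trips residue
#' codes, chain ids, atom names and coordinates.
#'
#' @param structure a [complex_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  atoms <- structure$atoms
  # peptide chain last, receptor chains first, residues in order
  chains <- c(setdiff(sort(unique(atoms$chain)), structure$peptide_chain),
              structure$peptide_chain)
  out <- character(0)
  serial <- 0L
  for (ch in chains) {
    a <- atoms[atoms$chain == ch, , drop = FALSE]
    a <- a[order(a$resno), , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- a$atom[i]
      # column-13 alignment rule: 1-letter elements start in column 14
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      out <- c(out, sprintf(
        "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, nm_fmt, a$resname[i], ch, a$resno[i],
        a$x[i], a$y[i], a$z[i], a$occupancy[i], 0, toupper(a$element[i])))
    }
    if (nrow(a)) out <- c(out, "TER")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
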