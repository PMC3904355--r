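# Minimal fixed-width reader for PDB ATOM records.  Only the fields the
# contact-map builder needs are extracted; HETATM, alternate locations and
# models are ignored.  Returns a data.frame with one row per heavy atom.
parse_pdb_atoms <- function(lines) {
  atoms <- lines[startsWith(lines, "ATOM  ")]
  if (length(atoms) == 0L) {
    stop("no ATOM records found", call. = FALSE)
  }
  fw <- function(from, to) trimws(substr(atoms, from, to))
  df <- data.frame(
    atom_name = fw(13, 16),
    chain = fw(22, 22),
    resseq = as.integer(fw(23, 26)),
    x = as.numeric(fw(31, 38)),
    y = as.numeric(fw(39, 46)),
    z = as.numeric(fw(47, 54)),
    element = fw(77, 78),
    stringsAsFactors = FALSE
  )
  # element column may be absent in minimal files; fall back to the first
  # letter of the atom name
  missing_el <- df$element == ""
  df$element[missing_el] <- substr(df$atom_name[missing_el], 1, 1)
  df[df$element != "H", , drop = FALSE]
}

#' Build a contact map from a peptide-MHC structure
#'
#' Reads PDB-format text (a file path or a character vector of lines) and
#' records, for each of the 9 peptide positions, the HLA residues with any
#' heavy-atom pair within `cutoff` angstroms.  Weights are either 1 per
#' contacted residue (`"binary"`) or the number of qualifying atom pairs
#' (`"atom_count"`); within each nonempty peptide position the weights are
#' normalised to sum to 1 so the energy scale is comparable across
#' positions.  HLA positions are taken from the residue numbers of the HLA
#' chain (1-based mature-protein numbering, the convention of class I
#' crystal structures).
#'
#' @param structure Path to a PDB file, or a character vector of PDB lines.
#' @param hla_chain,peptide_chain Chain identifiers; the peptide chain must
#'   contain exactly 9 residues.
#' @param cutoff Heavy-atom distance cutoff in angstroms (> 0, default 4.5).
#' @param weighting `"binary"` or `"atom_count"`.
#' @return A [contact_map()].
#' @export
build_contact_map <- function(structure, hla_chain = "A", peptide_chain = "C",
                              cutoff = 4.5, weighting = c("binary",
                                                          "atom_count")) {
  weighting <- match.arg(weighting)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("cutoff must be a positive distance in angstroms", call. = FALSE)
  }
  lines <- if (length(structure) == 1L && !grepl("\n", structure) &&
               file.exists(structure)) readLines(structure) else structure
  atoms <- parse_pdb_atoms(lines)

  hla <- atoms[atoms$chain == hla_chain, , drop = FALSE]
  pep <- atoms[atoms$chain == peptide_chain, , drop = FALSE]
  if (nrow(hla) == 0L) stop("chain '", hla_chain, "' not found", call. = FALSE)
  if (nrow(pep) == 0L) stop("chain '", peptide_chain, "' not found",
                            call. = FALSE)
  pep_res <- sort(unique(pep$resseq))
  if (length(pep_res) != PEPTIDE_LENGTH) {
    stop("peptide chain '", peptide_chain, "' has ", length(pep_res),
         " residues, expected ", PEPTIDE_LENGTH, call. = FALSE)
  }
  pep$pos <- match(pep$resseq, pep_res)   # residue order -> positions 1..9

  d2 <- outer(pep$x, hla$x, "-")^2 + outer(pep$y, hla$y, "-")^2 +
    outer(pep$z, hla$z, "-")^2
  within <- d2 <= cutoff^2
  rows <- list()
  for (p in seq_len(PEPTIDE_LENGTH)) {
    hit <- within[pep$pos == p, , drop = FALSE]
    pairs_per_res <- tapply(colSums(hit), hla$resseq, sum)
    pairs_per_res <- pairs_per_res[pairs_per_res > 0]
    if (length(pairs_per_res) == 0L) next
    w <- if (weighting == "binary") rep(1, length(pairs_per_res)) else
      as.numeric(pairs_per_res)
    rows[[length(rows) + 1L]] <- data.frame(
      peptide_pos = p,
      hla_pos = as.integer(names(pairs_per_res)),
      weight = w / sum(w)
    )
  }
  contact_map(if (length(rows) == 0L) {
    data.frame(peptide_pos = integer(), hla_pos = integer(),
               weight = numeric())
  } else {
    do.call(rbind, rows)
  })
}
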