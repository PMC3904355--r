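# All tables are tab-separated UTF-8 with "#"-prefixed metadata lines
# before the column header.

write_tsv_meta <- function(df, path, meta = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(meta) > 0L) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  body <- lines[!startsWith(lines, "#")]
  utils::read.delim(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE)
}

#' Write a binding profile to a PFM TSV file
#'
#' Dialect: one metadata line
#' `# pfm <label> length=9 alphabet=ACDEFGHIKLMNPQRSTVWY`, then a column
#' header and 9 data rows `position<TAB>f_A<TAB>...<TAB>f_Y` with 10
#' significant digits (so write-read round-trips within 1e-9).
#'
#' @param profile A [binding_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(profile, path) {
  stopifnot(inherits(profile, "binding_profile"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# pfm ", profile$label, " length=", profile$length,
                    " alphabet=", paste(AA_ALPHABET, collapse = "")), con)
  writeLines(paste(c("position", paste0("f_", AA_ALPHABET)),
                   collapse = "\t"), con)
  for (p in seq_len(profile$length)) {
    writeLines(paste(c(p, sprintf("%.10g", profile$freqs[p, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a binding profile from a PFM TSV file
#'
#' @param path File written by [write_pfm()] (dialect documented there).
#' @return A [binding_profile()].
#' @export
read_pfm <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L || !grepl("^# pfm ", lines[1])) {
    stop("malformed PFM header in ", path, call. = FALSE)
  }
  header <- strsplit(sub("^# pfm ", "", lines[1]), " ", fixed = TRUE)[[1]]
  label <- header[1]
  fields <- header[-1]
  len <- as.integer(sub("^length=", "", fields[grepl("^length=", fields)]))
  alph <- sub("^alphabet=", "", fields[grepl("^alphabet=", fields)])
  if (length(len) != 1L || is.na(len) || len != PEPTIDE_LENGTH) {
    stop("PFM length must be ", PEPTIDE_LENGTH, " (got '",
         paste(len, collapse = ","), "')", call. = FALSE)
  }
  if (!identical(alph, paste(AA_ALPHABET, collapse = ""))) {
    stop("PFM alphabet does not match the canonical 20-letter alphabet",
         call. = FALSE)
  }
  body <- utils::read.delim(text = paste(lines[-1], collapse = "\n"),
                            stringsAsFactors = FALSE)
  if (nrow(body) != PEPTIDE_LENGTH) {
    stop("PFM has ", nrow(body), " data rows, expected ", PEPTIDE_LENGTH,
         call. = FALSE)
  }
  freqs <- as.matrix(body[paste0("f_", AA_ALPHABET)])
  sums <- rowSums(freqs)
  bad <- which(abs(sums - 1) > 1e-6)
  if (length(bad) > 0L) {
    stop("PFM row for position ", body$position[bad[1]], " sums to ",
         format(sums[bad[1]]), ", not 1", call. = FALSE)
  }
  freqs <- freqs / sums
  freqs <- freqs[order(body$position), , drop = FALSE]
  binding_profile(freqs, label = label)
}

#' Write / read an allele pool or sequence set as FASTA
#'
#' Sequences are keyed by allele label; the cohort TSV stores labels only
#' and resolves residues through such a FASTA.
#'
#' @param sequences Named character vector of residue strings, a list of
#'   [hla_sequence()], or an [generate_allele_pool()] pool.
#' @param path File path.
#' @return `write_allele_fasta`: `path`, invisibly.  `read_allele_fasta`:
#'   named character vector of sequences.
#' @export
write_allele_fasta <- function(sequences, path) {
  if (inherits(sequences, "allele_pool")) sequences <- sequences$alleles
  if (is.list(sequences)) {
    sequences <- vapply(sequences, function(s) {
      if (inherits(s, "hla_sequence")) s$residues else as.character(s)
    }, character(1))
  }
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_allele_fasta
#' @export
read_allele_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write / read a cohort TSV
#'
#' Columns `pair_id`, `patient_allele`, `donor_allele`, `death`,
#' `severity`; sequences are resolved from an accompanying allele FASTA at
#' read time, keyed by allele label.
#'
#' @param cohort A [transplant_cohort()].
#' @param path Cohort TSV path.
#' @param fasta_path Allele FASTA path (read side).
#' @return `write_cohort_tsv`: `path`, invisibly; `read_cohort_tsv`: a
#'   [transplant_cohort()].
#' @export
write_cohort_tsv <- function(cohort, path) {
  cohort <- transplant_cohort(cohort)
  write_tsv_meta(
    cohort[c("pair_id", "patient_allele", "donor_allele", "death",
             "severity")],
    path, meta = "cohort single-locus mismatched patient-donor pairs")
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path, fasta_path) {
  tab <- read_tsv_meta(path)
  seqs <- read_allele_fasta(fasta_path)
  missing <- setdiff(unique(c(tab$patient_allele, tab$donor_allele)),
                     names(seqs))
  if (length(missing) > 0L) {
    stop("alleles missing from FASTA: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab$patient_seq <- unname(seqs[tab$patient_allele])
  tab$donor_seq <- unname(seqs[tab$donor_allele])
  transplant_cohort(tab)
}

#' Write / read a contact map TSV
#'
#' Columns `peptide_pos`, `hla_pos`, `weight`.
#'
#' @param cmap A [contact_map()].
#' @param path File path.
#' @return Writer: `path`, invisibly; reader: a [contact_map()].
#' @export
write_contact_map <- function(cmap, path) {
  cmap <- contact_map(cmap)
  write_tsv_meta(as.data.frame(cmap), path, meta = "contact_map")
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  contact_map(read_tsv_meta(path))
}

#' Write / read an interaction model TSV
#'
#' 20 x 20 energy matrix with a leading residue column and residue-letter
#' column headers.
#'
#' @param model An [interaction_model()].
#' @param path File path.
#' @return Writer: `path`, invisibly; reader: an [interaction_model()].
#' @export
write_interaction_model <- function(model, path) {
  stopifnot(inherits(model, "interaction_model"))
  df <- data.frame(residue = AA_ALPHABET, model$energy,
                   check.names = FALSE)
  write_tsv_meta(df, path, meta = "interaction_model energies in kT")
}

#' @rdname write_interaction_model
#' @export
read_interaction_model <- function(path) {
  tab <- read_tsv_meta(path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$residue
  interaction_model(m[AA_ALPHABET, AA_ALPHABET])
}

#' Write a divergence report TSV
#'
#' One row per compared profile pair: `label_a`, `label_b`, `position`,
#' `res_a`, `res_b`, the nine per-position divergences `d_pos1..d_pos9`,
#' `divergence_total` and (optionally) `corr_divergence`.
#'
#' @param rows List of lists, each with `divergence` (a
#'   `divergence_result`), optional `position`, `res_a`, `res_b` and
#'   `corr_divergence`.
#' @param path File path.
#' @return `path` invisibly (writer); `data.frame` (reader).
#' @export
write_divergence_report <- function(rows, path) {
  df <- do.call(rbind, lapply(rows, function(r) {
    d <- r$divergence
    out <- data.frame(label_a = d$label_a, label_b = d$label_b,
                      position = if (is.null(r$position)) NA_integer_ else
                        r$position,
                      res_a = if (is.null(r$res_a)) NA_character_ else
                        r$res_a,
                      res_b = if (is.null(r$res_b)) NA_character_ else
                        r$res_b,
                      stringsAsFactors = FALSE)
    pp <- as.data.frame(rbind(d$per_position))
    names(pp) <- paste0("d_pos", seq_len(PEPTIDE_LENGTH))
    out <- cbind(out, pp)
    out$divergence_total <- d$total
    out$corr_divergence <- if (is.null(r$corr_divergence)) NA_real_ else
      r$corr_divergence
    out
  }))
  write_tsv_meta(df, path, meta = "divergence report")
}

#' @rdname write_divergence_report
#' @export
read_divergence_report <- function(path) {
  read_tsv_meta(path)
}

#' Write / read a risk table TSV
#'
#' Column layout matches [run_risk_pipeline()] output.
#'
#' @param risk_table A `risk_table` data.frame.
#' @param path File path.
#' @return Writer: `path`, invisibly; reader: `data.frame`.
#' @export
write_risk_table <- function(risk_table, path) {
  write_tsv_meta(as.data.frame(risk_table), path,
                 meta = "risk table per unoriented residue mismatch")
}

#' @rdname write_risk_table
#' @export
read_risk_table <- function(path) {
  read_tsv_meta(path)
}

#' Write / read a ground-truth TSV
#'
#' Columns `position`, `res_a`, `res_b`, `delta`.
#'
#' @param truth A [assign_ground_truth()] object.
#' @param path File path.
#' @return Writer: `path`, invisibly; reader: a `ground_truth` object.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  write_tsv_meta(truth$delta, path,
                 meta = "ground truth per-mismatch divergence")
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  structure(list(delta = read_tsv_meta(path)), class = "ground_truth")
}
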