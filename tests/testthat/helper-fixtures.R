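# Fixtures built in code; no data files.

aa_chars_test <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

allele_pair_key_test <- function(a, b) paste(pmin(a, b), pmax(a, b))

# independent TSV reader for checking written artifacts
read_tsv_meta_test <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

uniform_profile <- function(label = "uniform") {
  binding_profile(matrix(1 / 20, 9, 20), label = label)
}

# profile with all mass on one residue at every position
point_profile <- function(residue = "A", label = residue) {
  m <- matrix(0, 9, 20)
  m[, match(residue, AA_ALPHABET)] <- 1
  binding_profile(m, label = label)
}

# The worked 10-pair cohort: mismatch X = (5, A/C) carried by 4 pairs
# (orientation A->C: 2 pairs, 1 death; orientation C->A: 2 pairs, 2
# deaths); the other 6 pairs carry only (8, K/R) with 2 deaths.
hand_cohort <- function() {
  base <- paste(rep("G", 10), collapse = "")
  with_at <- function(pos, res) {
    s <- base
    substr(s, pos, pos) <- res
    s
  }
  seq_a5 <- with_at(5, "A"); seq_c5 <- with_at(5, "C")
  seq_k8 <- with_at(8, "K"); seq_r8 <- with_at(8, "R")
  transplant_cohort(data.frame(
    pair_id = sprintf("H%02d", 1:10),
    patient_allele = c(rep("AL*A", 2), rep("AL*C", 2), rep("AL*K", 6)),
    donor_allele = c(rep("AL*C2", 2), rep("AL*A2", 2), rep("AL*R", 6)),
    patient_seq = c(seq_a5, seq_a5, seq_c5, seq_c5, rep(seq_k8, 6)),
    donor_seq = c(seq_c5, seq_c5, seq_a5, seq_a5, rep(seq_r8, 6)),
    death = c(1, 0, 1, 1, 1, 1, 0, 0, 0, 0),
    severity = c(rep("low", 4), rep("intermediate", 3), rep("high", 3)),
    stringsAsFactors = FALSE
  ))
}

# random small cohort for property tests: alleles drawn from a tiny pool
random_small_cohort <- function(seed, max_pairs = 30L) {
  withr::with_seed(seed, {
    pool <- generate_allele_pool(n_alleles = 4L, seq_length = 12L,
                                 n_polymorphic = 4L, residues_per_site = 2L,
                                 seed = sample.int(1e6, 1))
    seqs <- vapply(pool$alleles, `[[`, character(1), "residues")
    labels <- names(seqs)
    n <- sample.int(max_pairs - 4L, 1) + 4L
    rows <- list()
    tries <- 0
    while (length(rows) < n && tries < 500) {
      tries <- tries + 1
      ab <- sample(labels, 2)
      if (seqs[ab[1]] == seqs[ab[2]]) next
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = sprintf("R%03d", length(rows) + 1L),
        patient_allele = ab[1], donor_allele = ab[2],
        patient_seq = unname(seqs[ab[1]]), donor_seq = unname(seqs[ab[2]]),
        death = stats::rbinom(1, 1, 0.4),
        severity = sample(c("low", "intermediate", "high"), 1),
        stringsAsFactors = FALSE)
    }
    transplant_cohort(do.call(rbind, rows))
  })
}
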