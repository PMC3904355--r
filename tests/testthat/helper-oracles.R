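# Independent oracles.  These deliberately reimplement quantities with
# plain loops and textbook formulas, sharing no code with the package paths
# they check.

# Jensen-Shannon divergence as the average KL divergence to the mixture.
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) {
      if (a[i] > 0) s <- s + a[i] * (log(a[i]) - log(b[i])) / log(2)
    }
    s
  }
  (kl(p, m) + kl(q, m)) / 2
}

# Exact stationary per-position residue distribution of the contact-map
# Metropolis chain, from first principles (loops, no shared helpers).
oracle_boltzmann <- function(hla_residues, cmap_df, energy, temperature = 1) {
  out <- matrix(0, 9, 20)
  for (p in 1:9) {
    e <- numeric(20)
    rows <- cmap_df[cmap_df$peptide_pos == p, , drop = FALSE]
    for (a in 1:20) {
      for (r in seq_len(nrow(rows))) {
        hres <- substr(hla_residues, rows$hla_pos[r], rows$hla_pos[r])
        e[a] <- e[a] + rows$weight[r] *
          energy[AA_ALPHABET[a], hres]
      }
    }
    w <- exp(-e / temperature)
    out[p, ] <- w / sum(w)
  }
  colnames(out) <- AA_ALPHABET
  out
}

# Brute-force risk pipeline on a small cohort (raw rate mode): loops over
# pairs and positions, no tallying machinery.
oracle_risk_table <- function(cohort, threshold) {
  n <- nrow(cohort)
  recs <- list()
  for (i in seq_len(n)) {
    p <- strsplit(cohort$patient_seq[i], "")[[1]]
    d <- strsplit(cohort$donor_seq[i], "")[[1]]
    for (pos in which(p != d)) {
      lo <- min(p[pos], d[pos]); hi <- max(p[pos], d[pos])
      key <- paste(pos, lo, hi)
      orient <- if (p[pos] == lo) 1L else 2L
      recs[[length(recs) + 1L]] <- data.frame(
        key = key, pos = pos, lo = lo, hi = hi, orient = orient,
        pair = cohort$pair_id[i], death = cohort$death[i])
    }
  }
  recs <- do.call(rbind, recs)
  rows <- list()
  for (key in sort(unique(recs$key))) {
    sub <- recs[recs$key == key, ]
    n1 <- sum(sub$orient == 1L); n2 <- sum(sub$orient == 2L)
    if (n1 < threshold || n2 < threshold) next
    r1 <- if (n1 > 0) sum(sub$death[sub$orient == 1L]) / n1 else NA_real_
    r2 <- if (n2 > 0) sum(sub$death[sub$orient == 2L]) / n2 else NA_real_
    sym <- max(c(r1, r2), na.rm = TRUE)
    outside <- !cohort$pair_id %in% sub$pair
    comp <- if (any(outside)) mean(cohort$death[outside]) else NA_real_
    rr <- if (is.na(comp) || comp == 0) NA_real_ else sym / comp
    rows[[length(rows) + 1L]] <- data.frame(
      position = sub$pos[1], res_a = sub$lo[1], res_b = sub$hi[1],
      count_or1 = n1, count_or2 = n2, rate_or1 = r1, rate_or2 = r2,
      rate_symmetrized = sym, rate_complement = comp, relative_risk = rr,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(position = integer(), res_a = character(),
                      res_b = character(), count_or1 = integer(),
                      count_or2 = integer(), rate_or1 = numeric(),
                      rate_or2 = numeric(), rate_symmetrized = numeric(),
                      rate_complement = numeric(),
                      relative_risk = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$position, out$res_a, out$res_b), , drop = FALSE]
}

# Exact expectation of the capped-subsampling rate for one orientation:
# each group contributes min(cap, n) draws whose expected death count is
# hypergeometric, drawn * deaths / n.
oracle_subsample_expectation <- function(groups, cap) {
  drawn <- pmin(cap, groups$n)
  sum(drawn * groups$deaths / groups$n) / sum(drawn)
}
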