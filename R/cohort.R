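SEVERITY_LEVELS <- c("low", "intermediate", "high")

#' Construct and validate a transplant cohort
#'
#' One row per patient-donor pair mismatched at a single HLA-C allele (and
#' matched at the other classical loci, the "9/10" setting).  The aligned
#' protein sequences of the two mismatched alleles, a binary death outcome
#' and a three-level disease-severity class are all that downstream risk
#' estimation needs.
#'
#' @param pairs `data.frame` with columns `pair_id`, `patient_allele`,
#'   `donor_allele`, `patient_seq`, `donor_seq`, `death` (0/1) and
#'   `severity` (`"low"`, `"intermediate"` or `"high"`).
#' @return Validated `data.frame` of class `transplant_cohort`.
#' @export
transplant_cohort <- function(pairs) {
  pairs <- as.data.frame(pairs)
  need <- c("pair_id", "patient_allele", "donor_allele",
            "patient_seq", "donor_seq", "death", "severity")
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0L) {
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pairs <- pairs[need]
  if (anyDuplicated(pairs$pair_id)) {
    stop("duplicated pair_id values", call. = FALSE)
  }
  if (!all(pairs$death %in% c(0, 1))) {
    stop("death must be 0 or 1", call. = FALSE)
  }
  pairs$death <- as.integer(pairs$death)
  bad_sev <- !pairs$severity %in% SEVERITY_LEVELS
  if (any(bad_sev)) {
    stop("unknown severity label '", pairs$severity[which(bad_sev)[1]],
         "' (pair ", pairs$pair_id[which(bad_sev)[1]], ")", call. = FALSE)
  }
  if (any(nchar(pairs$patient_seq) != nchar(pairs$donor_seq))) {
    stop("patient and donor sequences must be aligned to equal length",
         call. = FALSE)
  }
  same <- nrow(pairs) > 0 & pairs$patient_seq == pairs$donor_seq
  if (any(same)) {
    stop("pair ", pairs$pair_id[which(same)[1]],
         " has identical sequences: not a mismatched pair", call. = FALSE)
  }
  rownames(pairs) <- NULL
  class(pairs) <- c("transplant_cohort", "data.frame")
  pairs
}

#' Residue-level mismatches between two aligned sequences
#'
#' Reduces an aligned patient/donor sequence pair to its set of oriented
#' residue mismatches, ordered by position.  Orientation (who carries which
#' residue) is preserved because oriented mortality rates can be strikingly
#' asymmetric.
#'
#' @param patient_seq,donor_seq Aligned residue strings of equal length.
#' @return `data.frame` with columns `position` (1-based), `patient_res`,
#'   `donor_res`; zero rows when the sequences are identical.
#' @export
extract_mismatches <- function(patient_seq, donor_seq) {
  if (nchar(patient_seq) != nchar(donor_seq)) {
    stop("sequences have different lengths", call. = FALSE)
  }
  p <- aa_chars(patient_seq)
  d <- aa_chars(donor_seq)
  idx <- which(p != d)
  data.frame(position = idx, patient_res = p[idx], donor_res = d[idx],
             stringsAsFactors = FALSE)
}

# canonical key of an unoriented mismatch: position + residues sorted
mismatch_key <- function(position, res_a, res_b) {
  lo <- pmin(res_a, res_b)
  hi <- pmax(res_a, res_b)
  paste0(position, ":", lo, "/", hi)
}

# unordered allele-pair key, e.g. "SYN*001|SYN*003"
allele_pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Tally residue mismatches over a cohort
#'
#' Every pair contributes to the tally of every mismatch it carries.  For
#' each unoriented mismatch (position + residue pair), counts and deaths
#' are kept separately per orientation (orientation 1: the patient carries
#' the alphabetically smaller residue) and per unordered allele-level pair
#' — the grouping needed by the subsampling debiasing, since a handful of
#' common allele pairs can dominate a mismatch's carriers.
#'
#' @param cohort A [transplant_cohort()].
#' @return Named list of class `mismatch_tallies`, one `mismatch_tally`
#'   per unoriented mismatch key.  Each tally holds `position`, `res_a`,
#'   `res_b` (sorted), `orientations` (counts/deaths per orientation),
#'   `groups` (counts/deaths per orientation x allele pair), `pair_ids`
#'   (per orientation) and `carrier_ids`.
#' @export
tally_mismatches <- function(cohort) {
  cohort <- transplant_cohort(cohort)
  # mismatch sets depend only on the sequence pair; memoise per unique pair
  seq_key <- paste(cohort$patient_seq, cohort$donor_seq, sep = "\r")
  uniq <- !duplicated(seq_key)
  mm_by_key <- lapply(which(uniq), function(i) {
    extract_mismatches(cohort$patient_seq[i], cohort$donor_seq[i])
  })
  names(mm_by_key) <- seq_key[uniq]

  if (nrow(cohort) == 0L) {
    return(structure(list(), class = "mismatch_tallies", n_pairs = 0L))
  }
  per_pair <- mm_by_key[seq_key]
  n_mm <- vapply(per_pair, nrow, integer(1))
  long <- do.call(rbind, per_pair)
  rep_idx <- rep(seq_len(nrow(cohort)), n_mm)
  long$pair_id <- cohort$pair_id[rep_idx]
  long$death <- cohort$death[rep_idx]
  long$allele_pair <- allele_pair_key(cohort$patient_allele,
                                      cohort$donor_allele)[rep_idx]
  long$res_a <- pmin(long$patient_res, long$donor_res)
  long$res_b <- pmax(long$patient_res, long$donor_res)
  long$orientation <- ifelse(long$patient_res == long$res_a, 1L, 2L)
  long$key <- mismatch_key(long$position, long$patient_res, long$donor_res)
  rownames(long) <- NULL

  tallies <- lapply(split(long, long$key), function(d) {
    orientations <- do.call(rbind, lapply(1:2, function(o) {
      sub <- d[d$orientation == o, , drop = FALSE]
      data.frame(orientation = o, n = nrow(sub), deaths = sum(sub$death))
    }))
    groups <- stats::aggregate(
      cbind(n = rep(1L, nrow(d)), deaths = d$death),
      by = list(orientation = d$orientation, allele_pair = d$allele_pair),
      FUN = sum
    )
    structure(
      list(position = d$position[1], res_a = d$res_a[1], res_b = d$res_b[1],
           orientations = orientations,
           groups = groups[order(groups$orientation, groups$allele_pair), ],
           pair_ids = split(d$pair_id, factor(d$orientation, levels = 1:2)),
           carrier_ids = unique(d$pair_id)),
      class = "mismatch_tally"
    )
  })
  # order tallies by position then residues for stable downstream iteration
  ord <- order(vapply(tallies, `[[`, numeric(1), "position"),
               vapply(tallies, `[[`, character(1), "res_a"),
               vapply(tallies, `[[`, character(1), "res_b"))
  structure(tallies[ord], class = "mismatch_tallies",
            n_pairs = nrow(cohort))
}

#' Symmetrized mortality rate of a mismatch tally
#'
#' The maximum of the two oriented mortality rates (`deaths / count`, over
#' orientations actually observed).  Taking the maximum symmetrizes the
#' clinical rate to match the inherently symmetric structural divergence
#' while retaining the riskier orientation's signal.
#'
#' @param tally A `mismatch_tally` from [tally_mismatches()].
#' @return Rate in \[0, 1\]; `NA` when neither orientation has carriers.
#' @export
symmetrized_rate <- function(tally) {
  stopifnot(inherits(tally, "mismatch_tally"))
  o <- tally$orientations
  o <- o[o$n > 0, , drop = FALSE]
  if (nrow(o) == 0L) return(NA_real_)
  max(o$deaths / o$n)
}

#' Subsampling-adjusted mortality rate of a mismatch tally
#'
#' Skewed allele-pair frequencies can let a single common allele-level
#' mismatch dominate a residue mismatch's mortality rate.  To debias, each
#' replicate draws at most `cap` pairs without replacement from every
#' allele-pair group of an orientation, recomputes the mortality rate over
#' the drawn pairs, and the replicate rates are averaged; the two adjusted
#' oriented rates are then symmetrized by their maximum.  Only the number
#' of deaths among the drawn pairs matters, so each group's draw is taken
#' from the corresponding hypergeometric distribution.
#'
#' @param tally A `mismatch_tally`.
#' @param cap Maximum pairs any allele-pair group may contribute (>= 1).
#' @param reps Number of subsampling replicates (>= 1).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return List with `rate` (symmetrized adjusted rate, `NA` if the tally
#'   is empty) and `oriented` (the two adjusted oriented rates, `NA` where
#'   an orientation has no carriers).
#' @export
subsampled_rate <- function(tally, cap = 10L, reps = 1000L, seed = 1L) {
  stopifnot(inherits(tally, "mismatch_tally"), cap >= 1, reps >= 1)
  oriented <- withr::with_seed(seed, {
    vapply(1:2, function(o) {
      g <- tally$groups[tally$groups$orientation == o, , drop = FALSE]
      if (nrow(g) == 0L) return(NA_real_)
      drawn_n <- pmin(cap, g$n)
      # deaths drawn per replicate: reps x groups matrix of hypergeometrics
      deaths <- vapply(seq_len(nrow(g)), function(i) {
        stats::rhyper(reps, m = g$deaths[i], n = g$n[i] - g$deaths[i],
                      k = drawn_n[i])
      }, numeric(reps))
      deaths <- matrix(deaths, nrow = reps)
      mean(rowSums(deaths) / sum(drawn_n))
    }, numeric(1))
  })
  rate <- if (all(is.na(oriented))) NA_real_ else max(oriented, na.rm = TRUE)
  list(rate = rate, oriented = oriented)
}

#' Risk-pipeline configuration
#'
#' @param high_counts_threshold Minimum carrier count required in *each*
#'   orientation for a mismatch to enter the analysis (default 100); rates
#'   over smaller sets are too noisy to interpret.
#' @param subsample_cap Maximum pairs per allele-pair group in the
#'   subsampling adjustment (default 10).
#' @param subsample_reps Subsampling replicates averaged per rate
#'   (default 1000).
#' @param seed Seed for the subsampling randomness.
#' @param exclude_severities Severity levels to drop before tallying
#'   (subset of `low`, `intermediate`, `high`; default none).
#' @return Object of class `risk_config`.
#' @export
risk_config <- function(high_counts_threshold = 100L, subsample_cap = 10L,
                        subsample_reps = 1000L, seed = 1L,
                        exclude_severities = character()) {
  stopifnot(high_counts_threshold >= 1, subsample_cap >= 1,
            subsample_reps >= 1,
            all(exclude_severities %in% SEVERITY_LEVELS))
  structure(
    list(high_counts_threshold = as.integer(high_counts_threshold),
         subsample_cap = as.integer(subsample_cap),
         subsample_reps = as.integer(subsample_reps),
         seed = as.integer(seed),
         exclude_severities = exclude_severities),
    class = "risk_config"
  )
}

#' Filter tallies to high-counts mismatches
#'
#' Keeps the mismatches with at least `threshold` carriers in each of the
#' two orientations; mismatches seen mostly in one direction or in few
#' pairs carry too much sampling noise.
#'
#' @param tallies A `mismatch_tallies` list.
#' @param threshold Minimum per-orientation count (>= 1).
#' @return The filtered `mismatch_tallies`.
#' @export
high_counts_filter <- function(tallies, threshold = 100L) {
  stopifnot(inherits(tallies, "mismatch_tallies"), threshold >= 1)
  keep <- vapply(tallies, function(t) all(t$orientations$n >= threshold),
                 logical(1))
  structure(tallies[keep], class = "mismatch_tallies",
            n_pairs = attr(tallies, "n_pairs"))
}

#' Drop severity classes from a cohort
#'
#' Removing, e.g., the high-severity class (disease in relapse, blast
#' crisis) before recomputing risk factors strips a strong non-genetic
#' mortality driver and sharpens the mismatch-level signal.
#'
#' @param cohort A [transplant_cohort()].
#' @param exclude Severity levels to drop.
#' @return The filtered cohort (possibly empty).
#' @export
stratify_by_severity <- function(cohort, exclude = character()) {
  cohort <- transplant_cohort(cohort)
  stopifnot(all(exclude %in% SEVERITY_LEVELS))
  out <- cohort[!cohort$severity %in% exclude, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("transplant_cohort", "data.frame")
  out
}

# shared core: risk record for one tally against a cohort
risk_record_for_tally <- function(tally, cohort, config, rate_mode,
                                  subsample_seed) {
  o <- tally$orientations
  rate_or <- ifelse(o$n > 0, o$deaths / o$n, NA_real_)
  rate_sym <- symmetrized_rate(tally)
  adj <- subsampled_rate(tally, cap = config$subsample_cap,
                         reps = config$subsample_reps, seed = subsample_seed)
  complement <- !cohort$pair_id %in% tally$carrier_ids
  rate_comp <- if (any(complement)) mean(cohort$death[complement]) else
    NA_real_
  numerator <- if (rate_mode == "adjusted") adj$rate else rate_sym
  rr <- if (is.na(rate_comp) || rate_comp == 0 || is.na(numerator))
    NA_real_ else numerator / rate_comp
  data.frame(
    position = tally$position, res_a = tally$res_a, res_b = tally$res_b,
    count_or1 = o$n[1], count_or2 = o$n[2],
    rate_or1 = rate_or[1], rate_or2 = rate_or[2],
    rate_symmetrized = rate_sym, rate_adjusted = adj$rate,
    rate_complement = rate_comp, relative_risk = rr,
    stringsAsFactors = FALSE
  )
}

#' Relative mortality risk of one residue mismatch
#'
#' Numerator: the mismatch's symmetrized mortality rate (raw or
#' subsampling-adjusted).  Denominator: the mortality rate over all cohort
#' pairs not carrying the unoriented mismatch in either orientation — every
#' pair in the cohort is HLA-C-mismatched somewhere, so the complement is
#' "mismatched, but elsewhere".  Undefined ratios (empty complement or
#' zero complement mortality) are returned as `NA`, never coerced.
#'
#' @param mismatch List or one-row data.frame with `position`, `res_a`,
#'   `res_b` (residue order irrelevant).
#' @param cohort A [transplant_cohort()].
#' @param config A [risk_config()].
#' @param rate_mode `"raw"` (symmetrized oriented rates) or `"adjusted"`
#'   (subsampling-debiased rates).
#' @return One-row `data.frame` (a risk record) with oriented counts and
#'   rates, symmetrized/adjusted/complement rates and `relative_risk`.
#' @export
relative_risk <- function(mismatch, cohort, config = risk_config(),
                          rate_mode = c("raw", "adjusted")) {
  rate_mode <- match.arg(rate_mode)
  cohort <- transplant_cohort(cohort)
  key <- mismatch_key(mismatch$position, mismatch$res_a, mismatch$res_b)
  tallies <- tally_mismatches(cohort)
  if (!key %in% names(tallies)) {
    stop("mismatch ", key, " not present in cohort", call. = FALSE)
  }
  risk_record_for_tally(tallies[[key]], cohort, config, rate_mode,
                        derive_seed(config$seed, "subsample_single"))
}

#' Run the full mismatch-level risk pipeline
#'
#' Severity stratification (if configured), mismatch tallying, high-counts
#' filtering, raw and subsampling-adjusted symmetrized rates, and relative
#' risks against the complement of each mismatch's carriers.  Subsampling
#' seeds are derived per mismatch key from `config$seed`, so the output is
#' deterministic and independent of row order.
#'
#' @param cohort A [transplant_cohort()].
#' @param config A [risk_config()].
#' @param rate_mode Which numerator feeds `relative_risk`: `"adjusted"`
#'   (default) or `"raw"`.
#' @return `data.frame` of class `risk_table`, one row per high-counts
#'   mismatch with columns `position`, `res_a`, `res_b`, `count_or1`,
#'   `count_or2`, `rate_or1`, `rate_or2`, `rate_symmetrized`,
#'   `rate_adjusted`, `rate_complement`, `relative_risk`, `high_counts`.
#' @export
run_risk_pipeline <- function(cohort, config = risk_config(),
                              rate_mode = c("adjusted", "raw")) {
  rate_mode <- match.arg(rate_mode)
  cohort <- transplant_cohort(cohort)
  if (length(config$exclude_severities) > 0L) {
    cohort <- stratify_by_severity(cohort, config$exclude_severities)
  }
  tallies <- tally_mismatches(cohort)   # empty cohort -> empty risk table
  kept <- high_counts_filter(tallies, config$high_counts_threshold)
  rows <- lapply(names(kept), function(key) {
    risk_record_for_tally(kept[[key]], cohort, config, rate_mode,
                          derive_seed(config$seed, key))
  })
  out <- if (length(rows) == 0L) {
    data.frame(position = integer(), res_a = character(),
               res_b = character(), count_or1 = integer(),
               count_or2 = integer(), rate_or1 = numeric(),
               rate_or2 = numeric(), rate_symmetrized = numeric(),
               rate_adjusted = numeric(), rate_complement = numeric(),
               relative_risk = numeric(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  out$high_counts <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("risk_table", "data.frame")
  out
}
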