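test_that("extract_mismatches finds oriented differences", {
  expect_equal(nrow(extract_mismatches("AAAA", "AAAA")), 0)
  expect_error(extract_mismatches("AAA", "AAAA"), "length")

  # single mismatch at position 99 (F patient, Y donor)
  p <- paste(c(rep("A", 98), "F", rep("A", 10)), collapse = "")
  d <- paste(c(rep("A", 98), "Y", rep("A", 10)), collapse = "")
  mm <- extract_mismatches(p, d)
  expect_equal(mm$position, 99)
  expect_equal(mm$patient_res, "F")
  expect_equal(mm$donor_res, "Y")

  # co-occurring mismatches at 77 (N/S) and 80 (K/N)
  p <- paste(c(rep("A", 76), "N", "A", "A", "K", rep("A", 5)), collapse = "")
  d <- paste(c(rep("A", 76), "S", "A", "A", "N", rep("A", 5)), collapse = "")
  mm <- extract_mismatches(p, d)
  expect_equal(mm$position, c(77, 80))
  expect_equal(mm$patient_res, c("N", "K"))
  expect_equal(mm$donor_res, c("S", "N"))
})

test_that("transplant_cohort validates its inputs", {
  coh <- hand_cohort()
  expect_s3_class(coh, "transplant_cohort")
  bad <- as.data.frame(coh)
  bad$severity[1] <- "severe"
  expect_error(transplant_cohort(bad), "unknown severity label 'severe'")
  bad <- as.data.frame(coh)
  bad$donor_seq[1] <- bad$patient_seq[1]
  expect_error(transplant_cohort(bad), "identical sequences")
  bad <- as.data.frame(coh)
  bad$pair_id[2] <- bad$pair_id[1]
  expect_error(transplant_cohort(bad), "duplicated")
})

test_that("tally_mismatches matches a brute-force enumeration", {
  coh <- hand_cohort()
  tal <- tally_mismatches(coh)
  expect_named(tal, c("5:A/C", "8:K/R"))
  x <- tal[["5:A/C"]]
  expect_equal(x$orientations$n, c(2, 2))
  expect_equal(x$orientations$deaths, c(1, 2))
  expect_equal(sort(x$carrier_ids), sprintf("H%02d", 1:4))

  # orientation bookkeeping: 3 pairs all one way
  base <- "AAAAAAAAAA"
  t73 <- base; substr(t73, 3, 3) <- "T"
  coh3 <- transplant_cohort(data.frame(
    pair_id = c("a", "b", "c"),
    patient_allele = "X", donor_allele = "Y",
    patient_seq = base, donor_seq = t73,
    death = c(0, 1, 0), severity = "low", stringsAsFactors = FALSE))
  one <- tally_mismatches(coh3)[["3:A/T"]]
  expect_equal(one$orientations$n, c(3, 0))

  # pair with 2 mismatches appears in 2 tallies; conservation
  withr::with_seed(8, {
    for (s in sample.int(1e6, 5)) {
      coh <- random_small_cohort(s)
      tal <- tally_mismatches(coh)
      total_entries <- sum(vapply(tal, function(t) sum(t$orientations$n),
                                  numeric(1)))
      per_pair <- vapply(seq_len(nrow(coh)), function(i) {
        nrow(extract_mismatches(coh$patient_seq[i], coh$donor_seq[i]))
      }, integer(1))
      expect_equal(total_entries, sum(per_pair))
    }
  })
})

test_that("symmetrized_rate takes the max over observed orientations", {
  coh <- hand_cohort()
  tal <- tally_mismatches(coh)
  expect_equal(symmetrized_rate(tal[["5:A/C"]]), 1.0)   # max(0.5, 1.0)
  # single observed orientation
  one <- tally_mismatches(transplant_cohort(data.frame(
    pair_id = c("a", "b", "c"),
    patient_allele = "X", donor_allele = "Y",
    patient_seq = "AAA", donor_seq = "AAT",
    death = c(1, 0, 0), severity = "low")))[["3:A/T"]]
  expect_equal(symmetrized_rate(one), 1 / 3)
})

test_that("subsampled_rate honors the cap and matches expectations", {
  coh <- hand_cohort()
  tal <- tally_mismatches(coh)
  # all groups below the cap: identity with the raw rate for any seed
  for (s in c(1, 99, 12345)) {
    adj <- subsampled_rate(tal[["5:A/C"]], cap = 10, reps = 50, seed = s)
    expect_equal(adj$oriented, c(0.5, 1.0))
    expect_equal(adj$rate, 1.0)
  }

  # two-group scenario: group of 4 with 2 deaths + group of 20 with 0
  # deaths, cap 10 -> every replicate draws 4 + 10 = 14 pairs and the
  # expected rate is 2/14
  base <- "AAAAAAAAAA"; alt <- base; substr(alt, 2, 2) <- "C"
  mk <- function(n, deaths, pa, da) data.frame(
    pair_id = paste0(pa, da, seq_len(n)),
    patient_allele = pa, donor_allele = da,
    patient_seq = base, donor_seq = alt,
    death = rep(c(1, 0), c(deaths, n - deaths)), severity = "low")
  coh2 <- transplant_cohort(rbind(mk(4, 2, "G1", "G1b"),
                                  mk(20, 0, "G2", "G2b")))
  tal2 <- tally_mismatches(coh2)[["2:A/C"]]
  expect_equal(oracle_subsample_expectation(
    data.frame(n = c(4, 20), deaths = c(2, 0)), cap = 10), 2 / 14)
  adj <- subsampled_rate(tal2, cap = 10, reps = 2000, seed = 31)
  # MC standard error of the averaged replicate rates
  se <- sqrt(2000)^-1 * stats::sd(replicate(200, {
    (stats::rhyper(1, 2, 2, 4) + stats::rhyper(1, 0, 20, 10)) / 14
  }))
  expect_lt(abs(adj$oriented[1] - 2 / 14), 3 * max(se, 0.002))
})

test_that("replicate noise shrinks as 1/sqrt(reps)", {
  base <- "AAAAAAAAAA"; alt <- base; substr(alt, 2, 2) <- "C"
  coh <- transplant_cohort(data.frame(
    pair_id = sprintf("x%02d", 1:30),
    patient_allele = "A1", donor_allele = "A2",
    patient_seq = base, donor_seq = alt,
    death = rep(c(1, 0, 0), 10), severity = "low"))
  tal <- tally_mismatches(coh)[["2:A/C"]]
  sds <- vapply(c(100, 400, 1600), function(reps) {
    stats::sd(vapply(1:40, function(s) {
      subsampled_rate(tal, cap = 5, reps = reps, seed = s)$rate
    }, numeric(1)))
  }, numeric(1))
  # each quadrupling of reps should roughly halve the sd
  expect_lt(sds[2] / sds[1], 0.75)
  expect_lt(sds[3] / sds[2], 0.75)
})

test_that("relative_risk reproduces the hand example", {
  coh <- hand_cohort()
  rec <- relative_risk(list(position = 5, res_a = "A", res_b = "C"), coh,
                       rate_mode = "raw")
  expect_equal(rec$rate_symmetrized, 1.0)
  expect_equal(rec$rate_complement, 1 / 3)
  expect_equal(rec$relative_risk, 3.0)

  # mismatch carried by every pair: complement empty -> undefined
  base <- "AAAA"; alt <- "CAAA"
  all_coh <- transplant_cohort(data.frame(
    pair_id = c("a", "b", "c"), patient_allele = "X", donor_allele = "Y",
    patient_seq = base, donor_seq = alt, death = c(1, 0, 1),
    severity = "low"))
  rec <- relative_risk(list(position = 1, res_a = "A", res_b = "C"),
                       all_coh, rate_mode = "raw")
  expect_true(is.na(rec$relative_risk))
  expect_true(is.na(rec$rate_complement))

  expect_error(relative_risk(list(position = 9, res_a = "A", res_b = "C"),
                             coh), "not present")
})

test_that("high_counts_filter keeps both-orientation counts", {
  coh <- hand_cohort()
  tal <- tally_mismatches(coh)
  expect_named(high_counts_filter(tal, 2), c("5:A/C"))  # 8:K/R is 6/0
  expect_named(high_counts_filter(tal, 3), character(0))
  # threshold 1 keeps every mismatch observed in both orientations
  expect_named(high_counts_filter(tal, 1), "5:A/C")
})

test_that("stratify_by_severity filters and composes with the pipeline", {
  coh <- hand_cohort()   # 3 high-severity pairs of 10
  expect_equal(nrow(stratify_by_severity(coh, "high")), 7)
  expect_identical(stratify_by_severity(coh, character()), coh)
  empty <- stratify_by_severity(coh, c("low", "intermediate", "high"))
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(run_risk_pipeline(empty, risk_config(
    high_counts_threshold = 1))), 0)
  expect_error(stratify_by_severity(coh, "terrible"))
})

test_that("run_risk_pipeline equals the brute-force oracle", {
  cfg <- risk_config(high_counts_threshold = 1, seed = 5)
  seeds <- withr::with_seed(17, sample.int(1e6, 25))
  for (s in seeds) {
    coh <- random_small_cohort(s)
    got <- run_risk_pipeline(coh, cfg, rate_mode = "raw")
    want <- oracle_risk_table(coh, threshold = 1)
    expect_equal(nrow(got), nrow(want))
    expect_equal(as.integer(got$position), as.integer(want$position))
    expect_equal(got$res_a, want$res_a)
    expect_equal(as.integer(got$count_or1), as.integer(want$count_or1))
    expect_equal(as.integer(got$count_or2), as.integer(want$count_or2))
    expect_equal(got$rate_symmetrized, want$rate_symmetrized)
    expect_equal(got$rate_complement, want$rate_complement)
    expect_equal(got$relative_risk, want$relative_risk)
  }
  # determinism
  coh <- random_small_cohort(99)
  expect_identical(run_risk_pipeline(coh, cfg),
                   run_risk_pipeline(coh, cfg))
})

test_that("subsampling debiases a dominant allele pair", {
  # one allele pair duplicated 200x with atypical (all-survive) outcomes
  # dominates the raw rate; the adjusted rate moves toward the rate after
  # capping that group
  base <- "AAAAAAAAAA"; alt <- base; substr(alt, 4, 4) <- "S"
  mk <- function(n, deaths, pa, da, tag) data.frame(
    pair_id = paste0(tag, seq_len(n)), patient_allele = pa,
    donor_allele = da, patient_seq = base, donor_seq = alt,
    death = rep(c(1, 0), c(deaths, n - deaths)), severity = "low")
  coh <- transplant_cohort(rbind(
    mk(200, 0, "C*dup", "C*dup2", "d"),     # dominant, 0% mortality
    mk(20, 12, "C*a", "C*b", "a"),          # typical carriers, 60%
    mk(20, 12, "C*c", "C*d", "c")))
  tal <- tally_mismatches(coh)[["4:A/S"]]
  raw <- symmetrized_rate(tal)
  adj <- subsampled_rate(tal, cap = 10, reps = 2000, seed = 7)$rate
  dedup_rate <- oracle_subsample_expectation(
    data.frame(n = c(200, 20, 20), deaths = c(0, 12, 12)), cap = 10)
  expect_equal(raw, 24 / 240)
  expect_lt(abs(adj - dedup_rate), 0.02)
  expect_gt(adj, raw)   # moved toward the capped estimate
})
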