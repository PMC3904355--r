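toy_hla <- function(n = 20, fill = "A") {
  hla_sequence(paste(rep(fill, n), collapse = ""), "toy")
}

test_that("default interaction model encodes hydropathy and charge", {
  m <- default_interaction_model()$energy
  expect_identical(m, t(m))                      # symmetric, all 400 entries
  expect_lt(m["I", "I"], 0)                      # hydrophobic attraction
  # charge terms: like charges penalised, opposite rewarded
  h <- KD_HYDROPATHY / 4.5
  expect_equal(m["K", "K"], -h["K"]^2 + 1, ignore_attr = TRUE)
  expect_equal(m["K", "D"], -h["K"] * h["D"] - 1, ignore_attr = TRUE)
  expect_equal(m["K", "K"] - (-h["K"] * h["K"]), 1, ignore_attr = TRUE)
  # weights scale the two terms independently
  m2 <- default_interaction_model(w_h = 0, w_q = 2)$energy
  expect_equal(m2["K", "D"], -2, ignore_attr = TRUE)
  expect_equal(m2["I", "I"], 0, ignore_attr = TRUE)
})

test_that("peptide_energy is the weighted contact sum", {
  hla <- toy_hla()
  model <- default_interaction_model()
  zero_model <- interaction_model(matrix(0, 20, 20))
  empty <- contact_map(data.frame(peptide_pos = integer(),
                                  hla_pos = integer(), weight = numeric()))
  cm <- contact_map(data.frame(peptide_pos = 2, hla_pos = 9, weight = 1))

  expect_equal(peptide_energy(hla, cm, zero_model, "CLDEFGHIK"), 0)
  expect_equal(peptide_energy(hla, empty, model, "CLDEFGHIK"), 0)
  # single contact: E = e(peptide[2], hla[9]) exactly
  expect_equal(peptide_energy(hla, cm, model, "CLDEFGHIK"),
               unname(model$energy["L", "A"]))
  # contact beyond the sequence
  bad <- contact_map(data.frame(peptide_pos = 1, hla_pos = 99, weight = 1))
  expect_error(peptide_energy(hla, bad, model, "CLDEFGHIK"), "beyond")
})

test_that("build_contact_map recovers the designed toy contacts", {
  pdb <- generate_toy_structure(seed = 5)
  cm <- build_contact_map(pdb)
  expect_s3_class(cm, "contact_map")
  # designed support: hla residues 1,3,5,7,9 -> peptide 1,5,7,9,2
  expect_equal(cm$peptide_pos, c(1, 2, 5, 7, 9))
  expect_equal(cm$hla_pos, c(1, 9, 3, 5, 7))
  expect_equal(cm$weight, rep(1, 5))    # one contact per position

  expect_equal(nrow(build_contact_map(pdb, cutoff = 0.1)), 0)
  expect_equal(nrow(build_contact_map(pdb, cutoff = 1.0)), 0)
  # binary and atom_count agree on the support
  ac <- build_contact_map(pdb, weighting = "atom_count")
  expect_equal(ac[c("peptide_pos", "hla_pos")],
               cm[c("peptide_pos", "hla_pos")])

  expect_error(build_contact_map(pdb, hla_chain = "Z"), "'Z' not found")
  # drop one peptide residue -> length error
  short <- pdb[!(substr(pdb, 22, 22) == "C" &
                   trimws(substr(pdb, 23, 26)) == "9")]
  expect_error(build_contact_map(short), "8 residues")
})

test_that("mutate_hla mutates exactly one position", {
  hla <- hla_sequence(paste(c(rep("A", 115), "F", rep("A", 70)),
                            collapse = ""), "Cw")
  mut <- mutate_hla(hla, 116, "S")
  expect_equal(substr(mut$residues, 116, 116), "S")
  expect_equal(mut$allele, "Cw_pos116FS")
  # all else identical
  expect_equal(sum(aa_chars_test(mut$residues) !=
                     aa_chars_test(hla$residues)), 1L)
  # involution restores the original residues
  back <- mutate_hla(mut, 116, "F")
  expect_identical(back$residues, hla$residues)

  expect_error(mutate_hla(hla, 116, "F"), "no-op")
  expect_error(mutate_hla(hla, 500, "S"), "outside")
  expect_error(mutate_hla(hla, 1, "B"), "not an amino acid")
})

test_that("run_simulation is deterministic and mixes to the oracle", {
  hla <- mutate_hla(toy_hla(), 9, "I")
  cm <- contact_map(data.frame(peptide_pos = 2, hla_pos = 9, weight = 1))
  model <- default_interaction_model()
  cfg <- simulator_config(n_runs = 500, n_steps = 300, seed = 42,
                          pseudocount = 0)
  r1 <- run_simulation(hla, cm, model, cfg)
  r2 <- run_simulation(hla, cm, model, cfg)
  expect_identical(r1$final_peptides, r2$final_peptides)
  expect_identical(r1$acceptance_rate, r2$acceptance_rate)
  expect_length(r1$final_peptides, 500)

  # n_steps = 0: initialization profile, acceptance undefined
  r0 <- run_simulation(hla, cm, model,
                       simulator_config(n_runs = 2000, n_steps = 0,
                                        seed = 1, pseudocount = 0))
  expect_true(is.na(r0$acceptance_rate))
  expect_true(all(abs(r0$profile$freqs - 0.05) <
                    4 * sqrt(0.05 * 0.95 / 2000)))

  # all-zero model: stationary distribution is uniform
  rz <- run_simulation(hla, cm, interaction_model(matrix(0, 20, 20)),
                       simulator_config(n_runs = 2000, n_steps = 200,
                                        seed = 3, pseudocount = 0))
  expect_equal(rz$acceptance_rate, 1)
  expect_true(all(abs(rz$profile$freqs - 0.05) <
                    4 * sqrt(0.05 * 0.95 / 2000)))

  # contacted position enriched, untouched positions uniform
  exact <- positional_boltzmann(hla, cm, model)
  r <- run_simulation(hla, cm, model,
                      simulator_config(n_runs = 2000, n_steps = 500,
                                       seed = 9, pseudocount = 0))
  expect_gt(max(r$profile$freqs[2, ]), 0.05)
  se <- sqrt(exact * (1 - exact) / 2000)
  expect_true(all(abs(r$profile$freqs - exact) < 4 * pmax(se, 1e-12)))
  expect_equal(unname(exact[c(1, 3:9), ]), matrix(0.05, 8, 20))
})

test_that("temperature limit flattens the profile", {
  hla <- mutate_hla(toy_hla(), 9, "I")
  cm <- contact_map(data.frame(peptide_pos = 2, hla_pos = 9, weight = 1))
  model <- default_interaction_model()
  hot <- positional_boltzmann(hla, cm, model, temperature = 1e6)
  expect_true(all(abs(hot - 0.05) < 1e-6))
  r <- run_simulation(hla, cm, model,
                      simulator_config(n_runs = 1000, n_steps = 200,
                                       seed = 4, temperature = 1e6,
                                       pseudocount = 0))
  expect_true(all(abs(r$profile$freqs - 0.05) <
                    5 * sqrt(0.05 * 0.95 / 1000)))
})

test_that("mismatch_divergence validates and localizes", {
  hla <- toy_hla()
  cm <- contact_map(data.frame(peptide_pos = 9, hla_pos = 5, weight = 1))
  model <- default_interaction_model()
  cfg <- simulator_config(n_runs = 1500, n_steps = 300, seed = 10)

  expect_error(mismatch_divergence(hla, 5, "I", "I", cm, model, cfg),
               "no mismatch")
  expect_error(mismatch_divergence(hla, 5, "I", "D", cm, model, cfg),
               "incompatible")

  # strong I/D swap at the only contacted HLA position: divergence lands
  # on peptide position 9
  hla_i <- mutate_hla(hla, 5, "I")
  md <- mismatch_divergence(hla_i, 5, "I", "D", cm, model, cfg)
  d <- md$divergence$per_position
  expect_gt(d[9], 5 * max(d[1:8]))

  # mutation at a non-contact HLA position: total below a null bound
  # estimated from two independent simulations of the identical sequence
  null_a <- run_simulation(hla_i, cm, model,
                           simulator_config(n_runs = 1500, n_steps = 300,
                                            seed = 101))
  null_b <- run_simulation(hla_i, cm, model,
                           simulator_config(n_runs = 1500, n_steps = 300,
                                            seed = 202))
  null_total <- profile_divergence(null_a$profile, null_b$profile)$total
  md0 <- mismatch_divergence(hla_i, 12, "A", "W", cm, model, cfg)
  expect_lt(md0$divergence$total, 3 * null_total)
})
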