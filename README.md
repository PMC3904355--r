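# mismatchdiv

Does an amino-acid mismatch between a transplant patient's and donor's
HLA-C proteins change which peptides the molecule presents — and does the
size of that change track mortality risk after unrelated-donor
hematopoietic cell transplantation?  `mismatchdiv` implements, as a tested
R pipeline exercisable entirely on synthetic data, the analysis that links
the two: predicted peptide-binding specificity divergence on the
structural side, debiased mismatch-level relative mortality risk on the
clinical side, and the correlation joining them.

It is aimed at computational immunologists and statistical genetics
researchers who want to reproduce, stress-test or extend this style of
mismatch analysis without access to a registry cohort or a
docking cluster.

## The model in brief

**Binding profiles.** The specificity of one HLA variant is a position
frequency matrix (PFM) `F` with entries `F[p, a]`, the frequency of amino
acid `a` at position `p = 1..9` among predicted 9-mer binders.  Profiles
are produced by a Metropolis Monte Carlo sampler over peptide *sequence*
space: `n_runs` independent chains take single-position mutation steps
accepted with probability `min(1, exp(-ΔE/T))` under a contact-map energy

```
E(peptide) = Σ_p Σ_{(h,w) ∈ contacts(p)} w · e(peptide[p], hla[h])
```

where `e` is a symmetric 20×20 residue interaction model built from
Kyte–Doolittle hydropathy and charge.  The final peptide of every chain is
compiled into the PFM — a desk-scale, sequence-only stand-in for running
thousands of flexible-backbone docking simulations, preserving the
interface (sequence in, PFM out).  Because the energy is additive over
peptide positions, the sampler's stationary distribution is an exact
per-position Boltzmann closed form, which the test suite uses as an
oracle.

**Divergence of a mismatch.** For a residue mismatch X/Y at HLA position
`h`, simulate the two variants differing only at `h` and compare their
PFMs column-wise with the base-2 Jensen–Shannon divergence; the sum of
the 9 per-position values (range 0–9) is the predicted specificity
divergence.  A second, model-free measure is `1 − r`, one minus the
Pearson correlation of the two variants' predicted affinities over a
common panel of random 9-mers.

**Risk of a mismatch.** Each cohort record is a patient–donor pair
mismatched at a single HLA-C allele with a binary death outcome.  Per
residue mismatch the pipeline computes oriented mortality rates,
symmetrizes by taking the maximum, debiases by capped subsampling (each
allele-level pair contributes at most `cap = 10` pairs per replicate,
1000 replicates averaged), filters to mismatches with ≥ 100 carriers in
each orientation, and divides by the mortality rate of all pairs lacking
the mismatch to get a relative risk.

**Association.** Pearson and Spearman correlation (with p-values) of
relative risk against predicted divergence across mismatches.

## Worked example

Structural side — divergence of an I/D mismatch at an HLA position that
contacts only peptide position 7 of the toy structure:

```r
library(mismatchdiv)
cmap <- build_contact_map(generate_toy_structure(seed = 1))
hla  <- mutate_hla(hla_sequence(strrep("A", 20), "TOY*01"), 5, "I")
md   <- mismatch_divergence(hla, position = 5, res_a = "I", res_b = "D",
                            cmap, default_interaction_model(),
                            simulator_config(n_runs = 2000, n_steps = 500,
                                             seed = 42))
md$divergence
#> divergence_result: TOY*01_pos5AI vs TOY*01_pos5AI_pos5ID
#>   per position: 0.003 0.004 0.002 0.003 0.003 0.002 0.273 0.005 0.002
#>   total: 0.2968179
```

The divergence concentrates at peptide position 7 — the only position the
mutated HLA residue touches; the other eight values are sampling noise.
Swapping hydrophobic I for charged D at a pocket position reshuffles
roughly a quarter of a bit of that position's residue preference.

Clinical side — synthetic cohort, risk pipeline, and recovery of the
generator's ground truth:

```r
seed  <- 1
pool  <- generate_allele_pool(seed = derive_seed(seed, "pool"))
truth <- assign_ground_truth(pool, seed = derive_seed(seed, "truth"))
coh   <- generate_cohort(pool, truth,
                         cohort_model(n_pairs = 2000,
                                      seed = derive_seed(seed, "cohort")))
risk  <- run_risk_pipeline(coh, risk_config(seed = derive_seed(seed, "risk")))
head(risk[, c("position", "res_a", "res_b", "count_or1", "count_or2",
              "rate_adjusted", "relative_risk")], 3)
#>   position res_a res_b count_or1 count_or2 rate_adjusted relative_risk
#> 1        7     L     Q       469       440     0.6213514     1.2280694
#> 2        8     D     M       297       289     0.7269067     1.5159971
#> 3       17     H     Y       766       763     0.5854730     0.9778644
associate(risk, truth$delta)
#> association_result over 12 mismatches
#>   Pearson  r = 0.406 (P = 0.19)
#>   Spearman r = 0.345 (P = 0.272)
```

Each risk-table row is one unoriented residue mismatch: its carrier
counts per orientation, the subsampling-adjusted symmetrized mortality
rate, and the relative risk against non-carriers.  The positive Pearson
correlation between estimated relative risk and the generator's true
per-mismatch divergence shows the pipeline recovering a planted
divergence–mortality effect from outcome data alone; at the default
production scale (`n_pairs = 5000`) it exceeds 0.4 in 10/10 test seeds.

`run_all(out_dir, seed)` chains synthesize → risk → simulate → associate
and writes every artifact (FASTA, cohort TSV, PFM TSVs, risk table,
scatter and summary) into `out_dir`, byte-identically per seed.  A
command-line front end with the same subcommands is installed at
`system.file("cli", "mismatchdiv.R", package = "mismatchdiv")`.

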