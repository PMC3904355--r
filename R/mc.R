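#' Construct an HLA sequence object
#'
#' Holds an allele label and the residue string of the mature protein.
#' Positions are 1-based over this string, following the conventional
#' mature-protein numbering of class I heavy chains (so the classical
#' HLA-C pocket positions 9, 77, 99, 116, 152 index directly).
#'
#' @param residues Amino-acid string over [AA_ALPHABET].
#' @param allele Allele label.
#' @return Object of class `hla_sequence` with `allele` and `residues`.
#' @export
hla_sequence <- function(residues, allele = "allele") {
  stopifnot(is.character(residues), length(residues) == 1L)
  ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), residues)
  if (!ok) {
    stop("HLA sequence contains a non-alphabet symbol", call. = FALSE)
  }
  structure(list(allele = as.character(allele), residues = residues),
            class = "hla_sequence")
}

#' @export
print.hla_sequence <- function(x, ...) {
  cat("hla_sequence '", x$allele, "' (", nchar(x$residues), " residues)\n",
      sep = "")
  invisible(x)
}

#' Point-mutate an HLA sequence
#'
#' Returns a copy of the sequence differing only at `position`, the basic
#' move for building the two members of a mismatched variant pair ("differ
#' only by the mismatch in question").  The label is suffixed
#' `pos<position><old><new>`, e.g. `pos116FS`.
#'
#' @param hla An [hla_sequence()].
#' @param position 1-based residue position.
#' @param new_residue Replacement amino acid; must differ from the current
#'   residue (a no-op mutation is not a mismatch and is rejected).
#' @return A new `hla_sequence`.
#' @export
mutate_hla <- function(hla, position, new_residue) {
  stopifnot(inherits(hla, "hla_sequence"))
  n <- nchar(hla$residues)
  if (!is.numeric(position) || length(position) != 1L ||
      position < 1 || position > n) {
    stop("position ", position, " outside sequence of length ", n,
         call. = FALSE)
  }
  if (!new_residue %in% AA_ALPHABET) {
    stop("new_residue '", new_residue, "' is not an amino acid",
         call. = FALSE)
  }
  old <- substr(hla$residues, position, position)
  if (old == new_residue) {
    stop("no-op mismatch: position ", position, " already carries ",
         new_residue, call. = FALSE)
  }
  res <- hla$residues
  substr(res, position, position) <- new_residue
  hla_sequence(res, allele = paste0(hla$allele, "_pos", position, old,
                                    new_residue))
}

#' Construct a contact map
#'
#' A contact map couples each peptide position 1..9 to the HLA residues it
#' packs against, with nonnegative weights.  It is the structural skeleton
#' the sequence-space sampler keeps from the docking picture: the pocket
#' composition each peptide position feels is determined by the contacted
#' HLA residues.
#'
#' @param contacts `data.frame` with columns `peptide_pos` (1..9),
#'   `hla_pos` (1-based) and `weight` (>= 0).  Peptide positions absent
#'   from the table simply have no contacts.
#' @return Object of class `contact_map` (a validated data.frame).
#' @seealso [build_contact_map()] to derive one from a structure.
#' @export
contact_map <- function(contacts) {
  contacts <- as.data.frame(contacts)
  need <- c("peptide_pos", "hla_pos", "weight")
  if (!all(need %in% names(contacts))) {
    stop("contact map needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  contacts <- contacts[need]
  contacts$peptide_pos <- as.integer(contacts$peptide_pos)
  contacts$hla_pos <- as.integer(contacts$hla_pos)
  contacts$weight <- as.numeric(contacts$weight)
  if (nrow(contacts) > 0L) {
    stopifnot(all(contacts$peptide_pos >= 1L),
              all(contacts$peptide_pos <= PEPTIDE_LENGTH),
              all(contacts$hla_pos >= 1L),
              all(contacts$weight >= 0))
  }
  contacts <- contacts[order(contacts$peptide_pos, contacts$hla_pos), ,
                       drop = FALSE]
  rownames(contacts) <- NULL
  class(contacts) <- c("contact_map", "data.frame")
  contacts
}

#' Default residue-residue interaction model
#'
#' Symmetric 20 x 20 contact energy in thermal (kT) units built from two
#' physicochemical axes known to discriminate permissive from risky
#' mismatches: hydropathy and charge.
#' `e(a, b) = -w_h * h(a) * h(b) + w_q * q(a) * q(b)` with `h` the
#' Kyte-Doolittle hydropathy rescaled to \[-1, 1\] and `q` in \{-1, 0, +1\}
#' (D, E negative; K, R positive).  Hydrophobic pairs attract; like charges
#' repel, opposite charges attract.
#'
#' @param w_h,w_q Nonnegative weights of the hydropathy and charge terms.
#' @return Object of class `interaction_model`: a symmetric named 20 x 20
#'   matrix under `$energy`.
#' @export
default_interaction_model <- function(w_h = 1.0, w_q = 1.0) {
  h <- KD_HYDROPATHY[AA_ALPHABET] / max(abs(KD_HYDROPATHY))
  q <- stats::setNames(numeric(20), AA_ALPHABET)
  q[c("D", "E")] <- -1
  q[c("K", "R")] <- +1
  energy <- -w_h * outer(h, h) + w_q * outer(q, q)
  dimnames(energy) <- list(AA_ALPHABET, AA_ALPHABET)
  interaction_model(energy)
}

#' Construct an interaction model from an energy matrix
#'
#' @param energy Symmetric finite numeric 20 x 20 matrix in kT units, rows
#'   and columns in [AA_ALPHABET] order.
#' @return Object of class `interaction_model`.
#' @export
interaction_model <- function(energy) {
  energy <- as.matrix(energy)
  if (!identical(dim(energy), c(20L, 20L)) || !all(is.finite(energy))) {
    stop("energy must be a finite 20 x 20 matrix", call. = FALSE)
  }
  if (max(abs(energy - t(energy))) > 1e-9) {
    stop("energy matrix must be symmetric", call. = FALSE)
  }
  dimnames(energy) <- list(AA_ALPHABET, AA_ALPHABET)
  structure(list(energy = energy), class = "interaction_model")
}

#' Simulator configuration
#'
#' @param n_runs Number of independent Monte Carlo chains; each contributes
#'   one final peptide to the compiled profile (default 2000; the full
#'   production scale of the docking analogue is 20000).
#' @param n_steps Single-position mutation proposals per chain (default 200).
#' @param temperature Metropolis temperature in kT (> 0, default 1).
#' @param seed Master seed for the simulation.
#' @param pseudocount Smoothing used when compiling the final peptides into
#'   a profile (default 0.5).
#' @return Object of class `simulator_config`.
#' @export
simulator_config <- function(n_runs = 2000L, n_steps = 200L,
                             temperature = 1.0, seed = 1L,
                             pseudocount = 0.5) {
  stopifnot(n_runs >= 1, n_steps >= 0, temperature > 0, pseudocount >= 0)
  structure(
    list(n_runs = as.integer(n_runs), n_steps = as.integer(n_steps),
         temperature = as.numeric(temperature), seed = as.integer(seed),
         pseudocount = as.numeric(pseudocount)),
    class = "simulator_config"
  )
}

# Per-position energy table: 9 x 20 matrix with
#   Epos[p, a] = sum over contacts (h, w) of peptide position p of
#                w * e(a, hla[h]).
# The total peptide energy is additive over positions, which is what makes
# the stationary distribution factorise (see positional_boltzmann()).
positional_energy <- function(hla, cmap, model) {
  stopifnot(inherits(hla, "hla_sequence"), inherits(model, "interaction_model"))
  cmap <- contact_map(cmap)
  n <- nchar(hla$residues)
  if (nrow(cmap) > 0L && max(cmap$hla_pos) > n) {
    stop("contact map references HLA position ", max(cmap$hla_pos),
         " beyond sequence length ", n, call. = FALSE)
  }
  hla_res <- aa_chars(hla$residues)
  epos <- matrix(0, PEPTIDE_LENGTH, length(AA_ALPHABET),
                 dimnames = list(NULL, AA_ALPHABET))
  for (i in seq_len(nrow(cmap))) {
    p <- cmap$peptide_pos[i]
    epos[p, ] <- epos[p, ] +
      cmap$weight[i] * model$energy[, hla_res[cmap$hla_pos[i]]]
  }
  epos
}

#' Contact-map energy of a peptide bound to an HLA variant
#'
#' `E = sum over peptide positions p, contacts (h, w) of p of
#' w * e(peptide[p], hla[h])` in kT units.  This pairwise-additive energy
#' replaces all-atom force-field scoring in the sequence-space sampler.
#'
#' @param hla An [hla_sequence()].
#' @param cmap A [contact_map()].
#' @param model An [interaction_model()].
#' @param peptide 9-mer string (or vector of 9-mers).
#' @return Numeric energy (kT), one value per peptide.
#' @export
peptide_energy <- function(hla, cmap, model, peptide) {
  validate_peptides(peptide)
  epos <- positional_energy(hla, cmap, model)
  idx <- matrix(aa_index(unlist(strsplit(peptide, "", fixed = TRUE),
                                use.names = FALSE)),
                nrow = PEPTIDE_LENGTH)
  e <- epos[cbind(rep(seq_len(PEPTIDE_LENGTH), ncol(idx)), as.vector(idx))]
  colSums(matrix(e, nrow = PEPTIDE_LENGTH))
}

#' Closed-form stationary peptide-position distributions
#'
#' Because the contact-map energy is additive over peptide positions, the
#' Metropolis chain's stationary distribution factorises: the residue at
#' peptide position `p` is Boltzmann-distributed with
#' `P(a) = exp(-Epos[p, a] / T) / Z_p` independently of the other
#' positions.  This closed form is the exact oracle against which the
#' sampler is validated.
#'
#' @inheritParams peptide_energy
#' @param temperature Temperature in kT.
#' @return 9 x 20 matrix of exact stationary frequencies (rows sum to 1).
#' @export
positional_boltzmann <- function(hla, cmap, model, temperature = 1.0) {
  stopifnot(temperature > 0)
  epos <- positional_energy(hla, cmap, model)
  w <- exp(-epos / temperature)
  w / rowSums(w)
}

#' Run the Metropolis Monte Carlo binding-specificity simulation
#'
#' Samples peptide sequence space for one HLA variant: `n_runs` independent
#' chains each start from a uniformly random 9-mer and perform `n_steps`
#' single-position mutation proposals (position uniform over 1..9, new
#' residue uniform over the other 19), accepted with probability
#' `min(1, exp(-dE / temperature))` under the contact-map energy.  The final
#' sequence of every chain is kept and compiled into a position frequency
#' matrix — the sequence-space analogue of running many independent docking
#' simulations and compiling the optimised peptides.
#'
#' All chains are advanced in lock-step from one seeded RNG stream, which
#' keeps them statistically independent while letting each sweep be a
#' vectorised operation; results are bit-reproducible given
#' `config$seed`.
#'
#' @param hla An [hla_sequence()].
#' @param cmap A [contact_map()].
#' @param model An [interaction_model()].
#' @param config A [simulator_config()].
#' @return Object of class `simulation_result`: `final_peptides`
#'   (character, length `n_runs`), `profile` (a [binding_profile()]) and
#'   `acceptance_rate` (fraction of accepted proposals; `NA` when
#'   `n_steps = 0`, since zero proposals have no acceptance rate).
#' @export
run_simulation <- function(hla, cmap, model, config = simulator_config()) {
  stopifnot(inherits(config, "simulator_config"))
  epos <- positional_energy(hla, cmap, model)
  n_runs <- config$n_runs
  n_steps <- config$n_steps
  inv_t <- 1 / config$temperature

  res <- withr::with_seed(config$seed, {
    # state[r, p] = residue index of chain r at peptide position p
    state <- matrix(sample.int(20L, n_runs * PEPTIDE_LENGTH, replace = TRUE),
                    nrow = n_runs)
    accepted <- 0
    if (n_steps > 0L) {
      for (step in seq_len(n_steps)) {
        pos <- sample.int(PEPTIDE_LENGTH, n_runs, replace = TRUE)
        cur <- state[cbind(seq_len(n_runs), pos)]
        # uniform over the 19 residues other than the current one
        prop <- cur + sample.int(19L, n_runs, replace = TRUE)
        prop <- ifelse(prop > 20L, prop - 20L, prop)
        d_e <- epos[cbind(pos, prop)] - epos[cbind(pos, cur)]
        acc <- stats::runif(n_runs) < exp(-d_e * inv_t)
        state[cbind(seq_len(n_runs), pos)[acc, , drop = FALSE]] <- prop[acc]
        accepted <- accepted + sum(acc)
      }
    }
    list(state = state, accepted = accepted)
  })

  letters_mat <- matrix(AA_ALPHABET[res$state], nrow = n_runs)
  final_peptides <- apply(letters_mat, 1, paste, collapse = "")
  profile <- compile_pfm(final_peptides, pseudocount = config$pseudocount,
                         label = hla$allele)
  structure(
    list(final_peptides = final_peptides,
         profile = profile,
         acceptance_rate = if (n_steps == 0L) NA_real_ else
           res$accepted / (as.numeric(n_runs) * n_steps)),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("simulation_result: ", length(x$final_peptides), " chains, acceptance ",
      if (is.na(x$acceptance_rate)) "NA" else
        sprintf("%.3f", x$acceptance_rate), "\n", sep = "")
  print(x$profile)
  invisible(x)
}

#' Predicted specificity divergence of a single residue mismatch
#'
#' Builds the two HLA variants that differ only by the mismatch
#' (`res_a`/`res_b` at `position`), simulates the binding specificity of
#' each with independent seeded streams, and compares the compiled
#' profiles.  The template sequence must already carry one of the two
#' residues at the position (mismatches incompatible with the template are
#' rejected rather than modelled).
#'
#' @param hla Template [hla_sequence()] carrying `res_a` or `res_b` at
#'   `position`.
#' @param position 1-based HLA position of the mismatch.
#' @param res_a,res_b The two mismatched residues (must differ).
#' @param cmap A [contact_map()].
#' @param model An [interaction_model()].
#' @param config A [simulator_config()]; per-variant seeds are derived from
#'   `config$seed`.
#' @return List with `divergence` (a [profile_divergence()] result),
#'   `result_a` and `result_b` (the per-variant `simulation_result`s).
#' @export
mismatch_divergence <- function(hla, position, res_a, res_b, cmap, model,
                                config = simulator_config()) {
  stopifnot(inherits(hla, "hla_sequence"))
  if (res_a == res_b) {
    stop("no mismatch: res_a and res_b are both '", res_a, "'",
         call. = FALSE)
  }
  template <- substr(hla$residues, position, position)
  if (!template %in% c(res_a, res_b)) {
    stop("template '", hla$allele, "' carries ", template, " at position ",
         position, ", neither ", res_a, " nor ", res_b,
         "; mismatch incompatible with template", call. = FALSE)
  }
  variant <- function(res, idx) {
    v <- if (template == res) hla else mutate_hla(hla, position, res)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "mismatch_divergence", idx)
    run_simulation(v, cmap, model, cfg)
  }
  result_a <- variant(res_a, 1L)
  result_b <- variant(res_b, 2L)
  list(divergence = profile_divergence(result_a$profile, result_b$profile),
       result_a = result_a, result_b = result_b)
}
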