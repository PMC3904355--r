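#' The 20-letter amino-acid alphabet
#'
#' Canonical single-letter codes in fixed alphabetical order.  Every matrix
#' in the package (position frequency matrices, interaction models) uses this
#' order for its amino-acid dimension, so columns are comparable across
#' objects without re-indexing.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Peptide length handled by the pipeline
#'
#' Binding profiles, peptide panels and the Monte Carlo sampler all operate
#' on 9-mers; MHC class I grooves bind 9-mers in the canonical register and
#' the modelling focuses on that length.  Other lengths are rejected.
#'
#' @export
PEPTIDE_LENGTH <- 9L

#' Kyte-Doolittle hydropathy scale
#'
#' Named vector over [AA_ALPHABET]. Used by [default_interaction_model()],
#' where it is linearly rescaled to \[-1, 1\] (the scale is symmetric about
#' zero: I = +4.5, R = -4.5, so rescaling divides by 4.5).
#'
#' @format Named numeric vector of length 20.
#' @export
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# residue letter -> 1..20 index; NA for non-alphabet symbols
aa_index <- function(x) {
  match(x, AA_ALPHABET)
}

# split a residue string into single letters
aa_chars <- function(s) {
  strsplit(s, "", fixed = TRUE)[[1]]
}

# validate a character vector of peptides: length 9, alphabet only.
# Errors name the first offending peptide.
validate_peptides <- function(peptides) {
  if (length(peptides) == 0L) {
    stop("peptide list is empty", call. = FALSE)
  }
  if (!is.character(peptides)) {
    stop("peptides must be a character vector", call. = FALSE)
  }
  bad_len <- nchar(peptides) != PEPTIDE_LENGTH
  if (any(bad_len)) {
    stop("peptide '", peptides[which(bad_len)[1]], "' does not have length ",
         PEPTIDE_LENGTH, call. = FALSE)
  }
  ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), peptides)
  if (!all(ok)) {
    stop("peptide '", peptides[which(!ok)[1]],
         "' contains a non-alphabet symbol", call. = FALSE)
  }
  invisible(peptides)
}

#' Derive a stage-specific RNG seed from a master seed
#'
#' One master seed drives every stochastic component of a pipeline run;
#' per-stage streams are decoupled by hashing the stage name and an index
#' into the seed.  The hash is a plain polynomial accumulation over the
#' stage string modulo 2^31 - 1, so the scheme is easy to restate in any
#' language (structure, not bits, is what a reimplementation would match).
#'
#' @param seed Master seed (integer).
#' @param stage Stage name (character scalar).
#' @param index Optional stream index within the stage.
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647               # 2^31 - 1, keeps results in integer range
  h <- 0
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% m
  }
  s <- (abs(seed) %% m)
  s <- (s * 48271) %% m         # Lehmer multiplier decorrelates nearby seeds
  as.integer((s + h * 7919 + index * 104729) %% (m - 1) + 1)
}
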