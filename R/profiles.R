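#' Construct a binding profile (position frequency matrix)
#'
#' A binding profile summarises the peptide-binding specificity of one HLA
#' variant as a 9 x 20 matrix of per-position amino-acid frequencies: row
#' `p` is the probability distribution over residues observed at peptide
#' position `p` among predicted binders.
#'
#' @param freqs Numeric 9 x 20 matrix; rows are peptide positions 1..9,
#'   columns the amino acids in [AA_ALPHABET] order.  Each row must be
#'   nonnegative and sum to 1 within `1e-9` (rows are renormalised exactly
#'   after validation).
#' @param label Name of the allele or variant the profile describes.
#' @return An object of class `binding_profile` with elements `label`,
#'   `length` (always 9) and `freqs`.
#' @seealso [compile_pfm()], [profile_divergence()], [read_pfm()]
#' @export
binding_profile <- function(freqs, label = "profile") {
  freqs <- as.matrix(freqs)
  if (!is.numeric(freqs) || nrow(freqs) != PEPTIDE_LENGTH ||
      ncol(freqs) != length(AA_ALPHABET)) {
    stop("freqs must be a numeric ", PEPTIDE_LENGTH, " x ",
         length(AA_ALPHABET), " matrix", call. = FALSE)
  }
  if (any(freqs < 0)) {
    stop("frequencies must be nonnegative", call. = FALSE)
  }
  sums <- rowSums(freqs)
  bad <- which(abs(sums - 1) > 1e-9)
  if (length(bad) > 0L) {
    stop("row for peptide position ", bad[1], " sums to ",
         format(sums[bad[1]]), ", not 1", call. = FALSE)
  }
  freqs <- freqs / sums
  dimnames(freqs) <- list(position = as.character(seq_len(PEPTIDE_LENGTH)),
                          residue = AA_ALPHABET)
  structure(
    list(label = as.character(label), length = PEPTIDE_LENGTH, freqs = freqs),
    class = "binding_profile"
  )
}

#' @export
print.binding_profile <- function(x, ...) {
  cat("binding_profile '", x$label, "': ", x$length,
      " positions x 20 amino acids\n", sep = "")
  top <- apply(x$freqs, 1, function(f) AA_ALPHABET[which.max(f)])
  cat("  consensus:", paste(top, collapse = ""), "\n")
  invisible(x)
}

#' Compile peptides into a position frequency matrix
#'
#' Counts residue occurrences per peptide position over a set of 9-mers and
#' normalises, with optional additive smoothing:
#' `freq[p, a] = (count(a at p) + pseudocount) / (N + 20 * pseudocount)`.
#'
#' @param peptides Character vector of 9-mer peptides over [AA_ALPHABET].
#' @param pseudocount Nonnegative smoothing constant added to every count.
#' @param label Label for the resulting profile.
#' @return A [binding_profile()].
#' @examples
#' compile_pfm(c("AAAAAAAAA", "CAAAAAAAA"), pseudocount = 0)
#' @export
compile_pfm <- function(peptides, pseudocount = 0, label = "pfm") {
  validate_peptides(peptides)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0) {
    stop("pseudocount must be a single nonnegative number", call. = FALSE)
  }
  n <- length(peptides)
  idx <- matrix(aa_index(unlist(strsplit(peptides, "", fixed = TRUE),
                                use.names = FALSE)),
                nrow = PEPTIDE_LENGTH)   # positions x peptides
  counts <- matrix(0, PEPTIDE_LENGTH, length(AA_ALPHABET))
  for (p in seq_len(PEPTIDE_LENGTH)) {
    counts[p, ] <- tabulate(idx[p, ], nbins = length(AA_ALPHABET))
  }
  freqs <- (counts + pseudocount) / (n + length(AA_ALPHABET) * pseudocount)
  binding_profile(freqs, label = label)
}

# Shannon entropy in bits of one or more probability rows; 0 log 0 = 0.
shannon_entropy <- function(p) {
  p <- as.matrix(p)
  lp <- ifelse(p > 0, log2(p), 0)
  -rowSums(p * lp)
}

#' Jensen-Shannon divergence between two probability vectors
#'
#' Base-2 Jensen-Shannon divergence
#' `JSD(p, q) = H(m) - (H(p) + H(q)) / 2` with `m = (p + q) / 2` and `H`
#' the Shannon entropy in bits.  Symmetric, bounded in \[0, 1\]; 0 iff
#' `p == q`, 1 iff the supports are disjoint.
#'
#' @param p,q Nonnegative numeric vectors of length 20 summing to 1 within
#'   `1e-6`.
#' @return Divergence in \[0, 1\].
#' @examples
#' p <- c(0.5, 0.5, rep(0, 18)); q <- c(1, rep(0, 19))
#' jsd_column(p, q)  # 0.311278
#' @export
jsd_column <- function(p, q) {
  for (v in list(p, q)) {
    if (!is.numeric(v) || length(v) != length(AA_ALPHABET)) {
      stop("probability vectors must be numeric of length ",
           length(AA_ALPHABET), call. = FALSE)
    }
    if (any(v < 0) || abs(sum(v) - 1) > 1e-6) {
      stop("input is not a normalized probability vector (sum = ",
           format(sum(v)), ")", call. = FALSE)
    }
  }
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  d <- shannon_entropy(rbind(m)) -
    (shannon_entropy(rbind(p)) + shannon_entropy(rbind(q))) / 2
  # clamp away floating-point dust at the boundaries
  min(max(as.numeric(d), 0), 1)
}

#' Per-position specificity divergence between two binding profiles
#'
#' Compares two position frequency matrices column by column with the
#' base-2 Jensen-Shannon divergence.  The sum of the 9 per-position values
#' is the predicted binding-specificity divergence of the variant pair,
#' bounded in \[0, 9\].
#'
#' @param a,b [binding_profile()] objects of equal length.
#' @return An object of class `divergence_result`: `per_position` (9
#'   values in \[0, 1\]), `total` (their sum) and the two labels.
#' @export
profile_divergence <- function(a, b) {
  stopifnot(inherits(a, "binding_profile"), inherits(b, "binding_profile"))
  if (a$length != b$length || !identical(dim(a$freqs), dim(b$freqs))) {
    stop("profiles have mismatched dimensions", call. = FALSE)
  }
  per_position <- vapply(seq_len(a$length),
                         function(p) jsd_column(a$freqs[p, ], b$freqs[p, ]),
                         numeric(1))
  structure(
    list(label_a = a$label, label_b = b$label,
         per_position = per_position, total = sum(per_position)),
    class = "divergence_result"
  )
}

#' @export
print.divergence_result <- function(x, ...) {
  cat("divergence_result: ", x$label_a, " vs ", x$label_b, "\n", sep = "")
  cat("  per position:",
      paste(sprintf("%.3f", x$per_position), collapse = " "), "\n")
  cat("  total:", format(x$total), "\n")
  invisible(x)
}

#' Differential profile between two binding profiles
#'
#' Signed per-position frequency differences `a - b`, highlighting the
#' residues favoured by one variant over the other (positive entries bind
#' variant `a` more favourably).  `column_height` carries the per-position
#' Jensen-Shannon divergence, the quantity used to scale differential-logo
#' columns for display.
#'
#' @param a,b [binding_profile()] objects of equal shape.
#' @return Object of class `differential_profile` with `diff` (9 x 20
#'   signed matrix, rows sum to 0) and `column_height` (9 divergences).
#' @export
differential_profile <- function(a, b) {
  div <- profile_divergence(a, b)
  structure(
    list(label_a = a$label, label_b = b$label,
         diff = a$freqs - b$freqs,
         column_height = div$per_position),
    class = "differential_profile"
  )
}

#' Log-frequency score of a peptide against a binding profile
#'
#' Additive position-specific scoring-matrix score used as a pseudo-affinity:
#' `sum over positions of log2((freq[p, aa] + alpha) / (1 + 20 * alpha))`.
#' Higher scores mean better predicted binding; `alpha` smooths away zero
#' frequencies.
#'
#' @param profile A [binding_profile()].
#' @param peptide A 9-mer string (or character vector of 9-mers, scored
#'   independently).
#' @param alpha Nonnegative smoothing constant; with `alpha = 0` a zero
#'   frequency at a used residue is an error.
#' @return Numeric score(s) in log2 units.
#' @export
score_peptide <- function(profile, peptide, alpha = 0.001) {
  stopifnot(inherits(profile, "binding_profile"))
  validate_peptides(peptide)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    stop("alpha must be a single nonnegative number", call. = FALSE)
  }
  idx <- matrix(aa_index(unlist(strsplit(peptide, "", fixed = TRUE),
                                use.names = FALSE)),
                nrow = PEPTIDE_LENGTH)   # positions x peptides
  f <- profile$freqs[cbind(rep(seq_len(PEPTIDE_LENGTH), ncol(idx)),
                           as.vector(idx))]
  if (alpha == 0 && any(f == 0)) {
    stop("peptide uses a residue with zero profile frequency; ",
         "use a nonzero smoothing alpha", call. = FALSE)
  }
  sc <- log2((f + alpha) / (1 + length(AA_ALPHABET) * alpha))
  colSums(matrix(sc, nrow = PEPTIDE_LENGTH))
}

#' Generate a random peptide panel
#'
#' Draws `n` 9-mers with residues i.i.d. uniform over the 20-letter
#' alphabet.  Panels are the common reference set over which two profiles'
#' predicted affinities are correlated (see
#' [affinity_correlation_divergence()]); the same seeded panel must be used
#' for every profile pair being compared.
#'
#' @param n Number of peptides (>= 1).
#' @param seed RNG seed; panels are deterministic given the seed.
#' @return Object of class `peptide_panel` with `peptides` and `seed`.
#' @export
make_random_panel <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  peptides <- withr::with_seed(seed, {
    letters20 <- matrix(sample(AA_ALPHABET, n * PEPTIDE_LENGTH, replace = TRUE),
                        nrow = n)
    apply(letters20, 1, paste, collapse = "")
  })
  structure(list(peptides = peptides, seed = as.integer(seed)),
            class = "peptide_panel")
}

#' Affinity-correlation divergence between two binding profiles
#'
#' Model-free divergence between two specificity predictions: score every
#' peptide of a common random panel against both profiles and return
#' `1 - r`, where `r` is the Pearson correlation of the two score vectors.
#' Values lie in \[0, 2\]; identical profiles give exactly 0.  Because it
#' only needs predicted affinities, the measure can compare specificity
#' predictors that share no underlying model.
#'
#' @param a,b [binding_profile()] objects.
#' @param panel A [make_random_panel()] panel (nonempty).
#' @param alpha Smoothing constant passed to [score_peptide()].
#' @return Divergence in \[0, 2\], or `NA` (with a warning) when either
#'   score vector has zero variance, where the correlation is undefined.
#' @export
affinity_correlation_divergence <- function(a, b, panel, alpha = 0.001) {
  stopifnot(inherits(panel, "peptide_panel"))
  if (length(panel$peptides) == 0L) {
    stop("panel is empty", call. = FALSE)
  }
  sa <- score_peptide(a, panel$peptides, alpha = alpha)
  sb <- score_peptide(b, panel$peptides, alpha = alpha)
  if (identical(a$freqs, b$freqs)) {
    return(0)                     # r = 1 exactly; avoid floating-point dust
  }
  if (stats::sd(sa) == 0 || stats::sd(sb) == 0) {
    warning("score vector with zero variance: correlation divergence undefined")
    return(NA_real_)
  }
  1 - stats::cor(sa, sb)
}
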