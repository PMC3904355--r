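#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation with the classical two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#' Degenerate inputs (zero variance) yield an explicit `NA` result rather
#' than an error or a silent zero.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return List with `r`, `p` and `n`.
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Spearman rank correlation with a p-value
#'
#' Pearson correlation applied to average ranks (so ties are handled by
#' midranks), with the large-sample t approximation for the p-value —
#' adequate for the descriptive use made of it here.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return List with `r`, `p` and `n`; `NA` (with a warning) when either
#'   vector is entirely tied.
#' @export
spearman_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete observations",
                           call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("all-tied vector: rank correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  pearson_with_p(rx, ry)
}

#' Join risk factors to divergence predictions and correlate
#'
#' Inner join of a risk table and a divergence table on the unoriented
#' mismatch key (`position`, sorted residue pair), followed by Pearson and
#' Spearman correlation of relative risk against predicted divergence —
#' the pipeline's headline statistic.  Rows with undefined relative risk
#' are dropped (their number is reported via a message and in the result).
#'
#' @param risk_table Output of [run_risk_pipeline()] (or any data.frame
#'   with `position`, `res_a`, `res_b`, `relative_risk`).
#' @param divergence_table `data.frame` with `position`, `res_a`, `res_b`
#'   and a divergence column (`divergence_total`, `total` or `delta` —
#'   first present wins, or set `divergence_col`).
#' @param divergence_col Optional explicit divergence column name.
#' @return Object of class `association_result`: `n`, `pearson_r`,
#'   `pearson_p`, `spearman_r`, `spearman_p`, `n_dropped` and `scatter`
#'   (the joined per-mismatch records).
#' @export
associate <- function(risk_table, divergence_table, divergence_col = NULL) {
  div <- as.data.frame(divergence_table)
  if (is.null(divergence_col)) {
    divergence_col <- intersect(c("divergence_total", "total", "delta"),
                                names(div))[1]
  }
  if (is.na(divergence_col) || !divergence_col %in% names(div)) {
    stop("divergence table has no recognised divergence column",
         call. = FALSE)
  }
  risk <- as.data.frame(risk_table)
  for (d in list(risk, div)) {
    stopifnot(all(c("position", "res_a", "res_b") %in% names(d)))
  }
  key_r <- mismatch_key(risk$position, risk$res_a, risk$res_b)
  key_d <- mismatch_key(div$position, div$res_a, div$res_b)
  idx <- match(key_r, key_d)
  joined <- risk[!is.na(idx), , drop = FALSE]
  joined$divergence <- div[[divergence_col]][idx[!is.na(idx)]]
  defined <- !is.na(joined$relative_risk) & !is.na(joined$divergence)
  n_dropped <- sum(!defined)
  if (n_dropped > 0L) {
    message("associate: dropped ", n_dropped,
            " mismatches with undefined risk or divergence")
  }
  joined <- joined[defined, , drop = FALSE]
  if (nrow(joined) < 3L) {
    stop("fewer than 3 mismatches shared between risk and divergence ",
         "tables", call. = FALSE)
  }
  joined <- joined[order(joined$position, joined$res_a, joined$res_b), ,
                   drop = FALSE]
  rownames(joined) <- NULL
  pe <- pearson_with_p(joined$divergence, joined$relative_risk)
  sp <- spearman_with_p(joined$divergence, joined$relative_risk)
  structure(
    list(n = nrow(joined), pearson_r = pe$r, pearson_p = pe$p,
         spearman_r = sp$r, spearman_p = sp$p, n_dropped = n_dropped,
         scatter = joined),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat("association_result over", x$n, "mismatches\n")
  cat(sprintf("  Pearson  r = %.3f (P = %.3g)\n", x$pearson_r, x$pearson_p))
  cat(sprintf("  Spearman r = %.3f (P = %.3g)\n", x$spearman_r, x$spearman_p))
  if (x$n_dropped > 0) cat("  (", x$n_dropped, "undefined rows dropped )\n")
  invisible(x)
}

#' Concordance of the two divergence measures
#'
#' For each supplied profile pair, computes both the total Jensen-Shannon
#' divergence and the affinity-correlation divergence (`1 - r` over a
#' common random peptide panel), then correlates the two measures across
#' pairs.  High concordance between these structurally unrelated measures
#' is evidence that the divergence signal is not an artifact of either
#' definition.
#'
#' @param profile_pairs List of >= 3 pairs, each a list with elements `a`
#'   and `b` (as returned by [generate_pfm_pair()]).
#' @param panel A common [make_random_panel()]; default 10000 peptides,
#'   seed 1.
#' @param alpha Smoothing for [score_peptide()].
#' @return List with `pearson_r`, `pearson_p`, `spearman_r`, `spearman_p`
#'   and `measures` (per-pair `jsd_total` and `corr_divergence`);
#'   correlations are `NA`-flagged when either measure is degenerate.
#' @export
compare_divergence_measures <- function(profile_pairs,
                                        panel = make_random_panel(10000,
                                                                  seed = 1L),
                                        alpha = 0.001) {
  stopifnot(is.list(profile_pairs), length(profile_pairs) >= 3L)
  jsd_total <- vapply(profile_pairs, function(pr) {
    profile_divergence(pr$a, pr$b)$total
  }, numeric(1))
  corr_div <- vapply(profile_pairs, function(pr) {
    affinity_correlation_divergence(pr$a, pr$b, panel, alpha = alpha)
  }, numeric(1))
  measures <- data.frame(jsd_total = jsd_total, corr_divergence = corr_div)
  if (stats::sd(jsd_total) == 0 || all(is.na(corr_div)) ||
      stats::sd(corr_div, na.rm = TRUE) == 0) {
    warning("degenerate divergence measures: correlation undefined")
    return(list(pearson_r = NA_real_, pearson_p = NA_real_,
                spearman_r = NA_real_, spearman_p = NA_real_,
                measures = measures))
  }
  pe <- pearson_with_p(jsd_total, corr_div)
  sp <- spearman_with_p(jsd_total, corr_div)
  list(pearson_r = pe$r, pearson_p = pe$p,
       spearman_r = sp$r, spearman_p = sp$p, measures = measures)
}
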