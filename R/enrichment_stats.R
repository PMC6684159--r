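# Direction counts, signed-rank enrichment, BH FDR, and QQ coordinates
# over the per-disease odds-ratio table.

#' Count effect directions
#'
#' Tallies phenotypes by the sign of the log-odds-ratio, regardless of
#' statistical significance.
#'
#' @param effects data.frame from [batch_transform()] (needs `logor`).
#' @return List with `n_harmful` (logOR > 0), `n_protective` (logOR < 0),
#'   `n_zero`.
#' @export
direction_counts <- function(effects) {
  stopifnot(nrow(effects) > 0L)
  list(n_harmful = sum(effects$logor > 0),
       n_protective = sum(effects$logor < 0),
       n_zero = sum(effects$logor == 0))
}

#' Wilcoxon signed-rank test for directional enrichment
#'
#' Two-sided one-sample Wilcoxon signed-rank test of symmetry about zero,
#' using the normal approximation with continuity correction and
#' average-rank tie handling; exact zeros are dropped. Applied to the
#' signed log-odds-ratios of the analysed diseases.
#'
#' @param values Numeric vector of signed values (e.g. log-odds-ratios),
#'   length >= 10 after zero removal for the normal approximation to be
#'   reasonable.
#' @return Two-sided p-value.
#' @export
signed_rank_test <- function(values) {
  v <- values[values != 0]
  if (length(v) == 0L) stop("signed-rank test undefined: all values are zero")
  stats::wilcox.test(v, mu = 0, alternative = "two.sided",
                     exact = FALSE, correct = TRUE)$p.value
}

#' Benjamini-Hochberg FDR
#'
#' Step-up procedure: with p-values sorted ascending, reject all
#' hypotheses up to the largest i with `p(i) <= q * i / m`. q-values are
#' the monotone-adjusted `p * m / i`.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param q FDR threshold (default 0.05).
#' @return List with `qvalues` (same order as input) and `reject`
#'   (logical).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  qv <- stats::p.adjust(pvals, method = "BH")
  list(qvalues = qv, reject = qv <= q)
}

#' Quantile-quantile plot coordinates for p-values
#'
#' Observed `-log10 p` sorted descending against the expected uniform
#' quantiles `-log10((i - 0.5) / m)` for rank i of m.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return data.frame with columns `expected` and `observed` (both
#'   -log10), one row per p-value, largest deviations first.
#' @export
qq_coordinates <- function(pvals) {
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(pvals)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = sort(-log10(pvals), decreasing = TRUE))
}

#' Enrichment report over a transformed panel
#'
#' Bundles direction counts, the signed-rank enrichment p-value on the
#' log-odds-ratios, BH FDR labelling, and QQ coordinates.
#'
#' @param effects data.frame from [batch_transform()].
#' @param fdr_q FDR threshold for labelling (default 0.05).
#' @return List with `n_harmful`, `n_protective`, `n_zero`, `wilcoxon_p`,
#'   `qvalues`, `fdr_hits` (phenotype ids with q-value below threshold),
#'   `per_phenotype` (table with q-values, hit flags and directions) and
#'   `qq` (coordinates).
#' @export
enrichment_report <- function(effects, fdr_q = 0.05) {
  dirs <- direction_counts(effects)
  fdr <- bh_fdr(effects$p, q = fdr_q)
  per <- data.frame(phenotype_id = effects$phenotype_id,
                    logor = effects$logor, or_ = effects$or_,
                    p = effects$p, qvalue = fdr$qvalues,
                    fdr_hit = fdr$reject,
                    direction = ifelse(effects$logor > 0, "harmful",
                                       ifelse(effects$logor < 0, "protective", "zero")),
                    stringsAsFactors = FALSE)
  c(dirs,
    list(wilcoxon_p = signed_rank_test(effects$logor),
         qvalues = fdr$qvalues,
         fdr_hits = effects$phenotype_id[fdr$reject],
         per_phenotype = per,
         qq = qq_coordinates(effects$p)))
}
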