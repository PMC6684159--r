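# Observed-scale to odds-ratio transformation for binary-trait GWAS effects.
#
# A linear regression of a 0/1 disease indicator on allele dosage yields an
# observed-scale effect beta_obs whose size depends on disease prevalence.
# With marginal prevalence K and effect-allele frequency f, (beta_obs, K, f)
# are sufficient to recover the allelic odds ratio: under Hardy-Weinberg
# genotype frequencies and P(case | dose g) = mu + beta_obs * g with
# mu = K - 2 f beta_obs (so the marginal case rate is K), the probability
# that a random allele copy's carrier is a case is
#   p1 = K + beta_obs (1 - f)   for the effect allele,
#   p0 = K - beta_obs f         for the other allele,
# and the allelic odds ratio is the cross-product ratio of the expected
# allele-by-status 2x2 table: OR = p1 (1 - p0) / (p0 (1 - p1)).

#' Transform an observed-scale effect to a log-odds-ratio
#'
#' Converts the slope of a linear regression of a 0/1 disease outcome on
#' allele dosage into an allelic log-odds-ratio, using the disease
#' prevalence and the effect-allele frequency as the remaining sufficient
#' statistics (expected allelic 2x2 reconstruction under Hardy-Weinberg).
#'
#' @param beta_obs Observed-scale effect (change in case probability per
#'   effect-allele copy). Vectorised.
#' @param eaf Effect-allele frequency, in (0,1).
#' @param prevalence Marginal case fraction K, in (0,1).
#' @return Log-odds-ratio per effect-allele copy; 0 iff `beta_obs` is 0.
#' @export
#' @examples
#' exp(obs_beta_to_logor(0.01, eaf = 0.1, prevalence = 0.05)) # OR ~ 1.217
obs_beta_to_logor <- function(beta_obs, eaf, prevalence) {
  stopifnot(all(eaf > 0 & eaf < 1), all(prevalence > 0 & prevalence < 1))
  p1 <- prevalence + beta_obs * (1 - eaf)
  p0 <- prevalence - beta_obs * eaf
  bad <- p1 <= 0 | p1 >= 1 | p0 <= 0 | p0 >= 1
  if (any(bad)) {
    stop("effect too large for given prevalence/frequency: per-allele case ",
         "probabilities fall outside (0,1) for ", sum(bad), " input(s)")
  }
  # grouped so a null effect (p1 == p0) cancels to exactly zero
  (log(p1) - log(p0)) + (log1p(-p0) - log1p(-p1))
}

#' Delta-method standard error of the log-odds-ratio
#'
#' Propagates the observed-scale SE through the transformation using the
#' analytic derivative
#' `d logOR / d beta_obs = (1-f)/(p1(1-p1)) + f/(p0(1-p0))`,
#' which reduces to `1/(K(1-K))` at `beta_obs = 0`.
#'
#' @inheritParams obs_beta_to_logor
#' @param se_obs Observed-scale standard error, > 0.
#' @return Standard error of the log-odds-ratio.
#' @export
se_logor_delta <- function(beta_obs, se_obs, eaf, prevalence) {
  stopifnot(all(se_obs > 0))
  p1 <- prevalence + beta_obs * (1 - eaf)
  p0 <- prevalence - beta_obs * eaf
  bad <- p1 <= 0 | p1 >= 1 | p0 <= 0 | p0 >= 1
  if (any(bad)) {
    stop("effect too large for given prevalence/frequency: per-allele case ",
         "probabilities fall outside (0,1) for ", sum(bad), " input(s)")
  }
  deriv <- (1 - eaf) / (p1 * (1 - p1)) + eaf / (p0 * (1 - p0))
  se_obs * abs(deriv)
}

#' Association Z score
#'
#' Effect estimate standardised by its standard error; standard normal
#' under the null of no association.
#'
#' @param beta_obs Effect estimate(s).
#' @param se_obs Standard error(s), > 0.
#' @return Z = beta_obs / se_obs.
#' @export
z_score <- function(beta_obs, se_obs) {
  if (any(se_obs <= 0)) stop("se_obs must be positive")
  beta_obs / se_obs
}

#' Transform a panel of oriented associations to the odds-ratio scale
#'
#' Applies [obs_beta_to_logor()], [se_logor_delta()] and [z_score()] to
#' every record, joining prevalence from the phenotype manifest. All
#' records must already be oriented to one target allele. Z scores are
#' computed on the observed scale (beta/SE from the GWAS) and p-values are
#' carried through unchanged.
#'
#' @param assocs data.frame of oriented association records.
#' @param metas Phenotype manifest with `phenotype_id`, `name`, `n_cases`,
#'   `prevalence`.
#' @param on_error `"fail"` stops at the first domain error (effect too
#'   large for the prevalence/frequency); `"collect"` drops offending
#'   records and reports them in the `errors` attribute.
#' @return data.frame with one row per input (order preserved): phenotype
#'   metadata, observed-scale fields, `logor`, `or_`, `se_logor`, `z`, and
#'   `harmful` (`logor > 0`).
#' @export
batch_transform <- function(assocs, metas, on_error = c("fail", "collect")) {
  on_error <- match.arg(on_error)
  if (nrow(assocs) == 0L) {
    out <- data.frame(phenotype_id = character(), name = character(),
                      n_cases = integer(), prevalence = numeric(),
                      beta_obs = numeric(), se_obs = numeric(), p = numeric(),
                      logor = numeric(), or_ = numeric(), se_logor = numeric(),
                      z = numeric(), harmful = logical(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (length(unique(assocs$effect_allele)) != 1L) {
    stop("records are not all oriented to one target allele")
  }
  idx <- match(assocs$phenotype_id, metas$phenotype_id)
  if (anyNA(idx)) {
    stop("no manifest entry for phenotype(s): ",
         paste(unique(assocs$phenotype_id[is.na(idx)]), collapse = ", "))
  }
  K <- metas$prevalence[idx]
  rows <- lapply(seq_len(nrow(assocs)), function(i) {
    tryCatch({
      lo <- obs_beta_to_logor(assocs$beta_obs[i], assocs$eaf[i], K[i])
      se <- se_logor_delta(assocs$beta_obs[i], assocs$se_obs[i],
                           assocs$eaf[i], K[i])
      data.frame(phenotype_id = assocs$phenotype_id[i],
                 name = metas$name[idx[i]],
                 n_cases = metas$n_cases[idx[i]],
                 prevalence = K[i],
                 beta_obs = assocs$beta_obs[i], se_obs = assocs$se_obs[i],
                 p = assocs$p[i],
                 logor = lo, or_ = exp(lo), se_logor = se,
                 z = z_score(assocs$beta_obs[i], assocs$se_obs[i]),
                 harmful = lo > 0, stringsAsFactors = FALSE)
    }, error = function(e) {
      if (on_error == "fail") {
        stop("phenotype ", assocs$phenotype_id[i], ": ", conditionMessage(e),
             call. = FALSE)
      }
      structure(list(phenotype_id = assocs$phenotype_id[i],
                     message = conditionMessage(e)), class = "transform_error")
    })
  })
  errs <- Filter(function(x) inherits(x, "transform_error"), rows)
  ok <- Filter(function(x) !inherits(x, "transform_error"), rows)
  out <- do.call(rbind, ok)
  rownames(out) <- NULL
  if (length(errs)) attr(out, "errors") <- errs
  out
}
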