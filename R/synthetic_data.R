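# Synthetic GWAS extracts with the statistical structure the audit
# assumes, so every pipeline stage runs offline.
#
# The generator works at the summary level: it never simulates
# individual-level genotypes. For a binary phenotype with prevalence K
# analysed by linear regression of the 0/1 outcome on allele dosage in n
# samples, the sampling SE of the observed-scale effect is
#   se_obs = sqrt( K (1 - K) / (n * 2 f (1 - f)) )
# (residual variance ~ K(1-K) for a small effect, dosage variance 2f(1-f)
# under Hardy-Weinberg). True effects enter as Z scores drawn from the
# symmetric three-component mixture; covariate adjustment is not
# simulated (its variance reduction is absorbed into the SE model).

#' Specification for a synthetic phenotype panel
#'
#' Defaults emulate a biobank-scale extract for a single deletion variant:
#' 131 curated binary phenotypes, effect-allele frequency 0.092 (the
#' European frequency of the CCR5 deletion), 361,194 samples, and true
#' effects drawn from the mixture (pi- = 0, pi0 = 0.769, pi+ = 0.231,
#' mu_z = 1.003). Prevalences are uniform on (0.003, 0.25): the lower edge
#' keeps every phenotype above ~1000 cases at this sample size, the upper
#' edge matches common chronic diseases.
#'
#' @param n_phenotypes Number of binary phenotypes.
#' @param prevalence_range Length-2 vector, prevalence bounds in (0,1).
#' @param eaf Target-allele frequency.
#' @param n_samples GWAS sample size.
#' @param mixture A [mixture_params()] object for the true-effect Z scores.
#' @param seed RNG seed.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_phenotypes = 131L,
                       prevalence_range = c(0.003, 0.25),
                       eaf = 0.092,
                       n_samples = 361194L,
                       mixture = mixture_params(0, 0.769, 0.231, 1.003),
                       seed = 1L) {
  stopifnot(n_phenotypes >= 1L, length(prevalence_range) == 2L,
            all(prevalence_range > 0 & prevalence_range < 1),
            prevalence_range[1] <= prevalence_range[2],
            eaf > 0, eaf < 1, n_samples >= 1L,
            inherits(mixture, "mixture_params"))
  structure(list(n_phenotypes = as.integer(n_phenotypes),
                 prevalence_range = prevalence_range, eaf = eaf,
                 n_samples = as.integer(n_samples), mixture = mixture,
                 seed = seed),
            class = "panel_spec")
}

# the deletion-variant id used for all synthetic panels (canonical format)
SYNTH_VARIANT <- "3:46414943_TACAGTCAGTATCAATTCTGGAAGAATTTCCAG_T"

#' Generate a synthetic phenotype panel
#'
#' For each phenotype: draws a prevalence uniformly from the spec range,
#' computes the design-implied observed-scale SE, draws a true Z score
#' from the mixture (component mean -mu_z, 0 or +mu_z plus unit sampling
#' noise), sets `beta_obs = Z * se_obs`, and takes the two-sided normal
#' p-value of Z. Effects are reported for the deletion (alt) allele.
#' Bit-reproducible given the spec (which carries the seed).
#'
#' @param spec A [panel_spec()].
#' @return List with `assocs` (association records in canonical form),
#'   `metas` (phenotype manifest with prevalence), and `truth`
#'   (per-phenotype generating component in {-1, 0, 1}, component mean,
#'   and drawn Z).
#' @export
gen_phenotype_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  n <- spec$n_phenotypes
  mix <- spec$mixture
  with_seed(spec$seed, {
    # integer case counts first, so prevalence is exactly the manifest ratio
    n_cases <- as.integer(round(stats::runif(
      n, spec$prevalence_range[1], spec$prevalence_range[2]) * spec$n_samples))
    K <- n_cases / spec$n_samples
    comp <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                   prob = c(mix$pi_minus, mix$pi_zero, mix$pi_plus))
    true_mean <- comp * mix$mu_z
    z <- stats::rnorm(n, mean = true_mean, sd = 1)
    f <- spec$eaf
    se <- sqrt(K * (1 - K) / (spec$n_samples * 2 * f * (1 - f)))
    beta <- z * se
    p <- 2 * stats::pnorm(-abs(z))

    ids <- sprintf("pheno_%03d", seq_len(n))
    vk <- parse_variant_id(SYNTH_VARIANT)
    assocs <- data.frame(
      variant = vk$id, chrom = vk$chrom, pos = vk$pos, ref = vk$ref,
      alt = vk$alt, effect_allele = vk$alt, eaf = f,
      n = spec$n_samples, beta_obs = beta, se_obs = se, p = p,
      phenotype_id = ids, stringsAsFactors = FALSE)
    metas <- data.frame(
      phenotype_id = ids,
      name = sprintf("synthetic disease %03d", seq_len(n)),
      n_cases = n_cases,
      n_controls = spec$n_samples - n_cases,
      stringsAsFactors = FALSE)
    metas$prevalence <- metas$n_cases / (metas$n_cases + metas$n_controls)
    truth <- data.frame(phenotype_id = ids, component = comp,
                        true_mean = true_mean, z = z,
                        stringsAsFactors = FALSE)
    list(assocs = assocs, metas = metas, truth = truth)
  })
}

#' Generate a sparse SNP-by-phenotype p-value matrix
#'
#' Each entry is "associated" with a per-entry probability (its p drawn
#' uniformly below the association threshold) and null otherwise (p
#' uniform above the threshold). Optional enriched locus sets elevate the
#' rate for their SNPs, emulating the excess pleiotropy of established
#' disease loci. MAFs are uniform on (0.01, 0.5).
#'
#' @param n_snps,n_phen Matrix dimensions.
#' @param base_rate Per-entry association probability in [0, 1].
#' @param enriched_sets Optional named list: disease -> list(`n_snps` =
#'   number of dedicated loci, `rate` = elevated per-entry probability).
#' @param threshold Association p-value threshold (default 5e-4).
#' @param seed RNG seed.
#' @return List with `matrix` (a [pvalue_matrix()]), `locus_sets` (named
#'   list of SNP ids, one per enriched disease), and `rates` (the per-SNP
#'   generating rate).
#' @export
gen_pvalue_matrix <- function(n_snps, n_phen, base_rate,
                              enriched_sets = NULL, threshold = 5e-4,
                              seed = 1L) {
  stopifnot(n_snps >= 1L, n_phen >= 1L, base_rate >= 0, base_rate <= 1)
  with_seed(seed, {
    snp_ids <- sprintf("rs%06d", seq_len(n_snps))
    rates <- rep(base_rate, n_snps)
    locus_sets <- list()
    next_free <- 1L
    for (d in names(enriched_sets)) {
      k <- enriched_sets[[d]]$n_snps
      r <- enriched_sets[[d]]$rate
      stopifnot(r >= 0, r <= 1, next_free + k - 1L <= n_snps)
      idx <- seq(next_free, next_free + k - 1L)
      rates[idx] <- r
      locus_sets[[d]] <- snp_ids[idx]
      next_free <- next_free + k
    }
    assoc <- matrix(stats::runif(n_snps * n_phen) < rates,
                    nrow = n_snps, ncol = n_phen)
    p <- matrix(stats::runif(n_snps * n_phen, min = threshold, max = 1),
                nrow = n_snps, ncol = n_phen)
    p[assoc] <- stats::runif(sum(assoc), min = 0, max = threshold)
    # guard the open-interval lower bound
    p[p == 0] <- .Machine$double.xmin
    maf <- stats::runif(n_snps, 0.01, 0.5)
    list(matrix = pvalue_matrix(p, snp_ids, maf,
                                sprintf("phen_%04d", seq_len(n_phen))),
         locus_sets = locus_sets, rates = rates)
  })
}

#' Generate a synthetic case/control genotype table
#'
#' Controls follow Hardy-Weinberg genotype frequencies at the given
#' allele frequency; case genotype frequencies are tilted by the
#' per-allele odds ratio (`freq_g proportional to HWE_g * OR^g`, the
#' multiplicative allele-dose disease model for a rare disease). Genotypes
#' are drawn multinomially.
#'
#' @param or_true True per-allele odds ratio (> 0).
#' @param eaf Deletion-allele frequency.
#' @param n_cases,n_controls Arm sizes.
#' @param seed RNG seed.
#' @return A [genotype_table()].
#' @export
gen_genotype_table <- function(or_true, eaf, n_cases, n_controls, seed = 1L) {
  stopifnot(or_true > 0, eaf > 0, eaf < 1, n_cases >= 1, n_controls >= 1)
  hwe <- c((1 - eaf)^2, 2 * eaf * (1 - eaf), eaf^2)
  case_freq <- hwe * or_true^(0:2)
  case_freq <- case_freq / sum(case_freq)
  with_seed(seed, {
    cases <- as.integer(stats::rmultinom(1, n_cases, case_freq))
    controls <- as.integer(stats::rmultinom(1, n_controls, hwe))
    genotype_table(cases, controls)
  })
}
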