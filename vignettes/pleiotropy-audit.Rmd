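---
title: "Auditing the pleiotropic footprint of a gene-editing target from GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the pleiotropic footprint of a gene-editing target from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioaudit)
```

## The problem

Before a variant such as the CCR5Δ32 deletion is considered as a
gene-editing target, one wants to know what *else* it does. Biobank-scale
GWAS releases provide, for a single variant, association summary
statistics against hundreds of binary disease phenotypes. `pleioaudit`
turns such an extract into a pleiotropy audit:

1. read and curate the per-phenotype summary statistics, orienting every
   effect to the allele that would be introduced by editing;
2. convert the observed-scale linear-model effects into odds ratios;
3. estimate what fraction of diseases the allele truly harms, protects
   against, or leaves untouched, by fitting a mixture model to the
   association Z scores;
4. summarise directional enrichment and FDR-significant diseases;
5. separately, quantify pleiotropy of any SNP set as phenome-wide
   association counts, and re-analyse small case/control genotype tables
   by allele-dose logistic regression.

Because the underlying biobank data cannot be bundled, the package ships
a synthetic-data generator that reproduces the *statistical structure* of
such an extract, so the entire pipeline is exercised offline.

## From observed-scale effects to odds ratios

Public biobank GWAS of binary traits are often run as linear regressions
of the 0/1 disease indicator $y$ on allele dosage $g$:
$y = \mu + g\,\beta_{obs} + e$. The slope $\beta_{obs}$ is the change in
case probability per allele copy and depends on disease prevalence, which
makes effects incomparable across diseases. For a small genetic effect,
$(\beta_{obs}, K, f)$ — the slope, the marginal prevalence and the
effect-allele frequency — are sufficient to recover the allelic odds
ratio. `obs_beta_to_logor()` reconstructs the expected allele-by-status
2×2 table under Hardy–Weinberg genotype frequencies with
$P(\text{case} \mid g) = \mu + \beta_{obs} g$ and
$\mu = K - 2f\beta_{obs}$ (so the marginal case rate is exactly $K$).
The probability that a random allele copy belongs to a case is then

$$p_1 = K + \beta_{obs}(1-f) \quad\text{(effect allele)},\qquad
  p_0 = K - \beta_{obs} f \quad\text{(other allele)},$$

and the per-allele odds ratio is the cross-product ratio
$\mathrm{OR} = p_1(1-p_0) / \big(p_0(1-p_1)\big)$. This form is exactly
equivalent to collapsing the genotype-level expected table to allele
counts (the test suite verifies agreement to ten significant digits over
randomly drawn valid parameters), it preserves the sign of
$\beta_{obs}$, and in the small-effect limit reduces to
$\log \mathrm{OR} \approx \beta_{obs} / \big(K(1-K)\big)$. Standard
errors are propagated by the delta method with the analytic derivative
$(1-f)/\big(p_1(1-p_1)\big) + f/\big(p_0(1-p_0)\big)$. Effects so large
that $p_1$ or $p_0$ leaves $(0,1)$ are a domain error — the transformation
is for the small-effect regime it assumes.

Two carried-through conventions: Z scores are the observed-scale
$\beta_{obs}/\mathrm{se}_{obs}$ (not recomputed after transformation),
and GWAS p-values pass through unchanged. Prevalence is always the
marginal case fraction from the phenotype manifest, never re-estimated.

## The three-component Z-score mixture

Raw sign counts overstate how many diseases a variant truly affects,
because most per-disease estimates are statistically null. The audit
therefore models the panel of Z scores as

$$z_i \sim \pi_- N(-\mu_Z, 1) + \pi_0 N(0, 1) + \pi_+ N(+\mu_Z, 1),$$

with unit component variances (the sampling variance of a Z score under
the null) and a single shared shift $\mu_Z \ge 0$. $\pi_+$ is the
proportion of truly harmful effects of the target allele; $\pi_+ \times
m$ over $m$ phenotypes is the expected number of diseases with elevated
risk (`expected_affected()`). The likelihood treats diseases as
independent — comorbidity and shared controls are not modelled, which
will understate uncertainty on real panels.

`fit_mixture()` maximises the likelihood by EM with the component
variances fixed at 1: responsibilities give the weight updates, and the
shift update is the responsibility-weighted mean
$\hat\mu_Z = (\sum_i r_{+i} z_i - \sum_i r_{-i} z_i) / \sum_i (r_{+i} +
r_{-i})$, floored at $10^{-6}$. Because the surface is multimodal, the
fit is the best of 20 starts: a moment-based start (tail fractions and
the mean of $|z|>1$), the pure-null model, and randomised
simplex/uniform-shift starts. Including the null model as a start
guarantees the attained log-likelihood never falls below the
one-component $N(0,1)$ fit. All log-density sums use log-sum-exp;
weights within $10^{-6}$ of the simplex boundary are snapped to it for
reporting. Every stochastic entry point takes an explicit seed and
restores the caller's RNG state.

### Identifiability, honestly

Two features of this model deserve a caution that the simulations in the
test suite and acceptance script make concrete.

First, at $\mu_Z = 0$ the three components coincide and the weights are
unidentifiable; near-zero fitted shifts therefore carry essentially
arbitrary weight splits. On pure-null data the fitted model is
*distributionally* equivalent to $N(0,1)$ — its first two moments match
within sampling noise and its likelihood gain over the null model is
statistically nil — but the reported $\hat\pi_0$ alone should not be
read as "the null proportion" when $\hat\mu_Z$ is tiny. The tests assert
exactly the distributional form of this statement.

Second, with a shift as weak as $\mu_Z \approx 1$ and a panel of 131
diseases, the *weights* of the mixture are only weakly identified even
at the true parameters. In repeated simulation from
$(\pi_-, \pi_0, \pi_+, \mu_Z) = (0, 0.769, 0.231, 1.003)$, a
substantial minority of replicates have their global maximum-likelihood
solution at a near-single-Gaussian mode ($\hat\pi_+ \to 1$ with a small
shift) rather than near the generating values, so the ML estimate of
$\pi_+$ is strongly dispersed and upward-biased on average, while the
mean shift $\hat\mu_Z$ is recovered well on average. This is a property
of the likelihood itself — warm-starting the optimiser at the truth
converges to the same solutions — and it is why the acceptance study
(`scripts/acceptance.R`) reports the simulation means of both
$\hat\pi_+$ and $\hat\mu_Z$ rather than asserting that either equals its
generating value. A point estimate of $\pi_+$ from a single 131-disease
panel should always be read together with its bootstrap SE, which is
wide.

### Bootstrap inference

The printed uncertainty comes from a nonparametric bootstrap
(`bootstrap_inference()`, default $B = 1000$): resample the Z vector
with replacement, refit warm-started at the point estimate plus a few
random restarts, and take the standard deviation of each parameter
across replicates. P-values are two-sided Wald-style,
$2\Phi(-|\hat\theta|/\widehat{se})$, with the convention that a
parameter snapped to 0 reports $p = 1$. A Wald summary is used rather
than empirical tail proportions because meaningful tail p-values far
below $1/B$ are otherwise impossible; it is a convention, not a claim of
exactness, and replicate draws are returned so users can form percentile
intervals instead. Replicates are seed-deterministic, and SEs shrink at
the expected $1/\sqrt{n}$ rate in simulation.

## Enrichment summaries

`direction_counts()` tallies harmful/protective signs regardless of
significance. `signed_rank_test()` applies the one-sample Wilcoxon
signed-rank test (two-sided, normal approximation with continuity
correction, zeros dropped, ties averaged) to the signed log-odds-ratios;
the sign pattern is identical for ORs, log-ORs and Z scores but the
magnitudes — hence the p-value — differ, and signed log-ORs are the
scale on which "symmetry about zero" is the natural null. Note the
normal approximation is trustworthy at panel scale ($n \gtrsim 15$);
against exact enumeration it is accurate to a few percent centrally and
poor in the extreme tails at very small $n$, so the package does not
use it there in anger. `bh_fdr()` is the Benjamini–Hochberg step-up at
$q = 0.05$ by default, over exactly the disease set analysed (an
external association, e.g. an HIV result from a separate cohort, may be
appended before labelling). `qq_coordinates()` returns $-\log_{10}$
observed versus expected $(i-0.5)/m$ quantiles for plotting.

## Contingency re-analysis and pleiotropy counts

`allelic_logistic_or()` fits case status on deletion-allele dose
$g \in \{0,1,2\}$ by grouped logistic regression, matching per-allele
("per substitution") OR language; an empty genotype class is tolerated,
and complete separation is surfaced as an error rather than silently
penalised (no Firth correction by default). The allele-counting 2×2
collapse is provided as a cross-check path.

`count_associations()` counts, per SNP, phenotypes with $p$ strictly
below $5\times10^{-4}$; missing entries never count.
`background_summary()` and `locus_set_summary()` give the genome and
per-disease means (SE = sample SD / $\sqrt{\text{set size}}$, undefined
and flagged for singleton sets), and `enrichment_flag()` applies the
strict mean-above-background comparison. Published genome-background
values of this metric (on the order of 5–6 associations per SNP across
a full biobank phenome) require the complete release and are not
reproducible at desk scale; the counter is instead validated by
brute-force oracle equivalence and by its binomial calibration on
synthetic matrices, where a per-entry association rate $r$ must give
mean counts near $r \times$ (number of phenotypes).

## What the synthetic generator does and does not emulate

`gen_phenotype_panel()` works at the summary level. Its defaults are the
study conditions the pipeline is aimed at: 131 binary phenotypes,
effect-allele frequency 0.092 (the European frequency of the CCR5
deletion), 361,194 samples, true effects from the mixture
$(0, 0.769, 0.231, 1.003)$, and prevalences uniform on $(0.003, 0.25)$
— the lower edge keeps every phenotype above the 1000-case curation
threshold at this sample size, the upper edge matches common chronic
disease. The observed-scale SE follows the design formula
$\sqrt{K(1-K) / (n \cdot 2f(1-f))}$ (unit-variance residual
approximation with Hardy–Weinberg dosage variance); covariate
adjustment, relatedness, case overlap between phenotypes, imputation
uncertainty and LD are *not* simulated. Null effects split signs evenly,
which is why raw harmful-direction counts on a default panel exceed
$\pi_+ \times 131$ — the same distinction the mixture is there to make.
Passing tests on this generator therefore validate the estimators'
internal correctness and calibration under the stated sampling model,
not robustness to the correlation structure of real biobank panels.

`gen_pvalue_matrix()` plants per-entry associations with controllable
rates (uniform p below the threshold when associated, uniform above
otherwise) and optional enriched locus sets; `gen_genotype_table()`
draws control genotypes from HWE and tilts case genotype frequencies by
$\mathrm{OR}^g$.

## Numerical and design choices

* **Curation boundary** is inclusive: "at least 1000 cases" keeps
  exactly the phenotypes with $n_{cases} \ge 1000$.
* **Association threshold** for pleiotropy counts is strict
  ($p < 5\times10^{-4}$); a locus is operationalised as its reported
  lead SNP, with no LD clumping.
* **NA policy** in summary-stat ingest is skip-and-log (public releases
  contain sporadic NA rows); frequencies outside $(0,1)$ and
  non-positive SEs are hard errors.
* **Variant ids** are fixed as `chrom:pos_ref_alt` (1-based, GRCh37),
  the convention of the source release; the colon form is accepted and
  normalised.
* **Mixture tolerances**: EM stops when the log-likelihood improves by
  less than $10^{-8}$ (capped at 1000 iterations); $\mu_Z$ floor
  $10^{-6}$; boundary snap $10^{-6}$.
* **Run reproducibility**: every report carries the seed and an MD5
  hash of the analytical configuration (paths excluded, so relocated
  copies of the same analysis hash identically); re-running a
  subcommand with the same config reproduces byte-identical payloads.

## Problem sizes used in validation

The shipped validation uses simulation sizes chosen to characterise the
estimators at the scale they are meant for: 1000 random parameter draws
for the transformation oracle; 200 replicates of 131 Z scores for the
mixture recovery study; bootstrap SE studies at $n \in \{131, 524,
2096\}$ with 120–150 replicates; 1000 random p-vectors for the BH
oracle; and synthetic p-value matrices up to $2000 \times 1400$.

## Known limitations

* Independence across diseases is assumed throughout; bootstrap SEs and
  the signed-rank p are anti-conservative under positive dependence.
* The mixture's weight estimates at weak separation are dispersed and
  biased (see above); trust the shift and the bootstrap spread more
  than the point weights on small panels.
* The scale transformation assumes the marginal-prevalence sampling
  model; covariate-adjusted GWAS effects are treated as if marginal.
* No liability-scale conversion, no LD-aware locus handling, no
  model-selection over the number of mixture components.
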