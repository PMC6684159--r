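# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the code paths they check.

# Expected allelic 2x2 reconstruction: build the genotype-level expected
# table under HWE with P(case | dose g) = mu + b*g, mu = K - 2*f*b, collapse
# genotypes to allele counts, take the cross-product ratio.
oracle_logor_hwe <- function(b, f, K) {
  g_freq <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  mu <- K - 2 * f * b
  p_case <- mu + b * (0:2)
  stopifnot(all(p_case > 0 & p_case < 1))
  case_del <- sum(g_freq * p_case * c(0, 1, 2))
  case_other <- sum(g_freq * p_case * c(2, 1, 0))
  ctrl_del <- sum(g_freq * (1 - p_case) * c(0, 1, 2))
  ctrl_other <- sum(g_freq * (1 - p_case) * c(2, 1, 0))
  log((case_del * ctrl_other) / (case_other * ctrl_del))
}

# random valid (b, f, K) triples for the transformation domain
draw_valid_transform_params <- function(n, seed) {
  with_seed(seed, {
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < n) {
      K <- runif(n, 0.005, 0.4)
      f <- runif(n, 0.01, 0.99)
      b <- runif(n, -1, 1) * 0.4 * pmin(K, 1 - K)
      mu <- K - 2 * f * b
      ok <- mu > 0 & mu + 2 * b > 0 & mu < 1 & mu + 2 * b < 1 &
        K + b * (1 - f) > 0 & K + b * (1 - f) < 1 &
        K - b * f > 0 & K - b * f < 1
      out <- rbind(out, cbind(b, f, K)[ok, , drop = FALSE])
    }
    unname(out[seq_len(n), , drop = FALSE])
  })
}

# "effectively null" mixture: the fitted density's first two moments match
# N(0,1) within the sampling noise of n observations (4 SEs of the sample
# mean and variance); covers both pi0 ~ 1 and the collapsed-shift ridge
is_effectively_null <- function(params, n) {
  shift <- (params$pi_plus - params$pi_minus) * params$mu_z
  extra_var <- (params$pi_plus + params$pi_minus) * params$mu_z^2
  abs(shift) < 4 / sqrt(n) && extra_var < 4 * sqrt(2 / n)
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank_exact <- function(v) {
  v <- v[v != 0]
  n <- length(v)
  stopifnot(n <= 14)
  r <- rank(abs(v))
  V <- sum(r[v > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Vs <= V), mean(Vs >= V)))
}

# brute-force BH step-up: scan all cutoffs
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= q * i / m) k <- i
  reject <- rep(FALSE, m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  reject
}

# draw Z scores from the three-component mixture
draw_mixture_z <- function(n, pi_minus, pi_zero, pi_plus, mu, seed) {
  with_seed(seed, {
    comp <- sample(c(-1, 0, 1), n, replace = TRUE,
                   prob = c(pi_minus, pi_zero, pi_plus))
    rnorm(n, mean = comp * mu, sd = 1)
  })
}

# small well-formed summary-stat file in the default (Neale-style) dialect
write_neale_fixture <- function(path, n = 3, na_beta_rows = integer(0)) {
  df <- data.frame(
    variant = rep("3:46414943_TACAGTCAGTATCAATTCTGGAAGAATTTCCAG_T", n),
    minor_allele = rep("T", n),
    minor_AF = rep(0.092, n),
    n_complete_samples = rep(361194L, n),
    beta = round(seq(-0.001, 0.001, length.out = n), 6),
    se = rep(4e-4, n),
    pval = round(seq(0.01, 0.9, length.out = n), 4),
    phenotype_id = sprintf("pheno_%03d", seq_len(n)),
    stringsAsFactors = FALSE)
  df$beta[na_beta_rows] <- NA
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

manifest_fixture <- function(ids, n_cases, n_total = 361194L) {
  data.frame(phenotype_id = ids,
             name = paste("disease", ids),
             n_cases = as.integer(n_cases),
             n_controls = as.integer(n_total - n_cases),
             prevalence = n_cases / n_total,
             stringsAsFactors = FALSE)
}
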