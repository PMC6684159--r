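test_that("a null observed-scale effect maps to odds ratio 1", {
  lo <- obs_beta_to_logor(0, eaf = 0.1, prevalence = 0.05)
  expect_identical(lo, 0)
  expect_identical(exp(lo), 1)
})

test_that("allele flip (b, f) -> (-b, 1-f) negates the log-odds-ratio exactly", {
  pars <- draw_valid_transform_params(50, seed = 21)
  lo1 <- obs_beta_to_logor(pars[, 1], pars[, 2], pars[, 3])
  lo2 <- obs_beta_to_logor(-pars[, 1], 1 - pars[, 2], pars[, 3])
  expect_equal(lo2, -lo1, tolerance = 1e-14)
})

test_that("the transformation agrees with the HWE 2x2 reconstruction oracle", {
  # worked value: beta_obs = 0.01, f = 0.1, K = 0.05 gives OR ~ 1.217
  expect_equal(exp(obs_beta_to_logor(0.01, 0.1, 0.05)), 1.216877,
               tolerance = 1e-6)
  pars <- draw_valid_transform_params(1000, seed = 42)
  for (i in seq_len(nrow(pars))) {
    got <- obs_beta_to_logor(pars[i, 1], pars[i, 2], pars[i, 3])
    want <- oracle_logor_hwe(pars[i, 1], pars[i, 2], pars[i, 3])
    expect_equal(got, want, tolerance = 1e-11)
  }
})

test_that("effects too large for the prevalence/frequency raise a domain error", {
  expect_error(obs_beta_to_logor(0.2, 0.5, 0.05), "too large")
  expect_error(se_logor_delta(0.2, 0.01, 0.5, 0.05), "too large")
})

test_that("the small-effect limit is beta_obs / (K (1 - K))", {
  pars <- draw_valid_transform_params(200, seed = 7)
  K <- pars[, 3]; f <- pars[, 2]
  b <- 0.009 * K * (1 - K) * with_seed(8, sample(c(-1, 1), 200, TRUE))
  lo <- obs_beta_to_logor(b, f, K)
  expect_true(all(abs(lo - b / (K * (1 - K))) / abs(lo) < 0.01))
})

test_that("logOR is sign-preserving and strictly increasing in beta_obs", {
  K <- 0.07; f <- 0.2
  b <- seq(-0.02, 0.02, length.out = 41)
  lo <- obs_beta_to_logor(b, f, K)
  expect_equal(sign(lo), sign(b))
  expect_true(all(diff(lo) > 0))
})

test_that("the delta-method SE has the closed-form null limit", {
  # at beta_obs = 0 the derivative is 1 / (K (1 - K))
  expect_equal(se_logor_delta(0, 0.1, 0.3, 0.05), 0.1 / (0.05 * 0.95))
  expect_equal(se_logor_delta(0, 2, 0.25, 0.5), 8) # K = 0.5 -> 4 * se_obs
  # matches numerical differentiation away from zero
  b <- 0.004; f <- 0.15; K <- 0.06; h <- 1e-7
  num <- (obs_beta_to_logor(b + h, f, K) - obs_beta_to_logor(b - h, f, K)) / (2 * h)
  expect_equal(se_logor_delta(b, 0.3, f, K), 0.3 * abs(num), tolerance = 1e-6)
  # invariant under the allele flip
  expect_equal(se_logor_delta(b, 0.3, f, K),
               se_logor_delta(-b, 0.3, 1 - f, K))
})

test_that("z_score is the effect standardised by its SE", {
  expect_equal(z_score(0.2, 0.1), 2)
  expect_equal(z_score(0, 5), 0)
  expect_equal(z_score(-0.3, 0.1), -3)
  expect_error(z_score(0.1, 0), "positive")
})

test_that("batch_transform handles the empty panel and composes per record", {
  metas <- manifest_fixture("p1", 18060L)
  empty <- batch_transform(data.frame(), metas)
  expect_equal(nrow(empty), 0L)

  one <- data.frame(variant = "1:1_A_G", effect_allele = "G", eaf = 0.092,
                    n = 361194, beta_obs = 0.002, se_obs = 0.001, p = 0.04,
                    phenotype_id = "p1", stringsAsFactors = FALSE)
  eff <- batch_transform(one, metas)
  expect_equal(eff$logor, obs_beta_to_logor(0.002, 0.092, metas$prevalence))
  expect_equal(eff$or_, exp(eff$logor))
  expect_equal(eff$z, 2)
  expect_equal(eff$p, 0.04)
  expect_true(eff$harmful)
})

test_that("on a synthetic panel the harmful count equals the positive-beta count", {
  panel <- gen_phenotype_panel(panel_spec(seed = 5))
  eff <- batch_transform(panel$assocs, panel$metas)
  expect_equal(nrow(eff), 131L)
  expect_equal(sum(eff$harmful), sum(panel$assocs$beta_obs > 0))
  expect_equal(sign(eff$logor), sign(eff$beta_obs))
})

test_that("batch_transform surfaces per-record domain errors by policy", {
  metas <- manifest_fixture(c("p1", "p2"), c(3612L, 18060L))
  two <- data.frame(variant = "1:1_A_G", effect_allele = "G", eaf = 0.5,
                    n = 1000, beta_obs = c(0.5, 0.001), se_obs = 0.01,
                    p = 0.5, phenotype_id = c("p1", "p2"),
                    stringsAsFactors = FALSE)
  expect_error(batch_transform(two, metas), "p1")
  collected <- batch_transform(two, metas, on_error = "collect")
  expect_equal(nrow(collected), 1L)
  expect_equal(collected$phenotype_id, "p2")
  expect_length(attr(collected, "errors"), 1L)
})
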