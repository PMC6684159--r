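test_that("mixture parameters are validated", {
  p <- mixture_params(0.2, 0.5, 0.3, 1)
  expect_s3_class(p, "mixture_params")
  expect_error(mixture_params(0.5, 0.5, 0.5, 1), "sum to 1")
  expect_error(mixture_params(-0.1, 0.8, 0.3, 1), "nonnegative")
  expect_error(mixture_params(0, 1, 0, -0.5), "mu_z")
})

test_that("the log-likelihood matches direct density summation", {
  # single standard-normal point under the pure-null mixture
  expect_equal(mixture_loglik(mixture_params(0, 1, 0, 1), 0),
               -0.918938533205, tolerance = 1e-10)
  # frozen from an independent three-term density sum:
  # sum(log(0.2 phi(z+1) + 0.5 phi(z) + 0.3 phi(z-1))) at z = (0.5, -1.2, 2.1)
  expect_equal(mixture_loglik(mixture_params(0.2, 0.5, 0.3, 1),
                              c(0.5, -1.2, 2.1)),
               -5.291818038514, tolerance = 1e-10)
  expect_error(mixture_loglik(mixture_params(0, 1, 0, 1), numeric(0)), "nonempty")
  expect_error(mixture_loglik(mixture_params(0, 1, 0, 1), c(1, NA)), "finite")
})

test_that("the log-likelihood is reflection symmetric", {
  z <- draw_mixture_z(60, 0.1, 0.6, 0.3, 1.4, seed = 3)
  p <- mixture_params(0.25, 0.45, 0.3, 1.2)
  p_swapped <- mixture_params(0.3, 0.45, 0.25, 1.2)
  expect_equal(mixture_loglik(p, z), mixture_loglik(p_swapped, -z),
               tolerance = 1e-12)
})

test_that("zero-weight components are excluded exactly", {
  z <- c(-0.4, 1.1)
  expect_equal(mixture_loglik(mixture_params(0, 1, 0, 3), z),
               sum(stats::dnorm(z, log = TRUE)), tolerance = 1e-12)
})

test_that("a single shifted component is recovered from well-separated data", {
  z <- with_seed(9, rnorm(2000, mean = 3))
  f <- fit_mixture(z, seed = 1)
  expect_gte(f$params$pi_plus, 0.95)
  expect_lt(abs(f$params$mu_z - 3), 0.1)
})

test_that("null data yield a fit equivalent to N(0,1)", {
  # On pure-null data the mu ridge makes the weights unidentifiable: the
  # fitted density must match N(0,1) in its first two moments, and the
  # likelihood gain over N(0,1) must be statistically nil.
  for (s in 1:3) {
    z <- with_seed(100 + s, rnorm(2000))
    f <- fit_mixture(z, seed = 1)
    expect_true(is_effectively_null(f$params, length(z)))
    expect_lt(f$loglik - f$loglik_null, qchisq(0.99, df = 3) / 2)
  }
})

test_that("the fitted likelihood always dominates the null model", {
  for (s in 1:5) {
    z <- draw_mixture_z(131, 0, 0.769, 0.231, 1.003, seed = 200 + s)
    f <- fit_mixture(z, n_restarts = 10, seed = s)
    expect_gte(f$loglik, f$loglik_null)
    w <- with(f$params, c(pi_minus, pi_zero, pi_plus))
    expect_lt(abs(sum(w) - 1), 1e-12)
    expect_gte(f$params$mu_z, 0)
  }
})

test_that("fitting -z swaps the protective and harmful weights", {
  z <- draw_mixture_z(400, 0.05, 0.55, 0.4, 2.2, seed = 17)
  f1 <- fit_mixture(z, n_restarts = 15, seed = 4)
  f2 <- fit_mixture(-z, n_restarts = 15, seed = 4)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-4)
  expect_equal(f1$params$pi_plus, f2$params$pi_minus, tolerance = 1e-3)
  expect_equal(f1$params$pi_minus, f2$params$pi_plus, tolerance = 1e-3)
  expect_equal(f1$params$mu_z, f2$params$mu_z, tolerance = 1e-3)
})

test_that("fits are deterministic given the seed", {
  z <- draw_mixture_z(131, 0, 0.769, 0.231, 1.003, seed = 77)
  f1 <- fit_mixture(z, seed = 12)
  f2 <- fit_mixture(z, seed = 12)
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$loglik, f2$loglik)
})

test_that("bootstrap inference is reproducible and reports p = 1 at zero estimates", {
  z <- draw_mixture_z(131, 0, 0.769, 0.231, 1.003, seed = 31)
  f <- fit_mixture(z, n_restarts = 10, seed = 2)
  b1 <- bootstrap_inference(z, f, n_boot = 120, seed = 5)
  b2 <- bootstrap_inference(z, f, n_boot = 120, seed = 5)
  expect_identical(b1$boot_se, b2$boot_se)
  expect_identical(b1$boot_p, b2$boot_p)
  expect_true(all(b1$boot_p >= 0 & b1$boot_p <= 1))
  expect_error(bootstrap_inference(z, f, n_boot = 50, seed = 1), "at least 100")

  # a component absent from the data snaps to 0 and reports p = 1
  z_pos <- with_seed(44, rnorm(200, mean = 3))
  f_pos <- fit_mixture(z_pos, n_restarts = 10, seed = 2)
  expect_identical(f_pos$params$pi_minus, 0)
  b_pos <- bootstrap_inference(z_pos, f_pos, n_boot = 120, seed = 5)
  expect_identical(unname(b_pos$boot_p["pi_minus"]), 1)
})

test_that("the bootstrap SE of mu shrinks roughly like 1/sqrt(n)", {
  ses <- sapply(c(131, 524, 2096), function(n) {
    z <- draw_mixture_z(n, 0.1, 0.6, 0.3, 2, seed = 1000 + n)
    f <- fit_mixture(z, n_restarts = 10, seed = 3)
    bootstrap_inference(z, f, n_boot = 150, seed = 3)$boot_se["mu_z"]
  })
  expect_true(all(diff(ses) < 0))             # monotone shrinkage
  expect_gt(ses[1] / ses[3], 2)               # 16x n gives ~4x shrinkage
})

test_that("the harmful-component weight translates into an expected disease count", {
  ea <- expected_affected(mixture_params(0, 0.769, 0.231, 1.003), 131)
  expect_equal(ea$expected, 30.261)
  expect_identical(ea$rounded, 30L)
  expect_identical(expected_affected(mixture_params(0.3, 0.7, 0, 1), 131)$expected, 0)
  expect_identical(expected_affected(mixture_params(0, 0, 1, 1), 10)$rounded, 10L)
})
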