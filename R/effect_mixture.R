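# Symmetric three-component Gaussian mixture for association Z scores.
#
# Z scores across a panel of diseases are modelled as draws from
#   pi_minus N(-mu_z, 1) + pi_zero N(0, 1) + pi_plus N(+mu_z, 1)
# with unit component variances (the sampling variance of a Z score) and a
# shared nonnegative mean shift. pi_plus estimates the proportion of
# phenotypes with truly harmful effects of the target allele, pi_minus the
# protective proportion, pi_zero the nulls. The likelihood treats the Z
# scores as independent; no between-disease correlation is modelled.

MU_FLOOR <- 1e-6        # keeps the fit off the non-identifiable mu_z = 0 ridge
BOUNDARY_SNAP <- 1e-6   # weights this close to the simplex edge report as 0/1

#' Construct mixture parameters
#'
#' @param pi_minus,pi_zero,pi_plus Component weights (nonnegative, summing
#'   to 1 within 1e-12): protective, null, harmful.
#' @param mu_z Nonnegative mean shift of the two non-null components, in
#'   Z-score units.
#' @return A `mixture_params` object (named list).
#' @export
mixture_params <- function(pi_minus, pi_zero, pi_plus, mu_z) {
  w <- c(pi_minus, pi_zero, pi_plus)
  if (any(!is.finite(w)) || any(w < 0)) stop("mixture weights must be finite and nonnegative")
  if (abs(sum(w) - 1) > 1e-12) stop("mixture weights must sum to 1 (got ", sum(w), ")")
  if (!is.finite(mu_z) || mu_z < 0) stop("mu_z must be finite and nonnegative")
  structure(list(pi_minus = pi_minus, pi_zero = pi_zero, pi_plus = pi_plus,
                 mu_z = mu_z), class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("mixture: pi- = %.3f, pi0 = %.3f, pi+ = %.3f, mu_z = %.3f\n",
              x$pi_minus, x$pi_zero, x$pi_plus, x$mu_z))
  invisible(x)
}

# n x 3 matrix of log(pi_k) + log phi_k(z_i); -Inf columns for zero weights
.component_logdens <- function(params, z) {
  lw <- log(c(params$pi_minus, params$pi_zero, params$pi_plus))
  cbind(lw[1] + stats::dnorm(z, -params$mu_z, 1, log = TRUE),
        lw[2] + stats::dnorm(z, 0, 1, log = TRUE),
        lw[3] + stats::dnorm(z, params$mu_z, 1, log = TRUE))
}

#' Mixture log-likelihood
#'
#' Sum over observations of the log mixture density, computed by
#' log-sum-exp for numerical stability. Zero-weight components contribute
#' nothing (their `log(0)` terms are excluded exactly).
#'
#' @param params A [mixture_params()] object.
#' @param z Numeric vector of Z scores (nonempty, finite).
#' @return The log-likelihood (scalar).
#' @export
mixture_loglik <- function(params, z) {
  if (!inherits(params, "mixture_params")) {
    params <- do.call(mixture_params, as.list(params))
  }
  if (length(z) == 0L) stop("z must be nonempty")
  if (any(!is.finite(z))) stop("z must be finite")
  ld <- .component_logdens(params, z)
  m <- pmax(ld[, 1], ld[, 2], ld[, 3])
  sum(m + log(rowSums(exp(ld - m))))
}

# Posterior component responsibilities (n x 3, rows sum to 1)
.responsibilities <- function(params, z) {
  ld <- .component_logdens(params, z)
  m <- pmax(ld[, 1], ld[, 2], ld[, 3])
  r <- exp(ld - m)
  r / rowSums(r)
}

# One EM run from a given start; component variances fixed at 1.
# mu update maximises the expected complete-data log-likelihood:
#   mu = (sum r+ z - sum r- z) / (sum r+ + sum r-), floored at mu_floor.
# Inner loop works on a raw parameter vector to keep iterations cheap.
.em_fit <- function(z, start, tol = 1e-8, max_iter = 1000L, mu_floor = MU_FLOOR) {
  w <- c(start$pi_minus, start$pi_zero, start$pi_plus)
  mu <- start$mu_z
  lphi <- -0.5 * log(2 * pi)
  logdens <- function(w, mu) {
    cbind(log(w[1]) + lphi - 0.5 * (z + mu)^2,
          log(w[2]) + lphi - 0.5 * z^2,
          log(w[3]) + lphi - 0.5 * (z - mu)^2)
  }
  ld <- logdens(w, mu)
  m <- pmax(ld[, 1], ld[, 2], ld[, 3])
  e <- exp(ld - m)
  s <- rowSums(e)
  ll <- sum(m + log(s))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    r <- e / s
    cs <- colSums(r)
    w <- cs / sum(cs)
    denom <- cs[1] + cs[3]
    if (denom > 0) {
      mu <- max(mu_floor, (sum(r[, 3] * z) - sum(r[, 1] * z)) / denom)
    }
    ld <- logdens(w, mu)
    m <- pmax(ld[, 1], ld[, 2], ld[, 3])
    e <- exp(ld - m)
    s <- rowSums(e)
    ll_new <- sum(m + log(s))
    if (is.finite(ll_new) && abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  list(params = mixture_params(w[1], w[2], w[3], mu),
       loglik = ll, converged = converged, iter = iter)
}

# Moment-based starting point: tail fractions seed the non-null weights,
# the mean magnitude of |z| > 1 seeds the shift.
.moment_start <- function(z) {
  p_plus <- min(max(mean(z > 1), 0.05), 0.9)
  p_minus <- min(max(mean(z < -1), 0.05), 0.9)
  s <- p_plus + p_minus
  if (s > 0.9) { p_plus <- p_plus * 0.9 / s; p_minus <- p_minus * 0.9 / s }
  mu <- mean(abs(z)[abs(z) > 1])
  if (!is.finite(mu)) mu <- 1
  mixture_params(p_minus, 1 - p_plus - p_minus, p_plus, max(mu, 0.5))
}

.snap_boundary <- function(params, eps = BOUNDARY_SNAP) {
  w <- c(params$pi_minus, params$pi_zero, params$pi_plus)
  w[w < eps] <- 0
  w <- w / sum(w)
  mixture_params(w[1], w[2], w[3], params$mu_z)
}

#' Fit the three-component mixture by maximum likelihood
#'
#' Runs EM (component variances fixed at 1, weights on the simplex,
#' `mu_z >= 1e-6`) from multiple starting points — a moment-based start,
#' the pure-null start, and randomised starts — and returns the solution
#' with the highest log-likelihood. Deterministic given `seed`. Weight
#' estimates within 1e-6 of the simplex boundary are snapped to the
#' boundary for reporting.
#'
#' @param z Numeric vector of Z scores, length >= 4, all finite.
#' @param n_restarts Number of starting points (default 20; includes the
#'   moment and null starts).
#' @param seed RNG seed for the randomised starts.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @return A `mixture_fit` object: `params`, `loglik`, `n`, `n_restarts`,
#'   `converged`, `seed`, and `posterior` (n x 3 responsibilities at the
#'   optimum, columns protective/null/harmful).
#' @export
fit_mixture <- function(z, n_restarts = 20L, seed = 1L, tol = 1e-8) {
  if (length(z) < 4L) stop("need at least 4 Z scores to fit the mixture")
  if (any(!is.finite(z))) stop("z must be finite")
  runs <- with_seed(seed, {
    starts <- list(.moment_start(z),
                   mixture_params(0, 1, 0, 1))
    n_random <- max(0L, as.integer(n_restarts) - length(starts))
    for (i in seq_len(n_random)) {
      w <- stats::rexp(3)
      w <- w / sum(w)
      starts[[length(starts) + 1L]] <-
        mixture_params(w[1], w[2], w[3], stats::runif(1, 0.2, 4))
    }
    lapply(starts, function(s) .em_fit(z, s, tol = tol))
  })
  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  if (all(!is.finite(lls))) stop("all mixture restarts failed to converge")
  best <- runs[[which.max(lls)]]
  params <- .snap_boundary(best$params)
  structure(list(params = params,
                 loglik = mixture_loglik(params, z),
                 loglik_null = mixture_loglik(mixture_params(0, 1, 0, 1), z),
                 n = length(z),
                 n_restarts = as.integer(n_restarts),
                 converged = best$converged,
                 seed = seed,
                 posterior = .responsibilities(params, z)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("three-component Z-score mixture fit (n = %d)\n", x$n))
  print(x$params)
  cat(sprintf("loglik = %.4f, converged = %s, restarts = %d, seed = %s\n",
              x$loglik, x$converged, x$n_restarts, format(x$seed)))
  if (!is.null(x$boot_se)) {
    cat("bootstrap SEs:", paste(sprintf("%s = %.4f", names(x$boot_se), x$boot_se),
                                collapse = ", "), "\n")
  }
  invisible(x)
}

#' Nonparametric bootstrap inference for the mixture parameters
#'
#' Resamples the Z-score vector with replacement (same n), refits each
#' replicate by EM warm-started at the point estimate (plus a few random
#' restarts to escape replicate-specific local optima), and summarises the
#' replicate parameter draws. Standard errors are the standard deviations
#' across replicates; p-values are two-sided Wald-style normal
#' approximations `2 * pnorm(-|theta| / SE)` for the null that the
#' parameter is zero, reported as 1 when the point estimate is exactly 0.
#'
#' @param z Numeric vector of Z scores the fit was computed on.
#' @param fit A `mixture_fit` from [fit_mixture()].
#' @param n_boot Number of bootstrap replicates (>= 100; default 1000).
#' @param seed RNG seed.
#' @param n_restarts Random restarts per replicate in addition to the warm
#'   start.
#' @param max_fail_frac Maximum tolerated fraction of failed replicate
#'   fits before erroring (default 0.05).
#' @return A list with `boot_se` and `boot_p` (named over `pi_minus`,
#'   `pi_zero`, `pi_plus`, `mu_z`), `n_boot`, `n_failed`, `seed`, and the
#'   replicate `draws` matrix.
#' @export
bootstrap_inference <- function(z, fit, n_boot = 1000L, seed = 1L,
                                n_restarts = 3L, max_fail_frac = 0.05) {
  if (n_boot < 100L) stop("n_boot must be at least 100")
  n <- length(z)
  draws <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_boot, ncol = 4L,
                  dimnames = list(NULL, c("pi_minus", "pi_zero", "pi_plus", "mu_z")))
    for (b in seq_len(n_boot)) {
      zb <- z[sample.int(n, n, replace = TRUE)]
      res <- tryCatch({
        runs <- list(.em_fit(zb, fit$params))
        for (r in seq_len(n_restarts)) {
          w <- stats::rexp(3); w <- w / sum(w)
          runs[[r + 1L]] <- .em_fit(
            zb, mixture_params(w[1], w[2], w[3], stats::runif(1, 0.2, 4)))
        }
        best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
        p <- .snap_boundary(best$params)
        c(p$pi_minus, p$pi_zero, p$pi_plus, p$mu_z)
      }, error = function(e) rep(NA_real_, 4L))
      out[b, ] <- res
    }
    out
  })
  n_failed <- sum(!stats::complete.cases(draws))
  if (n_failed > max_fail_frac * n_boot) {
    stop("bootstrap inference failed: ", n_failed, " of ", n_boot,
         " replicate fits did not converge")
  }
  ok <- draws[stats::complete.cases(draws), , drop = FALSE]
  boot_se <- apply(ok, 2L, stats::sd)
  est <- c(pi_minus = fit$params$pi_minus, pi_zero = fit$params$pi_zero,
           pi_plus = fit$params$pi_plus, mu_z = fit$params$mu_z)
  boot_p <- ifelse(est == 0, 1,
                   ifelse(boot_se > 0, 2 * stats::pnorm(-abs(est) / boot_se), 0))
  names(boot_p) <- names(est)
  list(boot_se = boot_se, boot_p = boot_p, n_boot = as.integer(n_boot),
       n_failed = n_failed, seed = seed, draws = ok)
}

#' Expected number of phenotypes with elevated risk
#'
#' Translates the harmful-component weight into an expected disease count:
#' `pi_plus * n_phenotypes`, with the rounded value computed half away
#' from zero.
#'
#' @param params A [mixture_params()] object.
#' @param n_phenotypes Number of phenotypes in the panel.
#' @return List with `expected` (real) and `rounded` (integer).
#' @export
#' @examples
#' expected_affected(mixture_params(0, 0.769, 0.231, 1.003), 131)
expected_affected <- function(params, n_phenotypes) {
  stopifnot(n_phenotypes >= 1)
  expected <- params$pi_plus * n_phenotypes
  list(expected = expected,
       rounded = as.integer(sign(expected) * floor(abs(expected) + 0.5)))
}
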