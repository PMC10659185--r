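# Independent oracles used across tests.

# Brute-force double-quadrature oracle for the boundary likelihood:
# integrates the full generative chain numerically, marginalizing the
# measurement m (inner) and the stimulus S (outer) with the class-state
# indicator restricting the S range.  Kept free of the closed form it checks.
quad_boundary_likelihood <- function(b, m_prime, cl, sigma_m, sigma_mprime,
                                     sigma_s) {
  p_mprime_given_s <- function(s) {
    vapply(s, function(si) {
      stats::integrate(function(m)
        dnorm(m_prime, m, sigma_mprime) * dnorm(m, si, sigma_m),
        lower = si - 10 * sigma_m, upper = si + 10 * sigma_m,
        rel.tol = 1e-11, abs.tol = 1e-13)$value
    }, numeric(1))
  }
  integrand <- function(s) p_mprime_given_s(s) * dnorm(s, b, sigma_s)
  span <- 10 * (sigma_s + sigma_m + sigma_mprime)
  if (cl == 0L)
    stats::integrate(integrand, lower = b - span, upper = b,
                     rel.tol = 1e-10, abs.tol = 1e-12)$value
  else
    stats::integrate(integrand, lower = b, upper = b + span,
                     rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Very-fine-grid refinement oracle for the posterior moments (1e5 points on
# the documented union support).
finegrid_posterior <- function(belief, m_prime, cl, params, n = 1e5) {
  sd_p <- sqrt(belief$variance)
  half <- sqrt(params[["sigma_mprime"]]^2 + params[["sigma_m"]]^2 +
                 params[["sigma_s"]]^2)
  lo <- min(belief$mean - 8 * sd_p, m_prime - 8 * half)
  hi <- max(belief$mean + 8 * sd_p, m_prime + 8 * half)
  b <- seq(lo, hi, length.out = n)
  lp <- boundary_likelihood(b, m_prime, cl, params, log = TRUE) +
    dnorm(b, belief$mean, sd_p, log = TRUE)
  d <- exp(lp - max(lp))
  h <- b[2] - b[1]
  w <- rep(h, n); w[c(1, n)] <- h / 2
  d <- d / sum(w * d)
  mu <- sum(w * d * b)
  va <- sum(w * d * (b - mu)^2)
  list(mean = mu, variance = va)
}

# Standard world/value parameter sets used in several tests.
test_world_pars <- c(mu0 = 0, sigma_m = 1, sigma_s = 1.5, sigma_0 = 1.6,
                     sigma_mprime = 0.5, sigma_diffusion = 0.5)

# Binomial counts from an arbitrary psychometric curve.
counts_from_curve <- function(p, n_per_level, levels = -2:2,
                              exact = TRUE) {
  n <- rep(n_per_level, length(levels))
  k <- if (exact) round(n * p) else rbinom(length(levels), n, p)
  data.frame(level = levels, n = n, k = k)
}
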