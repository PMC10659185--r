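# BMBU, the Bayesian boundary-updating agent.
#
# The agent's learned generative model is
#   S  ~ N(B, sigma_s^2)        believed stimulus distribution
#   m  ~ N(S, sigma_m^2)        sensory measurement
#   m' ~ N(m, sigma_mprime^2)   mnemonic measurement
#   CL = large iff S > B        true class state
# Decisions compare the measurement against the current boundary belief;
# after feedback the class state CL is deduced from (choice, feedback) and
# the boundary belief is updated by Bayes rule from (m', CL), then decays
# toward mu0 and diffuses before the next trial.

#' Gaussian summary of the boundary belief
#'
#' @param mean belief mean (the operative class boundary `B`).
#' @param variance belief variance (>= 0).
#' @param grid optional list with `b` (support) and `density` (normalized
#'   posterior densities) retained from the most recent update.
#' @return object of class `boundary_belief`.
#' @export
boundary_belief <- function(mean, variance, grid = NULL) {
  stopifnot(is.finite(mean), is.finite(variance), variance >= 0)
  structure(list(mean = mean, variance = variance, grid = grid),
            class = "boundary_belief")
}

#' @export
print.boundary_belief <- function(x, ...) {
  cat(sprintf("<boundary_belief mean=%.4f var=%.4f%s>\n", x$mean, x$variance,
              if (is.null(x$grid)) "" else
                sprintf(" grid[%d]", length(x$grid$b))))
  invisible(x)
}

#' Decision from a measurement and the current boundary belief
#'
#' `p_L = Phi((m - B) / sigma_m)`; large is chosen iff `p_L > 0.5`, with an
#' exact tie broken by a fair coin.
#'
#' @param m sensory measurement.
#' @param belief a [boundary_belief()].
#' @param sigma_m sensory noise SD.
#' @return list with `choice` (0/1) and `p_l`.
#' @export
decide <- function(m, belief, sigma_m) {
  p_l <- belief_state(m, belief$mean, sigma_m)
  choice <- if (p_l > 0.5) 1L else if (p_l < 0.5) 0L else
    as.integer(runif(1) < 0.5)
  list(choice = choice, p_l = p_l)
}

#' Class state deduced from choice and feedback
#'
#' `CL = large` iff (large, correct) or (small, incorrect); small otherwise.
#' With the 0/1 encodings this is `choice == feedback`.
#'
#' @param choice 0 = small, 1 = large (vectorized).
#' @param feedback 0 = incorrect, 1 = correct.
#' @return integer vector, 1 = large, 0 = small.
#' @export
deduce_class_state <- function(choice, feedback) {
  stopifnot(all(choice %in% 0:1), all(feedback %in% 0:1))
  as.integer(choice == feedback)
}

sigma_M2 <- function(params) {
  params[["sigma_mprime"]]^2 + params[["sigma_m"]]^2
}

#' Likelihood of the class boundary given mnemonic measurement and class state
#'
#' Marginalizing the unknown stimulus out of the generative model gives, with
#' `sigma_M^2 = sigma_mprime^2 + sigma_m^2` and `sigma_S^2 = sigma_s^2`,
#' \deqn{L_{small}(b) = \Phi\!\left(\frac{b - w(b)}{\sqrt v}\right)
#'   N(m'; b, \sigma_M^2 + \sigma_S^2),}
#' where `w(b) = (b sigma_M^2 + m' sigma_S^2) / (sigma_M^2 + sigma_S^2)` and
#' `v = sigma_M^2 sigma_S^2 / (sigma_M^2 + sigma_S^2)`; `L_large` carries the
#' complementary CDF factor.  The two sum to `N(m'; b, sigma_M^2 + sigma_S^2)`.
#'
#' @param b boundary value(s); vectorized.
#' @param m_prime mnemonic measurement.
#' @param cl class state (1 = large, 0 = small).
#' @param params named parameters of a world agent (see [world_agent()]).
#' @param log return log densities.
#' @return density values, same length as `b`.
#' @export
boundary_likelihood <- function(b, m_prime, cl, params, log = FALSE) {
  params <- validate_params(if ("alpha" %in% names(params)) "hybrid" else
                              "world", unlist(params))
  sM2 <- sigma_M2(params)
  sS2 <- params[["sigma_s"]]^2
  if (sM2 <= 0 || sS2 <= 0)
    stop("degenerate sigma_M or sigma_S: closed form undefined")
  w <- (b * sM2 + m_prime * sS2) / (sM2 + sS2)
  v <- sM2 * sS2 / (sM2 + sS2)
  z <- (b - w) / sqrt(v)
  log_cdf <- pnorm(z, log.p = TRUE, lower.tail = (cl == 0L))
  log_gauss <- dnorm(m_prime, b, sqrt(sM2 + sS2), log = TRUE)
  out <- log_cdf + log_gauss
  if (log) out else exp(out)
}

#' Bayesian update of the boundary belief
#'
#' The posterior `p(b | m', CL)` is the boundary likelihood times the
#' Gaussian prior, normalized by trapezoidal integration on a grid spanning
#' the union of `prior mean +/- 8 prior SD` and
#' `m' +/- 8 sqrt(sigma_S^2 + sigma_M^2)` with `n_grid` points.  The
#' returned belief carries the grid's mean and variance (the two moments the
#' prior propagation consumes).
#'
#' @param belief prior [boundary_belief()] with positive variance.
#' @param m_prime mnemonic measurement.
#' @param cl class state (1 = large, 0 = small).
#' @param params world-agent parameters.
#' @param n_grid number of grid points (>= 2001 by default).
#' @param keep_grid retain the normalized grid in the result.
#' @return posterior [boundary_belief()].
#' @export
posterior_update <- function(belief, m_prime, cl, params, n_grid = 2001,
                             keep_grid = TRUE) {
  stopifnot(inherits(belief, "boundary_belief"), belief$variance > 0)
  params <- validate_params("world", unlist(params)[model_par_names("world")])
  half <- sqrt(sigma_M2(params) + params[["sigma_s"]]^2)
  for (widen in c(8, 16)) {
    sd_p <- sqrt(belief$variance)
    lo <- min(belief$mean - widen * sd_p, m_prime - widen * half)
    hi <- max(belief$mean + widen * sd_p, m_prime + widen * half)
    b <- seq(lo, hi, length.out = n_grid)
    lp <- boundary_likelihood(b, m_prime, cl, params, log = TRUE) +
      dnorm(b, belief$mean, sd_p, log = TRUE)
    d <- exp(lp - max(lp))
    h <- b[2] - b[1]
    wts <- rep(h, n_grid); wts[c(1, n_grid)] <- h / 2
    z <- sum(wts * d)
    if (is.finite(z) && z > 0) {
      d <- d / z
      mu <- sum(wts * d * b)
      va <- sum(wts * d * (b - mu)^2)
      return(boundary_belief(mu, va,
                             grid = if (keep_grid) list(b = b, density = d)))
    }
  }
  stop("posterior normalizer is numerically zero even on the widened grid")
}

#' Decay-and-diffusion propagation of the posterior into the next prior
#'
#' With `lambda = sigma_0^2 / (sigma_0^2 + post_var)`, the next prior is
#' `N(lambda * post_mean + (1 - lambda) * mu0,
#'    lambda * post_var + sigma_diffusion^2)`.
#'
#' @param post posterior [boundary_belief()].
#' @param params world-agent parameters.
#' @return prior [boundary_belief()] for the next trial.
#' @export
propagate_prior <- function(post, params) {
  params <- validate_params("world", unlist(params)[model_par_names("world")])
  s02 <- params[["sigma_0"]]^2
  lambda <- s02 / (s02 + post$variance)
  boundary_belief(lambda * post$mean + (1 - lambda) * params[["mu0"]],
                  lambda * post$variance + params[["sigma_diffusion"]]^2)
}

#' One full BMBU trial (reference implementation)
#'
#' Samples the measurement, decides, receives feedback from the virtual
#' criterion, samples the mnemonic measurement, deduces the class state,
#' updates the posterior and propagates the prior for the next trial.  The
#' bulk simulator ([simulate_agent_session()]) runs the same computation in
#' compiled code.
#'
#' @param belief current prior [boundary_belief()].
#' @param stimulus stimulus level.
#' @param criterion virtual criterion value for this trial.
#' @param params world-agent parameters.
#' @param n_grid grid resolution for the posterior update.
#' @return list with `choice`, `feedback`, `m`, `m_prime`, `p_l`,
#'   `posterior` and the next-trial prior `belief`.
#' @export
bmbu_step <- function(belief, stimulus, criterion, params, n_grid = 2001) {
  params <- validate_params("world", unlist(params)[model_par_names("world")])
  m <- rnorm(1, stimulus, params[["sigma_m"]])
  dec <- decide(m, belief, params[["sigma_m"]])
  truth <- as.integer(stimulus > criterion)
  feedback <- as.integer(dec$choice == truth)
  m_prime <- rnorm(1, m, params[["sigma_mprime"]])
  cl <- deduce_class_state(dec$choice, feedback)
  post <- posterior_update(belief, m_prime, cl, params, n_grid = n_grid,
                           keep_grid = FALSE)
  list(choice = dec$choice, feedback = feedback, m = m, m_prime = m_prime,
       p_l = dec$p_l, posterior = post,
       belief = propagate_prior(post, params))
}
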