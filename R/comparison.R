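# Model evidence (AICc), random-effects group Bayesian model selection and
# model recovery.

#' Sample-size-corrected Akaike information criterion
#'
#' `AICc = -2 ll + 2 p + 2 p (p + 1) / (n - p - 1)`.
#'
#' @param ll maximized log likelihood.
#' @param p number of free parameters.
#' @param n number of trials.
#' @export
aicc <- function(ll, p, n) {
  if (any(n <= p + 1)) stop("AICc requires n > p + 1")
  -2 * ll + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Log model evidence from AICc
#'
#' The per-participant log model evidence is `-AICc / 2`.
#' @inheritParams aicc
#' @export
log_model_evidence <- function(ll, p, n) -aicc(ll, p, n) / 2

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Random-effects group Bayesian model selection
#'
#' Variational Dirichlet scheme over population model frequencies (uniform
#' `Dirichlet(1)` prior): responsibilities are updated proportional to
#' `exp(evidence + digamma terms)` and the Dirichlet concentrations to the
#' prior plus summed responsibilities, iterated to convergence.  Exceedance
#' probabilities are Monte-Carlo estimates from the Dirichlet posterior;
#' the Bayesian omnibus risk (BOR) compares the free energy of the
#' alternative against the null of equal frequencies, and the protected
#' exceedance probability is `(1 - BOR) * xp + BOR / M`.
#'
#' @param lme matrix of log model evidences, agents x models.
#' @param n_samples Monte-Carlo samples for exceedance probabilities.
#' @param prior_alpha Dirichlet prior concentration (default 1).
#' @param tol convergence tolerance on the concentrations.
#' @param max_iter iteration cap; non-convergence is flagged.
#' @return list with `alpha`, `ep` (expected posterior model
#'   probabilities), `xp`, `pxp`, `bor`, `z` (per-agent responsibilities),
#'   `converged`.
#' @export
group_bms <- function(lme, n_samples = 1e6, prior_alpha = 1, tol = 1e-6,
                      max_iter = 500) {
  lme <- as.matrix(lme)
  stopifnot(nrow(lme) >= 1, ncol(lme) >= 1, all(is.finite(lme)))
  n <- nrow(lme); M <- ncol(lme)
  if (M == 1)
    return(list(alpha = prior_alpha + n, ep = 1, xp = 1, pxp = 1, bor = NA,
                z = matrix(1, n, 1), converged = TRUE))
  a0 <- rep(prior_alpha, M)
  a <- a0 + n / M
  z <- matrix(1 / M, n, M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lw <- sweep(lme, 2, digamma(a) - digamma(sum(a)), "+")
    z <- exp(lw - apply(lw, 1, log_sum_exp))
    a_new <- a0 + colSums(z)
    if (max(abs(a_new - a)) < tol) { a <- a_new; converged <- TRUE; break }
    a <- a_new
  }
  ep <- a / sum(a)
  samp <- matrix(rgamma(n_samples * M, shape = rep(a, each = n_samples)),
                 n_samples, M)
  xp <- tabulate(max.col(samp), M) / n_samples
  # Free energy of the alternative (variational) and the null of equal
  # frequencies (exact), following the protected-exceedance formulation.
  elog_r <- digamma(a) - digamma(sum(a))
  zs <- pmax(z, 1e-300)
  f1 <- sum(z * lme) + sum(z %*% elog_r) - sum(z * log(zs)) -
    (lgamma(sum(a)) - sum(lgamma(a)) - lgamma(sum(a0)) + sum(lgamma(a0)) +
       sum((a - a0) * elog_r))
  f0 <- sum(apply(lme, 1, log_sum_exp) - log(M))
  bor <- 1 / (1 + exp(f1 - f0))
  pxp <- (1 - bor) * xp + bor / M
  list(alpha = a, ep = ep, xp = xp, pxp = pxp, bor = bor, z = z,
       converged = converged)
}

#' Warm starts for a model from fitted submodels
#'
#' Builds parameter vectors that embed already-fitted nested submodels into
#' a larger model's space (boundary updating switched off by a near-zero
#' baseline prior SD, value updating by a near-zero learning rate with a
#' sharp softmax), so that the larger model's search starts at least as good
#' as the submodel's optimum.
#'
#' @param model the model about to be fitted.
#' @param fits named list of `fit_result` objects keyed by model name.
#' @return list of named parameter vectors (possibly empty), suitable for
#'   `fit_model(extra_starts = )`.
#' @export
submodel_starts <- function(model, fits) {
  grab <- function(name)
    if (!is.null(fits[[name]]) && !isTRUE(fits[[name]]$failed))
      fits[[name]]$theta else NULL
  static_from <- function() {
    for (nm0 in c("fixed", "base")) {
      th <- grab(nm0)
      if (!is.null(th))
        return(c(mu0 = if ("mu0" %in% names(th)) th[["mu0"]] else 0,
                 sigma_m = th[["sigma_m"]]))
    }
    NULL
  }
  off_boundary <- c(sigma_s = 1, sigma_0 = 0.05, sigma_mprime = 0.3,
                    sigma_diffusion = 0.01)
  off_value <- c(alpha = 0.05, beta = 30, v_init = 1)
  out <- list()
  if (model == "fixed") {
    b <- grab("base")
    if (!is.null(b)) out <- c(out, list(c(mu0 = 0, sigma_m = b[["sigma_m"]])))
  }
  if (model == "value") {
    st <- static_from()
    if (!is.null(st)) out <- c(out, list(c(st, off_value)))
  }
  if (model == "world") {
    st <- static_from()
    if (!is.null(st)) out <- c(out, list(c(st, off_boundary)))
  }
  if (model == "hybrid") {
    w <- grab("world")
    if (!is.null(w)) out <- c(out, list(c(w, off_value)))
    v <- grab("value")
    if (!is.null(v))
      out <- c(out, list(c(v[c("mu0", "sigma_m")], off_boundary,
                           v[c("alpha", "beta", "v_init")])))
  }
  out
}

#' Model recovery analysis
#'
#' For each generating model, synthetic sessions are simulated from supplied
#' per-agent parameters, every candidate model is fitted to every dataset,
#' AICc-based log model evidence feeds [group_bms()] per generating model,
#' and the confusion entry (g, m) is the protected exceedance probability of
#' candidate m under ground truth g.  Candidates are fitted in nesting order
#' and each fit receives [submodel_starts()] of the dataset's earlier fits
#' as warm starts, so a supermodel never scores below its nested submodels
#' for want of searching.
#'
#' @param gen_params named list (one entry per generating model) of lists of
#'   `pdm_agent` objects, one per simulated agent.
#' @param candidates candidate model names fitted to every dataset.
#' @param schedule_fn zero-argument function returning a fresh session
#'   schedule for each simulated agent.
#' @param fit_args list of arguments forwarded to [fit_model()].
#' @param lapse_rate lapse rate used when generating the synthetic sessions.
#' @return list with `confusion` (generating x candidate PXP matrix),
#'   `evidence` (per generating model the agents x candidates lme matrix),
#'   `fits`, `failures`.
#' @export
model_recovery <- function(gen_params, candidates = names(gen_params),
                           schedule_fn = make_session_schedule,
                           fit_args = list(), lapse_rate = 0) {
  stopifnot(length(gen_params) >= 1, !is.null(names(gen_params)))
  truths <- names(gen_params)
  fit_order <- intersect(MODEL_NAMES, candidates)
  confusion <- matrix(NA_real_, length(truths), length(candidates),
                      dimnames = list(truths, candidates))
  evidence <- list(); fits <- list(); failures <- list()
  for (g in truths) {
    agents <- gen_params[[g]]
    lme <- matrix(NA_real_, length(agents), length(candidates),
                  dimnames = list(NULL, candidates))
    for (i in seq_along(agents)) {
      trials <- simulate_agent_session(agents[[i]], schedule_fn(),
                                       lapse_rate = lapse_rate)
      fits_ds <- list()
      for (mcand in fit_order) {
        fit <- do.call(fit_model,
                       c(list(model = mcand, trials = trials,
                              lapse_rate = lapse_rate,
                              extra_starts = submodel_starts(mcand,
                                                             fits_ds)),
                         fit_args))
        fits_ds[[mcand]] <- fit
        fits[[paste(g, i, mcand, sep = "/")]] <- fit
        if (isTRUE(fit$failed)) {
          failures[[paste(g, i, mcand, sep = "/")]] <- TRUE
          next
        }
        lme[i, mcand] <- log_model_evidence(fit$ll,
                                            length(model_par_names(mcand)),
                                            nrow(trials))
      }
    }
    keep <- complete.cases(lme)
    evidence[[g]] <- lme
    if (sum(keep) >= 1)
      confusion[g, ] <- group_bms(lme[keep, , drop = FALSE])$pxp
  }
  list(confusion = confusion, evidence = evidence, fits = fits,
       failures = failures)
}
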