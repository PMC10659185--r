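# Simulation-based maximum-likelihood fitting: inverse binomial sampling
# (IBS) log-likelihood estimation, lapse-trial designation and multistart
# derivative-free optimization.

#' Session-level lapse rate from the grand psychometric curve
#'
#' Fits the 4-parameter cumulative Gaussian to all trials pooled and returns
#' the average of the guess and lapse rates, `(gamma + lambda) / 2`.  A
#' non-identifiable grand fit returns 0 with a warning.
#'
#' @param trials trial table of one agent/participant.
#' @return lapse probability in `[0, 0.5]`.
#' @export
estimate_lapse_rate <- function(trials) {
  lc <- level_counts(trials)
  fit <- fit_psychometric(lc$level, lc$n, lc$k, include_lapse = TRUE)
  if (!fit$identifiable) {
    warning("grand psychometric fit non-identifiable; lapse rate set to 0")
    return(0)
  }
  min(max((fit$guess + fit$lapse) / 2, 0), 0.5)
}

#' Unbiased IBS estimate of the choice log likelihood
#'
#' Per trial, simulated choices are drawn from the model until one matches
#' the observed choice; with K draws the trial contributes
#' `-sum_{j=1}^{K-1} 1/j`.  Latent trajectories are conditioned on the
#' observed choices and feedback; the matching draw's measurement feeds the
#' mnemonic/update step.  Trials designated as lapse trials are scored under
#' the fair-coin emission.  Trials reaching `max_draws` without a match are
#' floored at the `max_draws` harmonic sum and counted in `n_capped`.
#'
#' @param agent a `pdm_agent`.
#' @param trials trial table with observed `stimulus`, `choice`, `feedback`,
#'   `run`.
#' @param lapse logical vector designating lapse trials (default none).
#' @param max_draws cap on draws per trial.
#' @param reps number of independent IBS repetitions averaged.
#' @param n_grid grid resolution of the compiled boundary-posterior update.
#' @return list with `ll` (mean across repetitions), `ll_reps`, `n_capped`.
#' @export
ibs_loglik <- function(agent, trials, lapse = NULL, max_draws = 1e4,
                       reps = 1, n_grid = 301) {
  stopifnot(inherits(agent, "pdm_agent"))
  n <- nrow(trials)
  if (is.null(lapse)) lapse <- rep(FALSE, n)
  stopifnot(length(lapse) == n)
  ll <- numeric(reps); capped <- integer(reps)
  for (r in seq_len(reps)) {
    est <- cpp_ibs(model_code(agent$model), unname(agent$params),
                   as.integer(trials$stimulus), as.integer(trials$choice),
                   as.integer(trials$feedback), as.integer(trials$run),
                   as.logical(lapse), as.integer(max_draws),
                   as.integer(n_grid), 10.0)
    ll[r] <- est$ll; capped[r] <- est$n_capped
  }
  list(ll = mean(ll), ll_reps = ll, n_capped = capped)
}

#' Multistart simulation-based maximum-likelihood fit
#'
#' Starting points are Latin-hypercube samples within the box bounds.  Each
#' optimized start runs a derivative-free pattern search: coordinate steps
#' (initially `step0` of each parameter range) are accepted when they
#' improve the objective and halved when a full sweep stalls.  The IBS
#' objective is stochastic, so the search is noise-aware in two ways: every
#' evaluation averages IBS repetitions drawn under common random numbers (a
#' fixed set of per-repetition seeds reused across evaluations, so nearby
#' parameter values see a consistent, not independently noisy, surface), and
#' the repetition count grows as the steps shrink (`reps_schedule`, one
#' entry per shrinkage stage).  Start finals are compared under shared seeds
#' (`reps_select`) and the winner is re-evaluated with `reps_final` fresh
#' repetitions, which gives the reported (unbiased) log-likelihood estimate.
#'
#' @param model model name.
#' @param trials observed trial table.
#' @param bounds bounds matrix as from [default_bounds()].
#' @param n_starts number of Latin-hypercube starts (default 20).
#' @param n_optimize how many starts to optimize; the rest stop after their
#'   first objective evaluation (ranked under shared seeds).  `NULL` (the
#'   default) optimizes every start; small values buy speed at desk scale.
#' @param lapse_rate probability used to designate lapse trials before the
#'   fit; `NULL` estimates it from the grand psychometric curve via
#'   [estimate_lapse_rate()].
#' @param reps_schedule IBS repetitions averaged per evaluation in each
#'   shrinkage stage of the pattern search.
#' @param n_sweeps sweep budget per optimized start.
#' @param step0 initial step as a fraction of each parameter range.
#' @param reps_select,reps_final IBS repetitions at start selection and for
#'   the reported final estimate.
#' @param max_draws,n_grid passed to [ibs_loglik()].
#' @param max_draws_search cheaper draw cap used during the search (capped
#'   trials are floored, which only matters at poor parameter values);
#'   selection and the final estimate use `max_draws`.
#' @param informed_start add one data-driven start: `mu0` and `sigma_m` from
#'   the grand probit fit of the pooled psychometric curve, remaining
#'   parameters at the (transformed) mid-range.  Always optimized.
#' @param extra_starts list of named parameter vectors used as additional
#'   always-optimized starts (e.g. embeddings of fitted submodels).
#' @return object of class `fit_result`: best parameters, final LL estimate
#'   and its SD, and the per-start table.
#' @export
fit_model <- function(model, trials, bounds = default_bounds(model),
                      n_starts = 20, n_optimize = NULL, lapse_rate = 0,
                      reps_schedule = c(2, 2, 4, 4, 8, 16), n_sweeps = 40,
                      step0 = 0.2, reps_select = 20, reps_final = 100,
                      max_draws = 1e4, n_grid = 51,
                      max_draws_search = 1000, informed_start = TRUE,
                      extra_starts = list()) {
  model <- match.arg(model, MODEL_NAMES)
  nm <- model_par_names(model)
  stopifnot(identical(colnames(bounds), nm), n_starts >= 1)
  if (is.null(n_optimize)) n_optimize <- n_starts
  n_optimize <- min(n_optimize, n_starts)
  if (is.null(lapse_rate)) lapse_rate <- estimate_lapse_rate(trials)
  n <- nrow(trials)
  lapse <- if (lapse_rate > 0) runif(n) < lapse_rate else rep(FALSE, n)
  crn_seeds <- sample.int(.Machine$integer.max,
                          max(reps_schedule, reps_select))
  ll_crn <- function(th, reps, draws = max_draws) {
    agent <- make_agent(model, stats::setNames(th, nm))
    mean(vapply(crn_seeds[seq_len(reps)], function(s) {
      set.seed(s)
      ibs_loglik(agent, trials, lapse, draws, 1, n_grid)$ll
    }, numeric(1)))
  }
  # scale-type parameters are searched on a log scale (their likelihood
  # valleys are badly conditioned linearly); location/rate parameters stay
  # linear.  LHS starts are drawn in the transformed space, i.e. log-uniform
  # over scales.
  tf_log <- nm %in% c("sigma_m", "sigma_s", "sigma_0", "sigma_mprime",
                      "sigma_diffusion", "beta")
  tf_off <- ifelse(nm == "beta", 1, 0.01)
  fwd <- function(th) { u <- th; u[tf_log] <- log(th[tf_log] + tf_off[tf_log]); u }
  bwd <- function(u) { th <- u; th[tf_log] <- exp(u[tf_log]) - tf_off[tf_log]; th }
  lo <- fwd(bounds["lower", ]); hi <- fwd(bounds["upper", ])
  frac <- lhs::randomLHS(n_starts, length(nm))
  starts <- lapply(seq_len(n_starts), function(i) lo + frac[i, ] * (hi - lo))
  # rank the LHS starts under the cheapest shared-seed objective
  probe_ll <- vapply(starts, function(u)
    ll_crn(bwd(u), reps_schedule[1], draws = max_draws_search), numeric(1))
  optimize_idx <- order(probe_ll, decreasing = TRUE)[seq_len(n_optimize)]
  clamp <- function(th) pmin(pmax(th, bounds["lower", ] + 1e-6),
                             bounds["upper", ] - 1e-6)
  if (informed_start) {
    lc <- level_counts(trials)
    f2 <- probit_fit2(lc$level, lc$n, lc$k)
    if (!is.null(f2)) {
      th0 <- bwd((lo + hi) / 2)
      if ("mu0" %in% nm) th0[nm == "mu0"] <- f2[["pse"]]
      th0[nm == "sigma_m"] <- f2[["sigma"]]
      extra_starts <- c(extra_starts, list(stats::setNames(th0, nm)))
    }
  }
  for (ex in extra_starts) {
    if (!all(nm %in% names(ex)))
      stop("extra start is missing parameters: ",
           paste(setdiff(nm, names(ex)), collapse = ", "))
    starts <- c(starts, list(fwd(clamp(as.numeric(ex[nm])))))
    probe_ll <- c(probe_ll, NA_real_)
    optimize_idx <- c(optimize_idx, length(starts))
  }
  search <- function(u, stage0 = 1, step_scale = 1) {
    step <- step0 * step_scale * (hi - lo)
    stage <- stage0
    f <- ll_crn(bwd(u), reps_schedule[stage], draws = max_draws_search)
    for (sw in seq_len(n_sweeps)) {
      improved <- FALSE
      for (d in sample(seq_along(u))) {
        for (sgn in c(1, -1)) {
          cand <- u
          cand[d] <- min(max(cand[d] + sgn * step[d], lo[d]), hi[d])
          if (cand[d] == u[d]) next
          fc <- ll_crn(bwd(cand), reps_schedule[stage],
                       draws = max_draws_search)
          if (fc > f) { u <- cand; f <- fc; improved <- TRUE; break }
        }
      }
      if (!improved) {
        step <- step / 2
        if (stage < length(reps_schedule)) {
          stage <- stage + 1
          f <- ll_crn(bwd(u), reps_schedule[stage], draws = max_draws_search)
        }
        if (max(step / (hi - lo)) < 0.005) break
      }
    }
    u
  }
  # warm (informed/extra) starts are near-solutions: polish them locally at
  # the high-repetition stages so early-stage noise cannot drag them off
  per_start <- vector("list", length(starts))
  polish_stage <- max(1, which(reps_schedule >= 8)[1] - 1)
  if (is.na(polish_stage)) polish_stage <- length(reps_schedule)
  for (i in seq_along(starts)) {
    warm <- i > n_starts
    th <- if (i %in% optimize_idx)
      tryCatch(bwd(search(starts[[i]],
                          stage0 = if (warm) polish_stage else 1,
                          step_scale = if (warm) 0.25 else 1)),
               error = function(e) NULL)
    else bwd(starts[[i]])
    if (is.null(th)) {
      per_start[[i]] <- data.frame(start = i, ll = NA_real_,
                                   optimized = TRUE, converged = FALSE)
      next
    }
    ll_sel <- if (i %in% optimize_idx) ll_crn(th, reps_select)
              else probe_ll[i]
    per_start[[i]] <- cbind(data.frame(start = i, ll = ll_sel,
                                       optimized = i %in% optimize_idx,
                                       converged = i %in% optimize_idx),
                            as.data.frame(as.list(stats::setNames(th, nm))))
  }
  tab <- do.call(rbind, lapply(per_start, function(d) {
    for (p in nm) if (is.null(d[[p]])) d[[p]] <- NA_real_
    d
  }))
  ok <- which(tab$converged & is.finite(tab$ll))
  if (length(ok) == 0)
    return(structure(list(model = model, theta = NULL, ll = NA_real_,
                          ll_sd = NA_real_, starts = tab, n_trials = n,
                          lapse_rate = lapse_rate, failed = TRUE),
                     class = "fit_result"))
  best <- ok[which.max(tab$ll[ok])]
  theta <- stats::setNames(as.numeric(tab[best, nm]), nm)
  fin <- ibs_loglik(make_agent(model, theta), trials, lapse, max_draws,
                    reps_final, n_grid)
  structure(list(model = model, theta = theta, ll = fin$ll,
                 ll_sd = stats::sd(fin$ll_reps) / sqrt(reps_final),
                 ll_reps = fin$ll_reps, starts = tab, n_trials = n,
                 lapse_rate = lapse_rate, lapse = lapse, failed = FALSE),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat("<fit_result:", x$model, "- all starts failed>\n")
    return(invisible(x))
  }
  cat(sprintf("<fit_result: %s  LL=%.2f (SE %.2f)  n=%d>\n", x$model, x$ll,
              x$ll_sd, x$n_trials))
  print(round(x$theta, 4))
  invisible(x)
}
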