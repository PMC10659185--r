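# Orchestration of the computational experiments: ex ante simulation over a
# sensory-noise grid, ex post simulation from supplied per-agent parameters,
# and the thin statistical reporting layer.

#' Point-estimate episode PSE table (no bootstrap)
#'
#' Retrospective and prospective PSEs per episode from single
#' maximum-likelihood fits; used where uncertainty is taken across
#' parameter sets or agents rather than within a cell.
#'
#' @param trials trial table.
#' @param min_trials minimum conditioned trials to report a cell.
#' @return long data.frame of episode x direction PSE point estimates.
#' @export
episode_pse_table <- function(trials, min_trials = 50) {
  ep <- episode_table()
  rows <- list()
  for (i in seq_len(nrow(ep))) {
    pse <- c(retrospective = NA_real_, prospective = NA_real_)
    nn <- c(retrospective = 0L, prospective = 0L)
    for (d in c(-1L, 1L)) {
      dir <- if (d < 0) "retrospective" else "prospective"
      sub <- condition_on_episode(trials, ep$stimulus[i], ep$choice[i],
                                  ep$feedback[i], d)
      nn[dir] <- nrow(sub)
      if (nrow(sub) >= min_trials) {
        lc <- level_counts(sub)
        f <- probit_fit2(lc$level, lc$n, lc$k)
        if (!is.null(f)) pse[dir] <- f[["pse"]]
      }
    }
    rows[[i]] <- data.frame(
      stimulus = ep$stimulus[i], choice = ep$choice[i],
      feedback = ep$feedback[i], episode = ep$label[i],
      direction = c(names(pse), "subtractive"),
      pse = c(pse, pse[["prospective"]] - pse[["retrospective"]]),
      n = c(nn, min(nn)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configuration of an ex ante simulation
#'
#' Defaults reproduce the study conditions: a sensory-noise grid of 25
#' levels uniformly spaced on `[0.15, 3.27]`, 30 runs of 170 trials per
#' repetition, no lapse trials and no choice bias (`mu0 = 0`).  The
#' non-shared model parameters default to values that put simulated task
#' accuracy in the human range (about 61-74% correct).
#'
#' @param sigma_m_grid sensory-noise grid.
#' @param n_reps simulation repetitions per grid point.
#' @param n_runs,n_trials session geometry.
#' @param value_pars,world_pars named lists overriding the non-shared
#'   parameter defaults of the two learning models.
#' @param min_trials minimum conditioned trials per PSE cell.
#' @return config list for [run_ex_ante()].
#' @export
ex_ante_config <- function(sigma_m_grid = seq(0.15, 3.27, length.out = 25),
                           n_reps = 100, n_runs = 30, n_trials = 170,
                           value_pars = list(), world_pars = list(),
                           min_trials = 50) {
  vp <- utils::modifyList(list(mu0 = 0, alpha = 0.3, beta = 8, v_init = 1),
                          value_pars)
  wp <- utils::modifyList(list(mu0 = 0, sigma_s = 1.5, sigma_0 = 1.6,
                               sigma_mprime = 0.5, sigma_diffusion = 0.5),
                          world_pars)
  list(sigma_m_grid = sigma_m_grid, n_reps = n_reps, n_runs = n_runs,
       n_trials = n_trials, value_pars = vp, world_pars = wp,
       min_trials = min_trials)
}

#' Ex ante simulation of both learning models over the sensory-noise grid
#'
#' For every `sigma_m` grid point both agents are driven through identical
#' session schedules (same stimulus sequences and virtual-criterion draws)
#' for `n_reps` repetitions, and episode-conditioned retrospective /
#' prospective / subtractive PSEs are computed per grid point.
#'
#' @param config from [ex_ante_config()].
#' @param models which of the two learning models to simulate.
#' @return data.frame with columns `model`, `sigma_m`, episode fields,
#'   `direction`, `pse`, `n`, plus an `accuracy` attribute per model x grid
#'   point in `attr(, "accuracy")`.
#' @export
run_ex_ante <- function(config = ex_ante_config(),
                        models = c("value", "world")) {
  out <- list(); acc <- list()
  for (sm in config$sigma_m_grid) {
    agents <- list()
    if ("value" %in% models)
      agents$value <- make_agent("value", c(list(sigma_m = sm),
                                            config$value_pars))
    if ("world" %in% models)
      agents$world <- make_agent("world", c(list(sigma_m = sm),
                                            config$world_pars))
    trials <- stats::setNames(vector("list", length(agents)), names(agents))
    for (rep in seq_len(config$n_reps)) {
      sched <- make_session_schedule(n_runs = config$n_runs,
                                     n_trials = config$n_trials)
      sched$run <- sched$run + (rep - 1) * config$n_runs
      for (mn in names(agents))
        trials[[mn]][[rep]] <- simulate_agent_session(agents[[mn]], sched)
    }
    for (mn in names(agents)) {
      tt <- do.call(rbind, trials[[mn]])
      tab <- episode_pse_table(tt, config$min_trials)
      tab <- cbind(model = mn, sigma_m = sm, tab)
      out[[length(out) + 1]] <- tab
      acc[[length(acc) + 1]] <- data.frame(model = mn, sigma_m = sm,
                                           accuracy = mean(tt$feedback))
    }
  }
  res <- do.call(rbind, out)
  attr(res, "accuracy") <- do.call(rbind, acc)
  res
}

#' Repetition-level ex ante PSEs pooled across the sensory-noise grid
#'
#' Complements [run_ex_ante()]: each repetition simulates one full session
#' per `sigma_m` grid point for both models, pools the repetition's trials
#' across the grid, and computes episode-conditioned retrospective /
#' prospective PSEs from the pooled curves.  Repetitions are the independent
#' replicates, so `mean / SE` across repetitions tests the sign of a
#' history effect under observer heterogeneity (each pooled curve spans the
#' whole sensory-noise range).
#'
#' @param config from [ex_ante_config()].
#' @param models which learning models to simulate.
#' @return data.frame with columns `model`, `rep`, episode fields,
#'   `direction`, `pse`, `n`.
#' @export
ex_ante_signature <- function(config = ex_ante_config(),
                              models = c("value", "world")) {
  out <- list()
  for (rep in seq_len(config$n_reps)) {
    pooled <- stats::setNames(vector("list", length(models)), models)
    for (gi in seq_along(config$sigma_m_grid)) {
      sm <- config$sigma_m_grid[gi]
      sched <- make_session_schedule(n_runs = config$n_runs,
                                     n_trials = config$n_trials)
      sched$run <- sched$run + (gi - 1) * config$n_runs
      if ("value" %in% models) {
        ag <- make_agent("value", c(list(sigma_m = sm), config$value_pars))
        pooled$value[[gi]] <- simulate_agent_session(ag, sched)
      }
      if ("world" %in% models) {
        ag <- make_agent("world", c(list(sigma_m = sm), config$world_pars))
        pooled$world[[gi]] <- simulate_agent_session(ag, sched)
      }
    }
    for (mn in models) {
      tab <- episode_pse_table(do.call(rbind, pooled[[mn]]),
                               config$min_trials)
      out[[length(out) + 1]] <- cbind(model = mn, rep = rep, tab)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean and SE across repetitions of a signature table
#'
#' @param sig output of [ex_ante_signature()].
#' @return per model x episode x direction: `pse_mean`, `pse_se`, `n_reps`.
#' @export
signature_summary <- function(sig) {
  key <- interaction(sig$model, sig$stimulus, sig$choice, sig$feedback,
                     sig$direction, drop = TRUE)
  out <- do.call(rbind, lapply(split(sig, key), function(d) {
    v <- d$pse[is.finite(d$pse)]
    data.frame(model = d$model[1], stimulus = d$stimulus[1],
               choice = d$choice[1], feedback = d$feedback[1],
               direction = d$direction[1],
               pse_mean = if (length(v)) mean(v) else NA_real_,
               pse_se = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                        else NA_real_,
               n_reps = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Across-grid summary of an ex ante table
#'
#' Mean and SEM of the PSE across the sensory-noise grid points, per model,
#' episode and direction.
#'
#' @param ex_ante output of [run_ex_ante()].
#' @return summary data.frame with `pse_mean`, `pse_se`, `n_sets`.
#' @export
ex_ante_summary <- function(ex_ante) {
  key <- interaction(ex_ante$model, ex_ante$stimulus, ex_ante$choice,
                     ex_ante$feedback, ex_ante$direction, drop = TRUE)
  parts <- split(ex_ante, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    v <- d$pse[is.finite(d$pse)]
    data.frame(model = d$model[1], stimulus = d$stimulus[1],
               choice = d$choice[1], feedback = d$feedback[1],
               episode = d$episode[1], direction = d$direction[1],
               pse_mean = if (length(v)) mean(v) else NA_real_,
               pse_se = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                        else NA_real_,
               n_sets = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Ex post simulation from per-agent parameters
#'
#' Same machinery as the ex ante simulation, but each simulated agent uses
#' its own (fitted or supplied) parameters and lapse rate; per-agent episode
#' PSE tables and episode-pair maps are returned so that population-level
#' tests can be run against a reference table.
#'
#' @param agents list of `pdm_agent` objects (one per simulated agent).
#' @param lapse_rates per-agent lapse rates (recycled).
#' @param n_reps repetitions per agent.
#' @param n_runs,n_trials session geometry.
#' @param min_trials minimum conditioned trials per PSE cell.
#' @return list with `pse` (long data.frame with an `agent` column) and
#'   `pair_maps` (per agent: retrospective and prospective 20x20 maps).
#' @export
run_ex_post <- function(agents, lapse_rates = 0, n_reps = 1, n_runs = 30,
                        n_trials = 170, min_trials = 50) {
  lapse_rates <- rep_len(lapse_rates, length(agents))
  pse <- list(); maps <- list()
  for (i in seq_along(agents)) {
    tt <- do.call(rbind, lapply(seq_len(n_reps), function(rep) {
      sched <- make_session_schedule(n_runs = n_runs, n_trials = n_trials)
      sched$run <- sched$run + (rep - 1) * n_runs
      simulate_agent_session(agents[[i]], sched, lapse_rate = lapse_rates[i])
    }))
    pse[[i]] <- cbind(agent = i, episode_pse_table(tt, min_trials))
    maps[[i]] <- list(retrospective = episode_pair_map(tt, -1L),
                      prospective = episode_pair_map(tt, 1L))
  }
  list(pse = do.call(rbind, pse), pair_maps = maps)
}

#' Per-cell paired comparison of two PSE tables
#'
#' Aligns two per-agent PSE tables on (episode, direction) cells, runs a
#' paired two-sided test per cell, and applies the Bonferroni threshold
#' `0.05 / n_cells` over the non-missing cells.
#'
#' @param table_a,table_b long per-agent PSE tables as returned in
#'   `run_ex_post()$pse`; must cover identical agents and cells.
#' @param method `"t"` (paired t test) or `"wilcoxon"` (signed rank).
#' @param alpha familywise error level before correction.
#' @return data.frame per cell with the mean difference, p value,
#'   Bonferroni threshold and significance flag.
#' @export
report_stats <- function(table_a, table_b, method = c("t", "wilcoxon"),
                         alpha = 0.05) {
  method <- match.arg(method)
  key <- function(d) paste(d$episode, d$direction, d$agent)
  if (!identical(sort(key(table_a)), sort(key(table_b))))
    stop("tables are not aligned on (episode, direction, agent) cells")
  table_b <- table_b[match(key(table_a), key(table_b)), ]
  cell <- paste(table_a$episode, table_a$direction)
  rows <- lapply(split(seq_len(nrow(table_a)), cell), function(idx) {
    a <- table_a$pse[idx]; b <- table_b$pse[idx]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 2)
      return(data.frame(episode = table_a$episode[idx[1]],
                        direction = table_a$direction[idx[1]],
                        mean_diff = NA_real_, p = NA_real_, n = sum(ok)))
    d <- a[ok] - b[ok]
    p <- if (all(d == 0)) 1
         else if (method == "t") t.test(d)$p.value
         else suppressWarnings(wilcox.test(d)$p.value)
    data.frame(episode = table_a$episode[idx[1]],
               direction = table_a$direction[idx[1]],
               mean_diff = mean(a[ok] - b[ok]), p = p, n = sum(ok))
  })
  out <- do.call(rbind, rows)
  tested <- is.finite(out$p)
  out$threshold <- alpha / sum(tested)
  out$significant <- tested & out$p < out$threshold
  rownames(out) <- NULL
  out
}
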