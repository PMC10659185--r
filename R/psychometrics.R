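# Episode-conditioned history-effect analysis: cumulative-Gaussian
# psychometric fits, bootstrap PSE estimation, retrospective/prospective
# conditioning and episode-pair frequency maps.
#
# Sign convention: the PSE is the mean of the fitted cumulative Gaussian on
# the stimulus-level axis; negative PSE = choices biased toward "large".

#' The 20 decision-making episodes
#'
#' All combinations of stimulus level (-2..2), choice (0 = small, 1 = large)
#' and feedback (0 = incorrect, 1 = correct).
#'
#' @return data.frame with columns `stimulus`, `choice`, `feedback` and a
#'   label.
#' @export
episode_table <- function() {
  g <- expand.grid(feedback = 0:1, choice = 0:1, stimulus = STIM_LEVELS,
                   KEEP.OUT.ATTRS = FALSE)[, c("stimulus", "choice",
                                               "feedback")]
  g$label <- sprintf("S%+d/%s/%s", g$stimulus,
                     ifelse(g$choice == 1, "large", "small"),
                     ifelse(g$feedback == 1, "correct", "incorrect"))
  g
}

# Aggregate a trial table into per-level (n, k) counts.
level_counts <- function(trials, levels = STIM_LEVELS) {
  n <- k <- integer(length(levels))
  for (i in seq_along(levels)) {
    sel <- trials$stimulus == levels[i]
    n[i] <- sum(sel)
    k[i] <- sum(trials$choice[sel] == 1L)
  }
  data.frame(level = levels, n = n, k = k)
}

# Fast 2-parameter probit MLE on binomial counts.  Returns c(pse, sigma) or
# NULL when non-identifiable.
probit_fit2 <- function(x, n, k) {
  keep <- n > 0
  x <- x[keep]; n <- n[keep]; k <- k[keep]
  if (length(x) < 2 || all(k == 0) || all(k == n)) return(NULL)
  fit <- tryCatch(
    suppressWarnings(glm.fit(cbind(1, x), k / n, weights = n,
                             family = binomial("probit"))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  b <- unname(fit$coefficients)
  if (!all(is.finite(b)) || b[2] <= 1e-8) return(NULL)
  c(pse = -b[1] / b[2], sigma = 1 / b[2])
}

psi_loglik4 <- function(par, x, n, k) {
  p <- par[3] + (1 - par[3] - par[4]) * pnorm((x - par[1]) / exp(par[2]))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log1p(-p))
}

#' Maximum-likelihood cumulative-Gaussian psychometric fit
#'
#' Fits `psi(x) = gamma + (1 - gamma - lambda) * Phi((x - mu) / sigma)` to
#' binomial counts of "large" choices per stimulus level; the 2-parameter
#' variant fixes `gamma = lambda = 0`.  The PSE is `mu`.  Data with all
#' responses identical are flagged non-identifiable (PSE `NA`) rather than
#' extrapolated.
#'
#' @param levels stimulus levels.
#' @param n trials per level.
#' @param k "large" choices per level.
#' @param include_lapse fit guess (`gamma`) and lapse (`lambda`) rates,
#'   bounded in `[0, 0.5]`.
#' @return object of class `psychometric_fit`: list with `pse`, `slope_sd`,
#'   `guess`, `lapse`, `identifiable`.
#' @export
fit_psychometric <- function(levels, n, k, include_lapse = FALSE) {
  stopifnot(length(levels) == length(n), length(n) == length(k),
            all(k >= 0), all(k <= n))
  if (sum(n > 0) < 2) stop("need at least 2 levels with trials")
  f2 <- probit_fit2(levels, n, k)
  out <- list(pse = NA_real_, slope_sd = NA_real_, guess = 0, lapse = 0,
              identifiable = FALSE, include_lapse = include_lapse)
  if (!include_lapse) {
    if (!is.null(f2)) {
      out$pse <- unname(f2["pse"]); out$slope_sd <- unname(f2["sigma"])
      out$identifiable <- TRUE
    }
    return(structure(out, class = "psychometric_fit"))
  }
  start <- if (!is.null(f2)) c(f2["pse"], log(max(f2["sigma"], 1e-2)), 0.01,
                               0.01) else c(0, 0, 0.01, 0.01)
  opt <- tryCatch(
    optim(start, psi_loglik4, x = levels, n = n, k = k, method = "L-BFGS-B",
          lower = c(-20, log(1e-3), 0, 0), upper = c(20, log(100), 0.5, 0.5)),
    error = function(e) NULL)
  if (!is.null(opt) && !(all(k == 0) || all(k == n))) {
    out$pse <- unname(opt$par[1]); out$slope_sd <- unname(exp(opt$par[2]))
    out$guess <- unname(opt$par[3]); out$lapse <- unname(opt$par[4])
    out$identifiable <- TRUE
  }
  structure(out, class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit pse=%.4f sigma=%.4f%s%s>\n", x$pse,
              x$slope_sd,
              if (x$include_lapse)
                sprintf(" gamma=%.3f lambda=%.3f", x$guess, x$lapse) else "",
              if (x$identifiable) "" else " NON-IDENTIFIABLE"))
  invisible(x)
}

#' Bootstrap PSE estimate
#'
#' Per-level "large" counts are resampled binomially at the observed
#' proportions and refitted; the reported PSE is the mean over resamples
#' (the binomial random process bootstrap), its SE the resample SD.
#' Non-identifiable resamples are dropped and counted; the estimate is
#' flagged when more than 20% are dropped.
#'
#' @inheritParams fit_psychometric
#' @param n_boot number of bootstrap resamples (default 5000).
#' @return list with `pse` (bootstrap mean), `se` (bootstrap SD),
#'   `pse_point` (fit to the original counts), `n_dropped`, `flagged`.
#' @export
bootstrap_pse <- function(levels, n, k, n_boot = 5000,
                          include_lapse = FALSE) {
  stopifnot(n_boot >= 1)
  point <- fit_psychometric(levels, n, k, include_lapse)
  p_hat <- ifelse(n > 0, k / n, 0)
  pses <- rep(NA_real_, n_boot)
  for (i in seq_len(n_boot)) {
    kb <- rbinom(length(n), n, p_hat)
    if (include_lapse) {
      f <- fit_psychometric(levels, n, kb, TRUE)
      if (f$identifiable) pses[i] <- f$pse
    } else {
      f <- probit_fit2(levels, n, kb)
      if (!is.null(f)) pses[i] <- f[["pse"]]
    }
  }
  ok <- is.finite(pses)
  list(pse = mean(pses[ok]), se = stats::sd(pses[ok]),
       pse_point = point$pse, n_boot = n_boot, n_dropped = sum(!ok),
       flagged = sum(!ok) > 0.2 * n_boot)
}

#' Trials neighbouring a decision-making episode
#'
#' Stacks the trials at position `toi + offset` for every trial of interest
#' matching the episode, respecting run boundaries (a toi at a run edge
#' contributes nothing in that direction).
#'
#' @param trials trial table.
#' @param stimulus,choice,feedback episode definition.
#' @param offset -1 (retrospective) or +1 (prospective).
#' @return the stacked sub-table (possibly empty).
#' @export
condition_on_episode <- function(trials, stimulus, choice, feedback,
                                 offset) {
  stopifnot(offset %in% c(-1L, 1L))
  toi <- which(trials$stimulus == stimulus & trials$choice == choice &
                 trials$feedback == feedback)
  tgt <- toi + offset
  keep <- tgt >= 1 & tgt <= nrow(trials)
  toi <- toi[keep]; tgt <- tgt[keep]
  same_run <- trials$run[tgt] == trials$run[toi]
  trials[tgt[same_run], , drop = FALSE]
}

#' Episode-conditioned history-effect table
#'
#' For each of the 20 episodes and both directions (retrospective toi-1,
#' prospective toi+1) the PSE of the conditioned psychometric curve is
#' estimated by [bootstrap_pse()]; a subtractive row (prospective minus
#' retrospective) is appended per episode.  Cells with fewer than
#' `min_trials` conditioned trials are reported as missing.
#'
#' @param trials trial table.
#' @param n_boot bootstrap resamples per cell.
#' @param min_trials minimum conditioned trials to report a cell.
#' @param include_lapse use the 4-parameter psychometric variant.
#' @return data.frame with one row per episode x direction
#'   (`retrospective`, `prospective`, `subtractive`): PSE, SE, trial counts.
#' @export
history_effect_table <- function(trials, n_boot = 5000, min_trials = 50,
                                 include_lapse = FALSE) {
  ep <- episode_table()
  rows <- list()
  for (i in seq_len(nrow(ep))) {
    est <- list()
    for (dir in c(retrospective = -1L, prospective = 1L)) {
      sub <- condition_on_episode(trials, ep$stimulus[i], ep$choice[i],
                                  ep$feedback[i], dir)
      if (nrow(sub) < min_trials) {
        est[[as.character(dir)]] <- list(pse = NA_real_, se = NA_real_,
                                         n = nrow(sub))
        next
      }
      lc <- level_counts(sub)
      bs <- bootstrap_pse(lc$level, lc$n, lc$k, n_boot, include_lapse)
      est[[as.character(dir)]] <- list(pse = bs$pse, se = bs$se,
                                       n = nrow(sub))
    }
    r <- est[["-1"]]; p <- est[["1"]]
    rows[[i]] <- data.frame(
      stimulus = ep$stimulus[i], choice = ep$choice[i],
      feedback = ep$feedback[i], episode = ep$label[i],
      direction = c("retrospective", "prospective", "subtractive"),
      pse = c(r$pse, p$pse, p$pse - r$pse),
      se = c(r$se, p$se, sqrt(r$se^2 + p$se^2)),
      n = c(r$n, p$n, min(r$n, p$n)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Episode-pair frequency map
#'
#' 20x20 conditional probabilities `P(episode at toi + offset | episode at
#' toi)`; each column (conditioning episode) sums to 1 over observed rows.
#' Conditioning episodes that never occur give an NA column.
#'
#' @param trials trial table.
#' @param offset -1 (retrospective map) or +1 (prospective map).
#' @return 20x20 matrix; rows = neighbouring episode, columns =
#'   conditioning episode.
#' @export
episode_pair_map <- function(trials, offset = 1L) {
  stopifnot(offset %in% c(-1L, 1L))
  ep <- episode_table()
  eid <- function(s, c, f) match(paste(s, c, f),
                                 paste(ep$stimulus, ep$choice, ep$feedback))
  id <- eid(trials$stimulus, trials$choice, trials$feedback)
  n <- nrow(trials)
  toi <- seq_len(n)
  tgt <- toi + offset
  keep <- tgt >= 1 & tgt <= n
  toi <- toi[keep]; tgt <- tgt[keep]
  keep2 <- trials$run[tgt] == trials$run[toi]
  toi <- toi[keep2]; tgt <- tgt[keep2]
  counts <- matrix(0, 20, 20, dimnames = list(ep$label, ep$label))
  tab <- table(factor(id[tgt], levels = 1:20),
               factor(id[toi], levels = 1:20))
  counts[] <- as.numeric(tab)
  cs <- colSums(counts)
  map <- sweep(counts, 2, cs, "/")
  map[, cs == 0] <- NA_real_
  map
}
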