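# Task simulator: stimulus sequences, run schedules with the stochastic
# virtual criterion, and bulk agent simulation.
#
# Experimental design emulated: runs of 170 trials; 5 ring-size levels
# (-2..2) randomized within every block of 5 trials; feedback generated from
# a virtual criterion drawn per trial from N(mu_true, sigma_true^2) with
# sigma_true = 1.28; mu_true is 0 early in a run and switches to one of
# {-0.4, 0, 0.4} after trial 40-50 (10 runs per value across a 30-run
# session, in shuffled order).

STIM_LEVELS <- -2:2

#' Blocked-randomized stimulus sequence
#'
#' Concatenation of independent uniform permutations of the stimulus levels,
#' so every level occurs exactly `n_trials / block_size` times.
#'
#' @param n_trials number of trials; must be divisible by `block_size`.
#' @param block_size block length; must equal the number of levels.
#' @param levels stimulus levels.
#' @return integer vector of stimulus levels.
#' @export
make_stimulus_sequence <- function(n_trials = 170, block_size = 5,
                                   levels = STIM_LEVELS) {
  if (n_trials %% block_size != 0)
    stop("n_trials (", n_trials, ") is not divisible by block_size (",
         block_size, ")")
  if (block_size != length(levels))
    stop("block_size must equal the number of stimulus levels")
  as.integer(unlist(lapply(seq_len(n_trials / block_size),
                           function(i) sample(levels))))
}

#' Stochastic feedback from a virtual criterion
#'
#' A criterion `b ~ N(mu_true, sigma_true^2)` is drawn per trial; the true
#' class is large iff `stimulus > b`, and feedback is correct iff the choice
#' matches the true class.  `sigma_true = 0` gives the degenerate
#' deterministic-criterion mode.
#'
#' @param stimulus stimulus level(s).
#' @param choice choice(s), 0 = small / 1 = large.
#' @param mu_true criterion mean (scalar or per trial).
#' @param sigma_true criterion SD (>= 0).
#' @return integer feedback (1 = correct, 0 = incorrect).
#' @export
generate_feedback <- function(stimulus, choice, mu_true, sigma_true = 1.28) {
  if (sigma_true < 0) stop("sigma_true must be >= 0")
  stopifnot(all(choice %in% 0:1))
  b <- rnorm(length(stimulus), mu_true, sigma_true)
  as.integer(choice == as.integer(stimulus > b))
}

#' Schedule of one run
#'
#' Builds the trial-level design for a run: the blocked stimulus sequence,
#' the per-trial criterion mean (0 before `switch_trial`, `mu_true` from it
#' on) and the pre-drawn virtual criterion values.  Pre-drawing the
#' criterion lets different agents be driven through identical schedules.
#'
#' @param mu_true post-switch criterion mean.
#' @param n_trials trials per run.
#' @param sigma_true criterion SD.
#' @param switch_trial trial index at which `mu_true` takes over; drawn
#'   uniformly from `switch_range` when `NULL`.
#' @param switch_range inclusive range for the random switch trial.
#' @param run run identifier stored in the schedule.
#' @return data.frame with columns `run`, `trial`, `stimulus`, `mu_true`,
#'   `criterion`.
#' @export
make_run_schedule <- function(mu_true = 0, n_trials = 170, sigma_true = 1.28,
                              switch_trial = NULL, switch_range = c(40, 50),
                              run = 1L) {
  if (is.null(switch_trial))
    switch_trial <- sample(switch_range[1]:switch_range[2], 1)
  if (switch_trial < switch_range[1] || switch_trial > switch_range[2])
    stop("switch_trial must lie in [", switch_range[1], ", ",
         switch_range[2], "]")
  trial <- seq_len(n_trials)
  mu <- ifelse(trial < switch_trial, 0, mu_true)
  data.frame(run = as.integer(run), trial = trial,
             stimulus = make_stimulus_sequence(n_trials),
             mu_true = mu,
             criterion = rnorm(n_trials, mu, sigma_true))
}

#' Session schedule: 30 runs, 10 per criterion mean, shuffled
#'
#' @param n_runs number of runs; must be divisible by `length(mu_values)`.
#' @param mu_values post-switch criterion means, assigned in equal
#'   proportion and shuffled order.
#' @inheritParams make_run_schedule
#' @return data.frame stacking the per-run schedules.
#' @export
make_session_schedule <- function(n_runs = 30, mu_values = c(-0.4, 0, 0.4),
                                  n_trials = 170, sigma_true = 1.28,
                                  switch_range = c(40, 50)) {
  if (n_runs %% length(mu_values) != 0)
    stop("n_runs must be divisible by the number of mu_true values")
  mus <- sample(rep(mu_values, each = n_runs / length(mu_values)))
  do.call(rbind, lapply(seq_len(n_runs), function(r)
    make_run_schedule(mu_true = mus[r], n_trials = n_trials,
                      sigma_true = sigma_true, switch_range = switch_range,
                      run = r)))
}

#' Simulate an agent through a session schedule
#'
#' Drives an agent trial by trial through the schedule: sample the
#' measurement, choose (lapse trials override the choice with a fair coin),
#' receive feedback against the pre-drawn criterion, update the agent's
#' latent state.  Latent state is re-initialized at every run start.
#'
#' @param agent a [pdm_agent][value_agent] object.
#' @param schedule data.frame from [make_session_schedule()] (columns `run`,
#'   `trial`, `stimulus`, `criterion`).
#' @param lapse_rate probability that a trial is a lapse trial.
#' @param n_grid grid resolution of the compiled boundary-posterior update
#'   used inside the simulation loop.
#' @return a trial table: the schedule columns plus `choice`, `feedback`,
#'   `lapse` and the latent traces `m`, `p_l`, `m_prime`, `b_mean`, `b_var`,
#'   `v_small`, `v_large` (NA where the model has no such latent).
#' @export
simulate_agent_session <- function(agent, schedule, lapse_rate = 0,
                                   n_grid = 501) {
  stopifnot(inherits(agent, "pdm_agent"),
            all(c("run", "trial", "stimulus", "criterion") %in%
                  names(schedule)))
  if (lapse_rate < 0 || lapse_rate > 1) stop("lapse_rate must be in [0, 1]")
  sim <- cpp_simulate(model_code(agent$model), unname(agent$params),
                      as.integer(schedule$stimulus),
                      as.integer(schedule$run),
                      as.numeric(schedule$criterion), lapse_rate,
                      as.integer(n_grid), 10.0)
  out <- cbind(schedule[c("run", "trial", "stimulus")],
               as.data.frame(sim), valid = TRUE)
  out
}

#' Write / read a trial table as CSV
#'
#' Column layout: `run, trial, stimulus, choice, feedback, lapse, m,
#' m_prime, b_mean, b_var, v_small, v_large` (latents optional).
#'
#' @param trials trial table.
#' @param path file path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path)
}
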