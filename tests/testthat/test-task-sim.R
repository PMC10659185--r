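# Task simulator: blocked stimulus sequences, the stochastic virtual
# criterion, run schedules, and the bulk simulation loop.

test_that("stimulus sequences are blocked permutations with exact level counts", {
  set.seed(1)
  s <- make_stimulus_sequence(170, 5)
  expect_equal(unname(table(s)), rep(34L, 5), ignore_attr = TRUE)
  for (b in seq(0, 165, by = 5))
    expect_setequal(s[(b + 1):(b + 5)], -2:2)
  set.seed(9); a <- make_stimulus_sequence(170, 5)
  set.seed(9); b <- make_stimulus_sequence(170, 5)
  expect_identical(a, b)
  expect_error(make_stimulus_sequence(171, 5), "divisible")
  expect_error(make_stimulus_sequence(170, 5, levels = -1:1), "levels")
})

test_that("feedback follows the virtual criterion, exactly so in the degenerate mode", {
  expect_equal(generate_feedback(2L, 1L, 0, 0), 1L)
  expect_equal(generate_feedback(-2L, 1L, 0, 0), 0L)
  expect_equal(generate_feedback(0L, 0L, 0.4, 0), 1L)  # criterion at 0.4 > 0
  expect_error(generate_feedback(0L, 1L, 0, -1), "sigma_true")
})

test_that("feedback veridicality matches the closed-form normal CDF and grows with |S|", {
  set.seed(5)
  n <- 2e5
  # P(true class = large) for S = 1 under mu = 0, sigma = 1.28
  fb <- generate_feedback(rep(1L, n), rep(1L, n), 0, 1.28)
  expect_equal(mean(fb), pnorm(1 / 1.28), tolerance = 0.005)
  expect_equal(pnorm(1 / 1.28), 0.7827, tolerance = 1e-4)
  fb0 <- generate_feedback(rep(0L, n), rep(1L, n), 0, 1.28)
  expect_equal(mean(fb0), 0.5, tolerance = 0.005)
  verid <- vapply(0:2, function(S)
    mean(generate_feedback(rep(S, n), rep(1L, n), 0, 1.28)), numeric(1))
  expect_true(all(diff(verid) > 0))
  expect_true(all(verid < 1))
  expect_equal(verid, pnorm(0:2 / 1.28), tolerance = 0.005)
})

test_that("run schedules switch the criterion mean inside the documented window", {
  set.seed(2)
  for (i in 1:10) {
    sch <- make_run_schedule(mu_true = 0.4)
    sw <- min(which(sch$mu_true != 0))
    expect_gte(sw, 40); expect_lte(sw, 50)
    expect_true(all(sch$mu_true[seq_len(sw - 1)] == 0))
    expect_true(all(sch$mu_true[sw:170] == 0.4))
  }
  expect_error(make_run_schedule(0.4, switch_trial = 30), "switch_trial")
  sch <- make_session_schedule(n_runs = 30)
  mu_by_run <- tapply(sch$mu_true, sch$run, function(m) m[170])
  expect_equal(unname(table(mu_by_run)), rep(10L, 3), ignore_attr = TRUE)
  expect_equal(unname(table(sch$stimulus)), rep(34L * 30, 5),
               ignore_attr = TRUE)
  expect_error(make_session_schedule(n_runs = 31), "divisible")
})

test_that("simulation respects lapse behavior at both extremes", {
  set.seed(3)
  sched <- make_session_schedule(n_runs = 9)
  ag <- base_agent(sigma_m = 0.5)
  tt <- simulate_agent_session(ag, sched, lapse_rate = 1)
  expect_true(all(tt$lapse == 1))
  expect_lt(abs(mean(tt$choice) - 0.5), 0.03)
  expect_lt(abs(mean(tt$choice[tt$stimulus == 2]) - 0.5), 0.06)
  tt0 <- simulate_agent_session(ag, sched, lapse_rate = 0)
  expect_true(all(tt0$lapse == 0))
})

test_that("noise-free base agent always chooses the true side of zero", {
  set.seed(4)
  sched <- make_session_schedule(n_runs = 3)
  tt <- simulate_agent_session(base_agent(1e-9), sched)
  off0 <- tt$stimulus != 0
  expect_true(all(tt$choice[off0] == as.integer(tt$stimulus[off0] > 0)))
  # feedback = correct exactly when the criterion lies on the choice's side
  expect_true(all(tt$feedback[off0] ==
    as.integer(tt$choice[off0] ==
                 as.integer(tt$stimulus[off0] > sched$criterion[off0]))))
})

test_that("the full pipeline is bit-reproducible under a fixed seed", {
  ag <- world_agent(0, 1, 1.5, 1.6, 0.5, 0.5)
  set.seed(77); s1 <- make_session_schedule(n_runs = 3)
  t1 <- simulate_agent_session(ag, s1)
  set.seed(77); s2 <- make_session_schedule(n_runs = 3)
  t2 <- simulate_agent_session(ag, s2)
  expect_identical(t1, t2)
})

test_that("base-agent choices are conditionally independent of the previous choice", {
  # stimuli are anticorrelated by the block design, so raw choice repetition
  # is below chance; conditioning on the current stimulus removes all
  # dependence for a memoryless observer
  set.seed(6)
  sched <- make_session_schedule(n_runs = 300)
  tt <- simulate_agent_session(base_agent(1.2), sched)
  nr <- nrow(tt)
  same_run <- tt$run[-1] == tt$run[-nr]
  s2 <- tt$stimulus[-1][same_run]
  c2 <- tt$choice[-1][same_run]
  c1 <- tt$choice[-nr][same_run]
  for (s in -2:2) {
    p_given_rep <- mean(c2[s2 == s & c1 == 1])
    p_marg <- mean(c2[s2 == s])
    expect_lt(abs(p_given_rep - p_marg), 0.02)
  }
})

test_that("trial tables round-trip through CSV", {
  set.seed(8)
  tt <- simulate_agent_session(value_agent(0, 1, 0.3, 8, 1),
                               make_session_schedule(n_runs = 3))
  path <- tempfile(fileext = ".csv")
  write_trials(tt, path)
  back <- read_trials(path)
  expect_equal(back$choice, tt$choice)
  expect_equal(back$v_large, tt$v_large, tolerance = 1e-12)
})

test_that("agent parameters round-trip through YAML", {
  ag <- world_agent(0.1, 1.2, 1.5, 1.6, 0.5, 0.5)
  path <- tempfile(fileext = ".yaml")
  write_agent_yaml(ag, path)
  back <- read_agent_yaml(path)
  expect_identical(back$model, "world")
  expect_equal(back$params, ag$params)
})
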