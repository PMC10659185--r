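# Cumulative-Gaussian psychometric fitting, bootstrap PSE, episode
# conditioning and pair maps.

test_that("the fit recovers the generating curve and respects symmetry", {
  lv <- -2:2
  cc <- counts_from_curve(pnorm((lv - 0.3) / 1.0), 1e4)
  f <- fit_psychometric(cc$level, cc$n, cc$k)
  expect_true(f$identifiable)
  expect_equal(f$pse, 0.30, tolerance = 0.02)
  expect_equal(f$slope_sd, 1.0, tolerance = 0.03)
  # symmetric proportions about zero pin the PSE at zero
  p <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  cc <- counts_from_curve(p, 1000)
  expect_equal(fit_psychometric(cc$level, cc$n, cc$k)$pse, 0,
               tolerance = 1e-6)
})

test_that("the 4-parameter variant nests the 2-parameter fit", {
  lv <- -2:2
  cc <- counts_from_curve(pnorm((lv - 0.2) / 0.9), 2000)
  f2 <- fit_psychometric(cc$level, cc$n, cc$k)
  f4 <- fit_psychometric(cc$level, cc$n, cc$k, include_lapse = TRUE)
  expect_equal(f4$pse, f2$pse, tolerance = 0.02)
  expect_lt(f4$guess + f4$lapse, 0.03)
  # and recovers true asymptote parameters when they are present
  p <- 0.04 + (1 - 0.04 - 0.06) * pnorm((lv - 0.1) / 0.8)
  cc <- counts_from_curve(p, 2e4)
  f <- fit_psychometric(cc$level, cc$n, cc$k, include_lapse = TRUE)
  expect_equal(f$guess, 0.04, tolerance = 0.015)
  expect_equal(f$lapse, 0.06, tolerance = 0.015)
})

test_that("all-identical responses are flagged non-identifiable, not extrapolated", {
  f <- fit_psychometric(-2:2, rep(50, 5), rep(0, 5))
  expect_false(f$identifiable)
  expect_true(is.na(f$pse))
  f <- fit_psychometric(-2:2, rep(50, 5), rep(50, 5), include_lapse = TRUE)
  expect_false(f$identifiable)
})

test_that("the PSE estimator is shift-equivariant", {
  set.seed(2)
  cc <- counts_from_curve(pnorm((-2:2 - 0.25) / 1.1), 500, exact = FALSE)
  f0 <- fit_psychometric(cc$level, cc$n, cc$k)
  f1 <- fit_psychometric(cc$level + 1.7, cc$n, cc$k)
  expect_equal(f1$pse, f0$pse + 1.7, tolerance = 1e-8)
})

test_that("bootstrap PSE collapses to the point estimate when sampling noise vanishes", {
  lv <- -2:2
  cc <- counts_from_curve(pnorm((lv - 0.1) / 0.5), 1e5)
  set.seed(3)
  bs <- bootstrap_pse(cc$level, cc$n, cc$k, n_boot = 200)
  expect_lt(abs(bs$pse - bs$pse_point), 1e-3)
  expect_lt(bs$se, 2e-3)
  expect_false(bs$flagged)
})

test_that("bootstrap SE scales like one over the square root of the trial count", {
  set.seed(4)
  lv <- -2:2
  p <- pnorm(lv / 1.2)
  ns <- c(200, 800, 3200, 12800)
  ses <- vapply(ns, function(n) {
    cc <- counts_from_curve(p, n)
    bootstrap_pse(cc$level, cc$n, cc$k, n_boot = 400)$se
  }, numeric(1))
  slope <- coef(lm(log(ses) ~ log(ns)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)
})

test_that("episode conditioning respects run boundaries and partitions trials", {
  trials <- data.frame(
    run = rep(1:2, each = 4), trial = rep(1:4, 2),
    stimulus = c(0, 1, 0, 2, 0, -1, 0, 1),
    choice = c(1, 1, 0, 1, 1, 0, 1, 1),
    feedback = c(1, 0, 1, 1, 1, 1, 0, 1))
  # (S=0, large, correct) occurs at rows 1, 5 (run starts) and none after
  pre <- condition_on_episode(trials, 0, 1, 1, -1L)
  expect_equal(nrow(pre), 0)
  post <- condition_on_episode(trials, 0, 1, 1, 1L)
  expect_equal(post$stimulus, c(1, -1))
  # totals over all 20 episodes at +1 equal the count of trials with a
  # same-run successor
  tot <- sum(vapply(seq_len(nrow(episode_table())), function(i) {
    e <- episode_table()[i, ]
    nrow(condition_on_episode(trials, e$stimulus, e$choice, e$feedback, 1L))
  }, numeric(1)))
  expect_equal(tot, 6)
  # empty selection returns an empty table, not an error
  expect_equal(nrow(condition_on_episode(trials, -2, 0, 0, 1L)), 0)
})

test_that("episode conditioning inherits the blocked-design stimulus dependency", {
  # stimuli are permuted within blocks of 5, so the level following a given
  # level is depleted at that level: P(S_next = s | S = s) = 1/25 (only via
  # a block boundary) while each other level gets 6/25
  set.seed(5)
  tt <- simulate_agent_session(base_agent(1.2),
                               make_session_schedule(n_runs = 300))
  sub <- condition_on_episode(tt, 0L, 1L, 1L, 1L)
  freq <- table(factor(sub$stimulus, levels = -2:2)) / nrow(sub)
  expect_lt(abs(freq[["0"]] - 1 / 25), 0.01)
  for (s in c("-2", "-1", "1", "2"))
    expect_lt(abs(freq[[s]] - 6 / 25), 0.02)
})

test_that("episode pair maps are column-normalized and time-reversal swaps directions", {
  set.seed(6)
  tt <- simulate_agent_session(value_agent(0, 1, 0.3, 8, 1),
                               make_session_schedule(n_runs = 30))
  mp <- episode_pair_map(tt, 1L)
  cs <- colSums(mp, na.rm = TRUE)
  expect_true(all(abs(cs[!is.na(colSums(mp))] - 1) < 1e-9))
  rev <- tt[rev(seq_len(nrow(tt))), ]
  expect_equal(episode_pair_map(rev, -1L), mp)
})

test_that("pair maps of an i.i.d. observer factorize given the stimulus schedule", {
  # with no latent state, successive episodes couple only through the
  # blocked stimulus design: P(ep2 | ep1) = P(C2, F2 | S2) P(S2 | S1)
  set.seed(7)
  tt <- simulate_agent_session(base_agent(1.2),
                               make_session_schedule(n_runs = 1200,
                                                     mu_values = 0))
  mp <- episode_pair_map(tt, 1L)
  ep <- episode_table()
  id <- match(paste(tt$stimulus, tt$choice, tt$feedback),
              paste(ep$stimulus, ep$choice, ep$feedback))
  marg <- tabulate(id, 20) / nrow(tt)
  p_s <- tapply(marg, ep$stimulus, sum)[as.character(ep$stimulus)]
  cf_given_s <- marg / p_s
  s_trans <- outer(ep$stimulus, ep$stimulus,
                   function(s2, s1) ifelse(s2 == s1, 1 / 25, 6 / 25))
  expected <- sweep(s_trans, 1, as.numeric(cf_given_s), "*")
  # rare conditioning episodes (nonveridical feedback at |S| = 2) have too
  # few occurrences for their columns to concentrate; check the rest
  n_cond <- tabulate(id[-length(id)], 20)
  common <- n_cond > 10000
  expect_gte(sum(common), 8)
  expect_lt(max(abs(mp[, common] - expected[, common]), na.rm = TRUE), 0.015)
})

test_that("history tables carry subtractive rows and flag thin cells as missing", {
  set.seed(8)
  tt <- simulate_agent_session(base_agent(1.2),
                               make_session_schedule(n_runs = 12))
  het <- history_effect_table(tt, n_boot = 100, min_trials = 50)
  expect_equal(nrow(het), 60)
  for (epi in unique(het$episode)) {
    rows <- het[het$episode == epi, ]
    r <- rows[rows$direction == "retrospective", ]
    p <- rows[rows$direction == "prospective", ]
    s <- rows[rows$direction == "subtractive", ]
    if (is.finite(r$pse) && is.finite(p$pse)) {
      expect_equal(s$pse, p$pse - r$pse)
      expect_equal(s$se, sqrt(p$se^2 + r$se^2))
    }
  }
  # rare nonveridical episodes at |S| = 2 with few runs stay missing
  expect_true(any(is.na(het$pse)))
})
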