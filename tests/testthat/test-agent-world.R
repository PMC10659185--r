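# BMBU: class-state deduction, boundary likelihood algebra, grid posterior,
# prior propagation and the full step.

test_that("class state is deduced from the choice-feedback pair", {
  expect_equal(deduce_class_state(1L, 1L), 1L)  # (large, correct) -> large
  expect_equal(deduce_class_state(0L, 0L), 1L)  # (small, incorrect) -> large
  expect_equal(deduce_class_state(1L, 0L), 0L)  # (large, incorrect) -> small
  expect_equal(deduce_class_state(0L, 1L), 0L)
  expect_equal(deduce_class_state(c(1L, 0L), c(1L, 1L)), c(1L, 0L))
})

test_that("boundary likelihoods marginalize to the Gaussian predictive and are symmetric at b = m'", {
  pars <- test_world_pars
  s2 <- pars[["sigma_mprime"]]^2 + pars[["sigma_m"]]^2 + pars[["sigma_s"]]^2
  b <- seq(-4, 4, length.out = 50)
  for (mp in seq(-3, 3, length.out = 7)) {
    ls <- boundary_likelihood(b, mp, 0L, pars)
    ll <- boundary_likelihood(b, mp, 1L, pars)
    expect_lt(max(abs(ls + ll - dnorm(mp, b, sqrt(s2)))), 1e-10)
  }
  expect_equal(boundary_likelihood(0.8, 0.8, 0L, pars),
               boundary_likelihood(0.8, 0.8, 1L, pars))
  expect_error(boundary_likelihood(0, 1, 1L, c(pars, recursive = TRUE) *
                                     c(1, 1, 0, 1, 1, 1)), "sigma_s")
})

test_that("closed-form boundary likelihood matches brute-force double quadrature", {
  cases <- expand.grid(b = c(-1, 0, 0.7), mp = c(-0.5, 1, 2), cl = 0:1)
  for (i in seq_len(nrow(cases))) {
    got <- boundary_likelihood(cases$b[i], cases$mp[i], cases$cl[i],
                               c(mu0 = 0, sigma_m = 0.6, sigma_s = 1,
                                 sigma_0 = 1, sigma_mprime = 0.8,
                                 sigma_diffusion = 0))
    want <- quad_boundary_likelihood(cases$b[i], cases$mp[i], cases$cl[i],
                                     sigma_m = 0.6, sigma_mprime = 0.8,
                                     sigma_s = 1)
    expect_lt(abs(got - want), 1e-8)
  }
})

test_that("grid posterior is normalized and matches a fine-grid refinement oracle", {
  pars <- test_world_pars
  set.seed(3)
  for (i in 1:10) {
    bel <- boundary_belief(runif(1, -1, 1), runif(1, 0.05, 2))
    mp <- runif(1, -3, 3); cl <- rbinom(1, 1, 0.5)
    post <- posterior_update(bel, mp, cl, pars)
    h <- diff(post$grid$b[1:2])
    w <- rep(h, length(post$grid$b)); w[c(1, length(w))] <- h / 2
    expect_equal(sum(w * post$grid$density), 1, tolerance = 1e-6)
    ref <- finegrid_posterior(bel, mp, cl, pars)
    expect_equal(post$mean, ref$mean, tolerance = 1e-4)
    expect_equal(post$variance, ref$variance, tolerance = 1e-4)
  }
})

test_that("compiled posterior update agrees with the R grid implementation", {
  pars <- test_world_pars
  sM2 <- pars[["sigma_mprime"]]^2 + pars[["sigma_m"]]^2
  set.seed(4)
  for (i in 1:20) {
    pm <- runif(1, -2, 2); pv <- runif(1, 0.02, 3)
    mp <- runif(1, -4, 4); cl <- rbinom(1, 1, 0.5)
    r_post <- posterior_update(boundary_belief(pm, pv), mp, cl, pars,
                               n_grid = 4001, keep_grid = FALSE)
    cpp <- pdmfeedback:::cpp_bmbu_posterior(pm, pv, mp, cl, sM2,
                                            pars[["sigma_s"]]^2, 501L, 10)
    expect_equal(cpp[1], r_post$mean, tolerance = 1e-6)
    expect_equal(cpp[2], r_post$variance, tolerance = 1e-6)
  }
})

test_that("a near-degenerate prior dominates the posterior", {
  pars <- test_world_pars
  # tight (but grid-resolvable) prior: the posterior mean barely moves
  post <- posterior_update(boundary_belief(0.4, 0.01), 2, 1L, pars)
  expect_lt(abs(post$mean - 0.4), 0.02)
  # exactly degenerate prior in the compiled path: returned unchanged
  cpp <- pdmfeedback:::cpp_bmbu_posterior(0.4, 0, 2, 1L, 1.25, 2.25, 501L, 10)
  expect_equal(cpp, c(0.4, 0))
})

test_that("posterior mean increases with the mnemonic measurement", {
  pars <- test_world_pars
  for (cl in 0:1) {
    m <- vapply(seq(-2, 2, length.out = 15), function(mp)
      posterior_update(boundary_belief(0, 0.8), mp, cl, pars,
                       keep_grid = FALSE)$mean, numeric(1))
    expect_true(all(diff(m) > 0))
  }
})

test_that("prior propagation follows the decay-and-diffusion rule and its limits", {
  pars <- test_world_pars
  # lambda -> 1: zero posterior variance keeps the mean, variance = diffusion
  pr <- propagate_prior(boundary_belief(0.9, 0), pars)
  expect_equal(pr$mean, 0.9)
  expect_equal(pr$variance, pars[["sigma_diffusion"]]^2)
  # lambda -> 0: huge posterior variance collapses to mu0
  pars2 <- pars; pars2[["mu0"]] <- -0.3
  pr <- propagate_prior(boundary_belief(5, 1e8), pars2)
  expect_equal(pr$mean, -0.3, tolerance = 1e-6)
  # arithmetic case: sigma_0^2 = 1, post = (2, 1), mu0 = 0, diff^2 = 0.1
  pars3 <- c(mu0 = 0, sigma_m = 1, sigma_s = 1, sigma_0 = 1,
             sigma_mprime = 0, sigma_diffusion = sqrt(0.1))
  pr <- propagate_prior(boundary_belief(2, 1), pars3)
  expect_equal(pr$mean, 1)
  expect_equal(pr$variance, 0.6)
})

test_that("single-episode updates push the boundary in the informed direction", {
  # diffuse prior, no memory noise: CL = large after an ambiguous stimulus
  # pushes the boundary below the prior mean; a remembered m' = 2 pulls it
  # above the prior mean despite the same class state.
  pars <- c(mu0 = 0, sigma_m = 1, sigma_s = 1.5, sigma_0 = 5,
            sigma_mprime = 0, sigma_diffusion = 0)
  post0 <- posterior_update(boundary_belief(0, 25), 0, 1L, pars)
  expect_lt(post0$mean, 0)
  post2 <- posterior_update(boundary_belief(0, 25), 2, 1L, pars)
  expect_gt(post2$mean, 0)
})

test_that("decisions compare the measurement to the believed boundary", {
  bel <- boundary_belief(0.5, 0.2)
  d <- decide(1.5, bel, 1)
  expect_equal(d$p_l, 0.841345, tolerance = 1e-6)
  expect_equal(d$choice, 1L)
  expect_equal(decide(-0.5, bel, 1)$choice, 0L)
  # shifting the boundary up strictly lowers p_L
  p <- vapply(seq(-1, 1, 0.25), function(b)
    decide(0.3, boundary_belief(b, 0.2), 1)$p_l, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("bmbu_step is reproducible and logs coherent latents", {
  pars <- test_world_pars
  set.seed(7)
  s1 <- bmbu_step(boundary_belief(0, 1.6^2), 1L, 0.3, pars, n_grid = 501)
  set.seed(7)
  s2 <- bmbu_step(boundary_belief(0, 1.6^2), 1L, 0.3, pars, n_grid = 501)
  expect_identical(s1, s2)
  expect_true(s1$choice %in% 0:1)
  expect_equal(s1$feedback,
               as.integer(s1$choice == as.integer(1 > 0.3)))
})

test_that("with a rigid baseline prior BMBU reduces to the fixed-boundary observer", {
  # sigma_0 -> 0 forces lambda -> 0, pinning the boundary at mu0
  set.seed(11)
  ag <- world_agent(mu0 = 0.3, sigma_m = 1, sigma_s = 1.5, sigma_0 = 1e-3,
                    sigma_mprime = 0.5, sigma_diffusion = 0)
  sched <- make_session_schedule(n_runs = 120)
  tw <- simulate_agent_session(ag, sched)
  for (S in -2:2) {
    expect_lt(abs(mean(tw$choice[tw$stimulus == S]) - pnorm((S - 0.3) / 1)),
              0.015)
  }
})
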