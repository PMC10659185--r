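# Reference agents: Base, Fixed, and the Hybrid that stacks value updating
# on top of the BMBU-inferred boundary.

#' Reference-agent decision steps
#'
#' `base_step()` draws `m ~ N(S, sigma_m^2)` and chooses large iff `m > 0`;
#' `fixed_step()` compares against a free constant boundary `mu0`.  Both are
#' vectorized over stimuli.  Stochasticity comes from the measurement alone
#' (argmax readout on `p_L`).
#'
#' @param stimulus stimulus level(s).
#' @param params agent parameters (see [base_agent()], [fixed_agent()]).
#' @return integer choices (0 = small, 1 = large).
#' @export
base_step <- function(stimulus, params) {
  m <- rnorm(length(stimulus), stimulus, params[["sigma_m"]])
  as.integer(m > 0)
}

#' @rdname base_step
#' @export
fixed_step <- function(stimulus, params) {
  m <- rnorm(length(stimulus), stimulus, params[["sigma_m"]])
  as.integer(m > params[["mu0"]])
}

# Reference hybrid trial: decide against the BMBU boundary with softmax over
# value-weighted expected values; after feedback both the value update and
# the boundary update are applied from the same (m, m', CL).  The two
# updates are independent given the episode, so their order is immaterial.
hybrid_step_r <- function(state, stimulus, criterion, params, n_grid = 2001) {
  wp <- unlist(params)[model_par_names("world")]
  m <- rnorm(1, stimulus, params[["sigma_m"]])
  p_l <- belief_state(m, state$belief$mean, params[["sigma_m"]])
  q <- expected_values(p_l, state$v_small, state$v_large)
  choice <- softmax_choice(q$q_small, q$q_large, params[["beta"]])
  truth <- as.integer(stimulus > criterion)
  feedback <- as.integer(choice == truth)
  p_c <- if (choice == 1L) p_l else 1 - p_l
  upd <- value_update(state$v_small, state$v_large, choice, p_c, feedback,
                      params[["alpha"]])
  m_prime <- rnorm(1, m, params[["sigma_mprime"]])
  cl <- deduce_class_state(choice, feedback)
  post <- posterior_update(state$belief, m_prime, cl, wp, n_grid = n_grid,
                           keep_grid = FALSE)
  list(choice = choice, feedback = feedback, m = m, m_prime = m_prime,
       p_l = p_l,
       state = list(belief = propagate_prior(post, wp),
                    v_small = upd$v_small, v_large = upd$v_large))
}
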