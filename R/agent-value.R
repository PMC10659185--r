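# The belief-based reinforcement-learning ("value-updating") agent.
#
# Per trial: a noisy measurement m of the stimulus produces a belief state
# p_L (the probability that the stimulus lies above the boundary), the two
# options' expected values are the belief-state-weighted learned values, the
# choice is a softmax over expected values, and after feedback the chosen
# value is reinforced by the reward prediction error
#   delta = r - p_C * V_C,   r = 1 (correct) or 0 (incorrect),
# so that confidence p_C scales the update but never flips its direction.

#' Belief state: probability that the stimulus exceeds the boundary
#'
#' With the stimulus belief `p(S | m) = N(m, sigma_m^2)`, the probability of
#' the "large" class is `p_L = Phi((m - boundary) / sigma_m)`.
#'
#' @param m sensory measurement(s).
#' @param boundary class boundary.
#' @param sigma_m sensory noise SD (> 0).
#' @return `p_L`, same length as `m`.
#' @export
belief_state <- function(m, boundary, sigma_m) {
  if (any(!is.finite(m))) stop("non-finite measurement")
  if (sigma_m <= 0) stop("sigma_m must be > 0")
  pnorm((m - boundary) / sigma_m)
}

#' Expected values of the two options
#'
#' `Q_large = p_L * v_large`, `Q_small = (1 - p_L) * v_small`.
#'
#' @param p_l belief state in `[0, 1]`.
#' @param v_small,v_large learned option values.
#' @return list with `q_small` and `q_large`.
#' @export
expected_values <- function(p_l, v_small, v_large) {
  stopifnot(all(p_l >= 0 & p_l <= 1))
  list(q_small = (1 - p_l) * v_small, q_large = p_l * v_large)
}

#' Softmax readout
#'
#' `P(large) = exp(beta * q_large) / (exp(beta * q_small) + exp(beta *
#' q_large))`, computed overflow-safely.
#'
#' @param q_small,q_large expected values.
#' @param beta inverse temperature (>= 0).
#' @return probability of choosing large.
#' @export
softmax_prob <- function(q_small, q_large, beta) {
  if (any(beta < 0)) stop("beta must be >= 0")
  plogis(beta * (q_large - q_small))
}

#' @rdname softmax_prob
#' @return `softmax_choice()` draws the choice (0 = small, 1 = large).
#' @export
softmax_choice <- function(q_small, q_large, beta) {
  p <- softmax_prob(q_small, q_large, beta)
  as.integer(runif(length(p)) < p)
}

#' Reward-prediction-error update of the chosen value
#'
#' Only the chosen option's value changes:
#' `delta = r - p_c * V_C`; `V_C <- V_C + alpha * delta`.
#'
#' @param v_small,v_large current values.
#' @param choice 0 = small, 1 = large.
#' @param p_c belief state of the chosen option.
#' @param reward 1 for correct feedback, 0 for incorrect.
#' @param alpha learning rate in `[0, 1]`.
#' @return list with updated `v_small`, `v_large` and the prediction error
#'   `delta`.
#' @export
value_update <- function(v_small, v_large, choice, p_c, reward, alpha) {
  stopifnot(choice %in% c(0L, 1L), reward %in% c(0, 1),
            alpha >= 0, alpha <= 1)
  v_c <- if (choice == 1L) v_large else v_small
  delta <- reward - p_c * v_c
  v_c <- v_c + alpha * delta
  if (choice == 1L) v_large <- v_c else v_small <- v_c
  list(v_small = v_small, v_large = v_large, delta = delta)
}

# Pure-R reference step for the value agent; the bulk simulator runs the
# same computation in compiled code.
value_step_r <- function(agent, state, stimulus, criterion) {
  p <- agent$params
  m <- rnorm(1, stimulus, p[["sigma_m"]])
  p_l <- belief_state(m, p[["mu0"]], p[["sigma_m"]])
  q <- expected_values(p_l, state$v_small, state$v_large)
  choice <- softmax_choice(q$q_small, q$q_large, p[["beta"]])
  truth <- as.integer(stimulus > criterion)
  feedback <- as.integer(choice == truth)
  p_c <- if (choice == 1L) p_l else 1 - p_l
  upd <- value_update(state$v_small, state$v_large, choice, p_c, feedback,
                      p[["alpha"]])
  list(choice = choice, feedback = feedback, m = m, p_l = p_l,
       state = list(v_small = upd$v_small, v_large = upd$v_large))
}
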