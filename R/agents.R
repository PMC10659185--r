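# Shared agent infrastructure: constructors, parameter order, bounds.
#
# Encodings used throughout the package:
#   choice:   0 = small, 1 = large
#   feedback: 0 = incorrect, 1 = correct
#   stimulus: integer level in -2..2 (one ring-size step per unit)

MODEL_NAMES <- c("base", "fixed", "value", "world", "hybrid")

#' Parameter names of a model, in the canonical order
#'
#' The order is the contract between the R surface and the compiled
#' simulation/likelihood core, and the order used by [default_bounds()] and
#' [fit_model()].
#'
#' @param model one of `"base"`, `"fixed"`, `"value"`, `"world"`, `"hybrid"`.
#' @return character vector of parameter names.
#' @export
model_par_names <- function(model) {
  model <- match.arg(model, MODEL_NAMES)
  switch(model,
    base   = "sigma_m",
    fixed  = c("mu0", "sigma_m"),
    value  = c("mu0", "sigma_m", "alpha", "beta", "v_init"),
    world  = c("mu0", "sigma_m", "sigma_s", "sigma_0", "sigma_mprime",
               "sigma_diffusion"),
    hybrid = c("mu0", "sigma_m", "sigma_s", "sigma_0", "sigma_mprime",
               "sigma_diffusion", "alpha", "beta", "v_init"))
}

model_code <- function(model) {
  match(match.arg(model, MODEL_NAMES), MODEL_NAMES)
}

validate_params <- function(model, params) {
  nm <- model_par_names(model)
  if (!all(nm %in% names(params)))
    stop("missing parameters for model '", model, "': ",
         paste(setdiff(nm, names(params)), collapse = ", "))
  params <- params[nm]
  if (any(!is.finite(params))) stop("parameters must be finite")
  chk_pos <- intersect(c("sigma_m", "sigma_s", "sigma_0"), nm)
  if (any(params[chk_pos] <= 0))
    stop(paste(chk_pos, collapse = "/"), " must be > 0")
  chk_nn <- intersect(c("sigma_mprime", "sigma_diffusion", "beta"), nm)
  if (any(params[chk_nn] < 0))
    stop(paste(chk_nn, collapse = "/"), " must be >= 0")
  if ("alpha" %in% nm && (params[["alpha"]] < 0 || params[["alpha"]] > 1))
    stop("alpha must lie in [0, 1]")
  params
}

new_agent <- function(model, params) {
  structure(list(model = model,
                 params = validate_params(model, unlist(params))),
            class = c(paste0(model, "_agent"), "pdm_agent"))
}

#' Observer-model constructors
#'
#' Five observer models span the model space:
#' * `base_agent()`: class boundary fixed at 0; choices are driven only by
#'   the noisy sensory measurement (1 parameter).
#' * `fixed_agent()`: boundary fixed at a free constant `mu0` (2 parameters).
#' * `value_agent()`: belief-based reinforcement learning; the boundary stays
#'   at `mu0` while the values of the two options are updated by
#'   confidence-weighted reward prediction errors and read out through a
#'   softmax (5 parameters).
#' * `world_agent()`: Bayesian boundary updating (BMBU); the boundary is the
#'   mean of a continually updated belief about the stimulus distribution,
#'   informed by the mnemonic measurement and the feedback-deduced class
#'   state (6 parameters).
#' * `hybrid_agent()`: value updating on top of the BMBU-inferred boundary
#'   (9 parameters).
#'
#' @param mu0 constant class boundary / long-run boundary attractor
#'   (stimulus-level units).
#' @param sigma_m sensory noise SD (> 0).
#' @param alpha learning rate in `[0, 1]`.
#' @param beta softmax inverse temperature (>= 0).
#' @param v_init initial value of both options.
#' @param sigma_s SD of the believed stimulus distribution (> 0).
#' @param sigma_0 baseline SD of the boundary prior (> 0); also sets the
#'   belief decay through `lambda = sigma_0^2 / (sigma_0^2 + post_var)`.
#' @param sigma_mprime memory (mnemonic measurement) noise SD (>= 0).
#' @param sigma_diffusion trial-to-trial diffusion SD of the boundary belief
#'   (>= 0).
#' @return an object of class `pdm_agent`.
#' @export
value_agent <- function(mu0, sigma_m, alpha, beta, v_init) {
  new_agent("value", list(mu0 = mu0, sigma_m = sigma_m, alpha = alpha,
                          beta = beta, v_init = v_init))
}

#' @rdname value_agent
#' @export
world_agent <- function(mu0, sigma_m, sigma_s, sigma_0, sigma_mprime,
                        sigma_diffusion) {
  new_agent("world", list(mu0 = mu0, sigma_m = sigma_m, sigma_s = sigma_s,
                          sigma_0 = sigma_0, sigma_mprime = sigma_mprime,
                          sigma_diffusion = sigma_diffusion))
}

#' @rdname value_agent
#' @export
base_agent <- function(sigma_m) new_agent("base", list(sigma_m = sigma_m))

#' @rdname value_agent
#' @export
fixed_agent <- function(mu0, sigma_m) {
  new_agent("fixed", list(mu0 = mu0, sigma_m = sigma_m))
}

#' @rdname value_agent
#' @export
hybrid_agent <- function(mu0, sigma_m, sigma_s, sigma_0, sigma_mprime,
                         sigma_diffusion, alpha, beta, v_init) {
  new_agent("hybrid", list(mu0 = mu0, sigma_m = sigma_m, sigma_s = sigma_s,
                           sigma_0 = sigma_0, sigma_mprime = sigma_mprime,
                           sigma_diffusion = sigma_diffusion, alpha = alpha,
                           beta = beta, v_init = v_init))
}

#' Build an agent from a model name and a named parameter vector
#' @param model model name.
#' @param params named numeric vector or list with the entries of
#'   [model_par_names()].
#' @export
make_agent <- function(model, params) {
  new_agent(match.arg(model, MODEL_NAMES), params)
}

#' @export
print.pdm_agent <- function(x, ...) {
  cat("<pdm_agent:", x$model, "model>\n")
  print(x$params)
  invisible(x)
}

#' Default box constraints for fitting
#'
#' SD-type parameters are bounded in `[0.01, 10]` stimulus-level units,
#' `alpha` in `[0, 1]`, `beta` in `[0, 50]`, `mu0` in `[-2, 2]` and `v_init`
#' in `[0, 5]`.
#'
#' @param model model name.
#' @return matrix with rows `lower`/`upper` and one column per parameter.
#' @export
default_bounds <- function(model) {
  nm <- model_par_names(model)
  lower <- c(mu0 = -2, sigma_m = 0.01, sigma_s = 0.01, sigma_0 = 0.01,
             sigma_mprime = 0, sigma_diffusion = 0, alpha = 0, beta = 0,
             v_init = 0)
  upper <- c(mu0 = 2, sigma_m = 10, sigma_s = 10, sigma_0 = 10,
             sigma_mprime = 10, sigma_diffusion = 10, alpha = 1, beta = 50,
             v_init = 5)
  rbind(lower = lower[nm], upper = upper[nm])
}

#' Read agent parameters from a YAML file
#'
#' The file holds `model:` and a `params:` mapping with the entries of
#' [model_par_names()].
#' @param path YAML file path.
#' @return a `pdm_agent`.
#' @export
read_agent_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  make_agent(cfg$model, unlist(cfg$params))
}

#' @rdname read_agent_yaml
#' @param agent a `pdm_agent` to serialize.
#' @export
write_agent_yaml <- function(agent, path) {
  yaml::write_yaml(list(model = agent$model, params = as.list(agent$params)),
                   path)
  invisible(path)
}
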