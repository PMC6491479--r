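# Posterior-mode (MAP) estimation, mainly used to validate the sampler
# against deterministic oracles: with no missing data and diffuse priors the
# mode of (alpha, beta, gamma) coincides with least squares on log
# concentration.

#' Posterior mode for one metabolite
#'
#' Maximizes the unconstrained-scale log-posterior with BFGS using the
#' analytic gradient, then maps the optimum back to the constrained scale.
#'
#' @param data a [cohort()].
#' @param metabolite metabolite name.
#' @param spec a [model_spec()].
#' @param scaling optional `scaling_spec`.
#' @return named numeric vector of parameter values at the mode.
#' @export
map_estimate <- function(data, metabolite, spec = model_spec(),
                         scaling = compute_scaling(data)) {
  md <- build_model(data, metabolite, spec, scaling, min_obs_rows = 10L)
  set.seed(0)
  init_fn <- make_init(md)
  u0 <- init_fn(1L)
  fn <- function(u) -lp_grad(u, md)$lp
  gr <- function(u) -lp_grad(u, md)$grad
  opt <- stats::optim(u0, fn, gr, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  constrain_u(opt$par, md)
}
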