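# Model fitting: one metabolite per fit, HMC over the joint posterior of
# regression parameters and imputed values.

#' Fit the Bayesian lognormal regression for one metabolite
#'
#' Builds the per-metabolite model (ethnicity-specific intercepts and HbA1c
#' slopes, covariate adjustment, imputation parameters for below-LOD cells,
#' QC-rejected cells and missing covariates) and samples its posterior with
#' Hamiltonian Monte Carlo. Initialization jitters each chain around empirical
#' moments of the observed data; a chain whose initial log-posterior is not
#' finite is re-initialized up to 10 times.
#'
#' @param data a [cohort()].
#' @param metabolite metabolite (panel column) name.
#' @param spec a [model_spec()].
#' @param sampler a [sampler_config()].
#' @param scaling optional `scaling_spec`; defaults to [compute_scaling()] on
#'   `data`.
#' @return An object of class `hbametab_fit` with the retained draws
#'   (iterations x chains x parameters array, constrained scale), the model
#'   layout, and sampler diagnostics. Methods: `print`, `summary`, `coef`,
#'   `plot`, [subgroup_slope()].
#' @examples
#' \donttest{
#' sim <- generate_cohort(sim_config(group_sizes = c(european = 60,
#'   ghanaian = 60, african_surinamese = 60), seed = 1))
#' fit <- fit_metabolite(sim$cohort, "isoleucine",
#'                       sampler = sampler_config(iterations = 400,
#'                                                warmup = 200, seed = 1))
#' summary(fit)
#' }
#' @export
fit_metabolite <- function(data, metabolite, spec = model_spec(),
                           sampler = sampler_config(),
                           scaling = compute_scaling(data)) {
  md <- build_model(data, metabolite, spec, scaling, min_obs_rows = 10L)
  fn <- function(u) lp_grad(u, md)
  init_fn <- make_init(md)
  t0 <- proc.time()[["elapsed"]]
  chains <- hmc_run(fn, init_fn, sampler)
  elapsed <- proc.time()[["elapsed"]] - t0

  keep <- sampler$iterations - sampler$warmup
  draws <- array(NA_real_, c(keep, sampler$chains, md$d),
                 dimnames = list(NULL, NULL, md$names))
  for (ch in seq_along(chains)) {
    dm <- chains[[ch]]$draws
    for (it in seq_len(keep)) dm[it, ] <- constrain_u(dm[it, ], md)
    draws[, ch, ] <- dm
  }
  divergences <- sum(vapply(chains, `[[`, 0L, "divergences"))

  fit <- structure(list(draws = draws, model = md, spec = spec,
                        sampler = sampler, scaling = scaling,
                        metabolite = metabolite,
                        divergences = divergences, elapsed = elapsed),
                   class = "hbametab_fit")
  # hard invariant: every retained below-LOD draw inside its bounds
  if (length(md$ilod)) {
    z <- draws[, , md$ilod, drop = FALSE]
    if (any(z <= 0) || any(z >= md$bound))
      stop("internal error: below-LOD draw outside (0, min observed)")
  }
  sm <- summary(fit)
  bad <- sm$rhat > 1.01
  if (any(bad, na.rm = TRUE))
    warning("metabolite '", metabolite, "': R-hat > 1.01 for ",
            sum(bad, na.rm = TRUE), " parameter(s); chains may not have mixed")
  fit$summary <- sm
  fit
}

# chain initialization: empirical-moment centers with per-chain jitter
make_init <- function(md) {
  t_obs <- md$t_obs
  m_t <- mean(t_obs)
  s_t <- if (length(t_obs) > 1L) max(stats::sd(t_obs), 1e-2) else 0.5
  alpha0 <- vapply(1:3, function(g) {
    sel <- intersect(md$idx_obs, md$idx_e[[g]])
    if (length(sel)) mean(t_obs[match(sel, md$idx_obs)]) else m_t
  }, 0)
  center_h <- md$scaling$center_hba1c
  center_b <- md$scaling$center_bmi
  function(chain) {
    u <- numeric(md$d)
    u[md$ia] <- alpha0 + stats::rnorm(3, 0, 0.2)
    u[c(md$ib, md$ieta, md$ig)] <- stats::rnorm(md$n_beta +
                                                  length(md$ieta) +
                                                  length(md$ig), 0, 0.1)
    if (length(md$isig)) u[md$isig] <- log(s_t) + stats::rnorm(1, 0, 0.2)
    if (length(md$ixh)) {
      u[md$imh_mu] <- log(center_h) + stats::rnorm(3, 0, 0.05)
      u[md$imh_s] <- log(5) + stats::rnorm(3, 0, 0.2)
      u[md$ixh] <- stats::rnorm(length(md$ixh), 0, 0.5)
    }
    if (length(md$ixb)) {
      u[md$imb_mu] <- log(center_b) + stats::rnorm(3, 0, 0.05)
      u[md$imb_s] <- log(5) + stats::rnorm(3, 0, 0.2)
      u[md$ixb] <- stats::rnorm(length(md$ixb), 0, 0.5)
    }
    if (length(md$ilod)) u[md$ilod] <- stats::rnorm(length(md$ilod), 0, 0.5)
    if (length(md$iqc)) u[md$iqc] <- stats::rnorm(length(md$iqc), m_t, s_t)
    u
  }
}

#' @export
print.hbametab_fit <- function(x, ...) {
  md <- x$model
  cat("Bayesian lognormal regression fit: ", x$metabolite, "\n", sep = "")
  cat("  n = ", md$n, " (", length(md$idx_obs), " observed, ",
      length(md$idx_lod), " below LOD, ", length(md$idx_qc),
      " QC-rejected)\n", sep = "")
  cat("  slope structure: ", x$spec$slope_structure, "\n", sep = "")
  cat("  ", x$sampler$chains, " chains x ", x$sampler$iterations,
      " iterations (", x$sampler$warmup, " warmup); ",
      x$divergences, " divergences\n", sep = "")
  sl <- subgroup_table(x)
  cat("HbA1c slopes (per 10 mmol/mol, posterior mean [95% CI]):\n")
  lab <- paste0(format(sl$ethnicity), " ", format(sl$glycemic_status), " ",
                format(sl$sex))
  for (i in seq_len(nrow(sl)))
    cat(sprintf("  %s % .3f [% .3f, % .3f]\n", lab[i], sl$coefficient[i],
                sl$ci_low[i], sl$ci_high[i]))
  invisible(x)
}

#' @export
summary.hbametab_fit <- function(object, ...) {
  if (!is.null(object$summary)) return(object$summary)
  sm <- summarize_draws(object$draws)
  attr(sm, "metabolite") <- object$metabolite
  sm
}

#' @export
coef.hbametab_fit <- function(object, ...) {
  md <- object$model
  idx <- c(md$ia, md$ib, md$ieta, md$ig, md$isig)
  apply(object$draws[, , idx, drop = FALSE], 3L, mean)
}

#' @export
subgroup_slope.hbametab_fit <- function(object, ethnicity, sex, diabetic, ...) {
  status <- if (as.logical(diabetic)) "diabetic" else "prediabetic"
  fully <- object$model$fully
  nm <- if (fully) paste0("beta[", ethnicity, ",", status, ",", sex, "]")
        else paste0("beta[", ethnicity, ",", status, "]")
  b <- as.vector(object$draws[, , nm])
  if (!fully && sex == "female") b <- b + as.vector(object$draws[, , "eta"])
  b
}

# all 12 subgroup slope records for one fit, composed draw-wise
subgroup_table <- function(fit) {
  grid <- expand.grid(sex = c("male", "female"),
                      glycemic_status = c("prediabetic", "diabetic"),
                      ethnicity = .ethnicities,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("ethnicity", "sex", "glycemic_status")]
  rec <- lapply(seq_len(nrow(grid)), function(i) {
    dr <- subgroup_slope(fit, grid$ethnicity[i], grid$sex[i],
                         grid$glycemic_status[i] == "diabetic")
    q <- stats::quantile(dr, c(0.025, 0.975), names = FALSE)
    mat <- matrix(dr, nrow = dim(fit$draws)[1L])
    data.frame(metabolite = fit$metabolite, grid[i, , drop = FALSE],
               coefficient = mean(dr), ci_low = q[1L], ci_high = q[2L],
               proportional_change = proportional_change(mean(dr)),
               rhat = rhat(mat), ess = ess(mat),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}

#' Forest plot of subgroup HbA1c slopes
#'
#' Posterior means and 95% credible intervals of the slope per 10 mmol/mol
#' HbA1c for all 12 ethnicity x sex x status subgroups of one fitted
#' metabolite.
#'
#' @param x an `hbametab_fit`.
#' @param ... passed to [graphics::plot()].
#' @return the subgroup table, invisibly.
#' @export
plot.hbametab_fit <- function(x, ...) {
  sl <- subgroup_table(x)
  k <- nrow(sl)
  ylim <- c(0.5, k + 0.5)
  xlim <- range(sl$ci_low, sl$ci_high, 0)
  graphics::plot(sl$coefficient, k:1, xlim = xlim, ylim = ylim, pch = 19,
                 yaxt = "n", xlab = "slope per 10 mmol/mol HbA1c", ylab = "",
                 main = x$metabolite, ...)
  graphics::segments(sl$ci_low, k:1, sl$ci_high, k:1)
  graphics::abline(v = 0, lty = 3)
  lab <- paste(sl$ethnicity, sl$glycemic_status, sl$sex)
  graphics::axis(2, at = k:1, labels = lab, las = 1, cex.axis = 0.6)
  invisible(sl)
}
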