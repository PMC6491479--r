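# The per-metabolite Bayesian lognormal regression.
#
# For participant i with ethnicity e, sex f (1 = female), diabetic status d
# (1 = diabetic) and scaled covariates (hba1c_u, age_u, bmi_u):
#
#   log y_i ~ Normal(mu_i, sigma)
#   mu_i = alpha[e] + (beta[e,d] + eta * f) * hba1c_u
#          + gamma_sex * f + gamma_age * age_u + gamma_diab * d
#          + gamma_bmi * bmi_u
#
# Missing data are parameters: a below-LOD concentration is constrained to
# (0, minimal observed value of that metabolite); a QC-rejected concentration
# is a positive parameter with the lognormal likelihood as its only density
# (marginalizing it out); a missing HbA1c or BMI covariate is a parameter with
# a Normal(mu_x[e], s_x[e]) imputation density whose ethnicity-specific mean
# and SD carry exponential hyperpriors on the raw measurement scale.

#' Prior specification
#'
#' Regularizing priors: Normal(0, `coef_sd`) on every intercept and coefficient
#' of the scaled covariates, Exponential(`sigma_rate`) on the residual SD.
#' The covariate-imputation hyperpriors are exponential on the raw scale:
#' rate 0.025 for the HbA1c imputation mean (prior mean 40 mmol/mol), rate
#' 0.04 for the BMI imputation mean (prior mean 25 kg/m^2), and rate 0.2 for
#' both imputation SDs (prior mean 5).
#'
#' @param coef_sd SD of the Normal prior on coefficients.
#' @param sigma_rate rate of the Exponential prior on the residual SD.
#' @param hba1c_mean_rate,hba1c_sd_rate,bmi_mean_rate,bmi_sd_rate exponential
#'   hyperprior rates for the covariate-imputation mean/SD parameters.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(coef_sd = 1, sigma_rate = 1,
                       hba1c_mean_rate = 0.025, hba1c_sd_rate = 0.2,
                       bmi_mean_rate = 0.04, bmi_sd_rate = 0.2) {
  stopifnot(coef_sd > 0, sigma_rate > 0, hba1c_mean_rate > 0,
            hba1c_sd_rate > 0, bmi_mean_rate > 0, bmi_sd_rate > 0)
  structure(list(coef_sd = coef_sd, sigma_rate = sigma_rate,
                 hba1c_mean_rate = hba1c_mean_rate,
                 hba1c_sd_rate = hba1c_sd_rate,
                 bmi_mean_rate = bmi_mean_rate, bmi_sd_rate = bmi_sd_rate),
            class = "prior_spec")
}

#' Prior means of the covariate-imputation hyperpriors
#'
#' The Exponential(rate) prior has mean 1/rate; with the default rates the
#' HbA1c imputation mean and SD have prior means 40 and 5 mmol/mol, and the
#' BMI imputation mean has prior mean 25 kg/m^2.
#'
#' @param priors a [prior_spec()].
#' @return named numeric vector of prior means.
#' @export
imputation_prior_means <- function(priors = prior_spec()) {
  c(hba1c_mean = 1 / priors$hba1c_mean_rate,
    hba1c_sd = 1 / priors$hba1c_sd_rate,
    bmi_mean = 1 / priors$bmi_mean_rate,
    bmi_sd = 1 / priors$bmi_sd_rate)
}

#' Model specification
#'
#' `slope_structure` chooses the HbA1c-slope parameterization:
#' `"ethnicity_x_diabetes_plus_sex_offset"` (default) uses one slope per
#' ethnicity x diabetic-status cell plus a single additive female offset `eta`
#' (7 slope parameters); `"fully_crossed"` uses one slope per ethnicity x
#' status x sex cell (12 parameters, no `eta`).
#'
#' @param slope_structure see above.
#' @param include_bmi adjust for BMI (and impute missing BMI)?
#' @param priors a [prior_spec()].
#' @param fixed_sigma if non-`NULL`, the residual SD is held at this known
#'   value instead of being sampled (used for closed-form validation
#'   subcases).
#' @return A `model_spec` list.
#' @export
model_spec <- function(slope_structure = c("ethnicity_x_diabetes_plus_sex_offset",
                                           "fully_crossed"),
                       include_bmi = TRUE, priors = prior_spec(),
                       fixed_sigma = NULL) {
  if (!is.null(fixed_sigma)) stopifnot(fixed_sigma > 0)
  structure(list(slope_structure = match.arg(slope_structure),
                 include_bmi = include_bmi, priors = priors,
                 fixed_sigma = fixed_sigma),
            class = "model_spec")
}

# ---- structured (constrained-space) densities -------------------------------

#' Linear predictor of the lognormal regression
#'
#' Evaluates `mu = alpha[e] + (beta[e,d] + eta*female)*hba1c_u + gamma_sex*female
#' + gamma_age*age_u + gamma_diab*diabetic + gamma_bmi*bmi_u`, vectorized over
#' rows. Under the fully crossed structure the slope is looked up directly per
#' (ethnicity, status, sex).
#'
#' @param params structured parameter list: `alpha` (named by ethnicity),
#'   `beta` (ethnicity x status matrix, or ethnicity x status x sex array for
#'   the fully crossed structure), `eta`, `gamma` (named `sex`,`age`,`diab`,
#'   `bmi`), `sigma`.
#' @param covars data frame from [scale_covariates()] (columns `hba1c_u`,
#'   `age_u`, `bmi_u`, `female`, `diabetic`).
#' @param ethnicity character vector of ethnicities, one per row.
#' @return numeric vector of expected log-concentrations.
#' @export
linear_predictor <- function(params, covars, ethnicity) {
  f <- covars$female
  d <- covars$diabetic
  status <- ifelse(d == 1, "diabetic", "prediabetic")
  if (length(dim(params$beta)) == 3L) {
    sex <- ifelse(f == 1, "female", "male")
    slope <- params$beta[cbind(ethnicity, status, sex)]
  } else {
    eta <- if (is.null(params$eta)) 0 else params$eta
    slope <- params$beta[cbind(ethnicity, status)] + eta * f
  }
  g <- params$gamma
  gb <- if (is.na(g["bmi"]) || is.null(g["bmi"])) 0 else g[["bmi"]]
  bmi_term <- if (gb == 0) 0 else gb * covars$bmi_u
  params$alpha[ethnicity] + slope * covars$hba1c_u +
    g[["sex"]] * f + g[["age"]] * covars$age_u + g[["diab"]] * d + bmi_term
}

#' Lognormal log-likelihood
#'
#' Log-density of the lognormal distribution: `-log y - log sigma -
#' log(2*pi)/2 - (log y - mu)^2 / (2 sigma^2)`; equivalently the Normal
#' log-density of `log y` minus `log y`.
#'
#' @param y positive concentration(s).
#' @param mu log-scale mean.
#' @param sigma log-scale SD (> 0).
#' @return log-density, vectorized.
#' @export
loglik_lognormal <- function(y, mu, sigma) {
  if (any(y <= 0)) stop("lognormal outcome must be positive")
  stopifnot(all(sigma > 0))
  ly <- log(y)
  -ly - log(sigma) - 0.5 * log(2 * pi) - (ly - mu)^2 / (2 * sigma^2)
}

#' Log-prior of the structured parameter vector
#'
#' Sum of Normal(0, s) log-densities over intercepts and coefficients,
#' Exponential log-densities over the residual SD and the imputation
#' hyperparameters, and Normal(mu_x[e], s_x[e]) log-densities over imputed
#' covariate values. Imputed outcome values (`z_lod`, `z_qc`) carry no extra
#' prior: their density is the (truncated) likelihood itself. Returns `-Inf`
#' outside the support.
#'
#' @param params structured parameter list (as in [linear_predictor()], plus
#'   optional `imput$hba1c`/`imput$bmi` with `mu`, `s` per ethnicity and
#'   `x_hba1c`, `x_bmi` imputed raw covariate values).
#' @param priors a [prior_spec()].
#' @return scalar log-density.
#' @export
log_prior <- function(params, priors = prior_spec()) {
  if (params$sigma <= 0) return(-Inf)
  coefs <- c(params$alpha, params$beta, params$eta, params$gamma)
  lp <- sum(stats::dnorm(coefs, 0, priors$coef_sd, log = TRUE)) +
    stats::dexp(params$sigma, priors$sigma_rate, log = TRUE)
  imp_block <- function(imp, x, mean_rate, sd_rate, eth) {
    if (is.null(imp)) return(0)
    if (any(imp$mu <= 0) || any(imp$s <= 0)) return(-Inf)
    val <- sum(stats::dexp(imp$mu, mean_rate, log = TRUE)) +
      sum(stats::dexp(imp$s, sd_rate, log = TRUE))
    if (length(x))
      val <- val + sum(stats::dnorm(x, imp$mu[eth], imp$s[eth], log = TRUE))
    val
  }
  lp + imp_block(params$imput$hba1c, params$x_hba1c,
                 priors$hba1c_mean_rate, priors$hba1c_sd_rate,
                 params$eth_hba1c) +
    imp_block(params$imput$bmi, params$x_bmi,
              priors$bmi_mean_rate, priors$bmi_sd_rate, params$eth_bmi)
}

#' Log-posterior (constrained space) for one metabolite
#'
#' Sums the lognormal log-likelihood over rows — observed concentrations use
#' the data, below-LOD cells use the imputed `z_lod` (which must lie strictly
#' between 0 and the metabolite's minimal observed value; otherwise the
#' density is `-Inf`), QC-rejected cells use the imputed positive `z_qc` —
#' plus [log_prior()]. Missing covariates are replaced by the imputed
#' `x_hba1c`/`x_bmi` before scaling.
#'
#' @param params structured parameter list; `z_lod` and `z_qc` ordered by row
#'   index within the metabolite's column.
#' @param data a [cohort()].
#' @param metabolite metabolite (column) name.
#' @param spec a [model_spec()].
#' @param scaling a `scaling_spec`.
#' @return scalar log-density.
#' @export
log_posterior <- function(params, data, metabolite, spec = model_spec(),
                          scaling = compute_scaling(data)) {
  md <- build_model(data, metabolite, spec, scaling, min_obs_rows = 1L)
  st <- data$status[, metabolite]
  bound <- md$bound
  z_lod <- params$z_lod
  z_qc <- params$z_qc
  if (length(z_lod) != length(md$idx_lod) || length(z_qc) != length(md$idx_qc))
    stop("z_lod/z_qc length must match the metabolite's missingness pattern")
  if (any(z_lod <= 0) || any(z_lod >= bound) || any(z_qc <= 0)) return(-Inf)
  if (params$sigma <= 0) return(-Inf)

  p <- data$participants
  if (length(md$idx_mh)) {
    if (length(params$x_hba1c) != length(md$idx_mh))
      stop("x_hba1c length mismatch")
    p$hba1c_mmol_mol[md$idx_mh] <- params$x_hba1c
    params$eth_hba1c <- p$ethnicity[md$idx_mh]
  }
  if (spec$include_bmi && length(md$idx_mb)) {
    if (length(params$x_bmi) != length(md$idx_mb)) stop("x_bmi length mismatch")
    p$bmi[md$idx_mb] <- params$x_bmi
    params$eth_bmi <- p$ethnicity[md$idx_mb]
  }
  covars <- scale_covariates(p, scaling)
  mu <- linear_predictor(params, covars, p$ethnicity)
  y <- data$conc[, metabolite]
  y[md$idx_lod] <- z_lod
  y[md$idx_qc] <- z_qc
  sum(loglik_lognormal(y, mu, params$sigma)) +
    log_prior(params, spec$priors)
}

#' Subgroup HbA1c slope
#'
#' The slope of log-concentration per 10 mmol/mol HbA1c for one ethnicity x
#' sex x status subgroup: `beta[e,d]` for males and `beta[e,d] + eta` for
#' females under the default structure; a direct lookup under the fully
#' crossed structure. Applied to a fitted model it is evaluated draw-wise and
#' returns the vector of posterior draws.
#'
#' @param object structured parameter list or `hbametab_fit`.
#' @param ethnicity,sex,diabetic subgroup selectors (`diabetic` logical or
#'   0/1).
#' @param ... unused.
#' @return scalar (parameter list) or numeric vector of draws (fit).
#' @export
subgroup_slope <- function(object, ethnicity, sex, diabetic, ...) {
  UseMethod("subgroup_slope")
}

#' @export
subgroup_slope.default <- function(object, ethnicity, sex, diabetic, ...) {
  status <- if (as.logical(diabetic)) "diabetic" else "prediabetic"
  if (length(dim(object$beta)) == 3L)
    return(object$beta[ethnicity, status, sex])
  b <- object$beta[ethnicity, status]
  if (sex == "female") b <- b + (if (is.null(object$eta)) 0 else object$eta)
  unname(b)
}

#' Proportional concentration change implied by a slope
#'
#' A lognormal regression coefficient `beta` per 10 mmol/mol HbA1c implies a
#' proportional concentration change of `exp(beta) - 1` per 10 mmol/mol.
#'
#' @param beta slope (vectorized).
#' @return fractional change.
#' @examples
#' proportional_change(0.14)  # +15.0%
#' @export
proportional_change <- function(beta) exp(beta) - 1

# ---- internal flat model ----------------------------------------------------

# Assemble everything the sampler needs for one metabolite: row covariates,
# missingness index sets, parameter layout on the unconstrained scale.
build_model <- function(data, metabolite, spec = model_spec(),
                        scaling = compute_scaling(data), min_obs_rows = 10L) {
  stopifnot(inherits(data, "cohort"))
  if (!metabolite %in% data$panel$name)
    stop("unknown metabolite: ", metabolite)
  st <- data$status[, metabolite]
  idx_obs <- which(st == "observed")
  if (length(idx_obs) < min_obs_rows)
    stop("metabolite '", metabolite, "': only ", length(idx_obs),
         " observed values (need >= ", min_obs_rows, ")")
  idx_lod <- which(st == "below_lod")
  idx_qc <- which(st == "qc_rejected")
  bound <- min(data$conc[idx_obs, metabolite])

  p <- data$participants
  cv <- scale_covariates(p, scaling)
  e <- match(p$ethnicity, .ethnicities)
  fully <- spec$slope_structure == "fully_crossed"
  k <- e + 3L * cv$diabetic + if (fully) 6L * cv$female else 0L
  n_beta <- if (fully) 12L else 6L

  idx_mh <- which(is.na(p$hba1c_mmol_mol))
  idx_mb <- if (spec$include_bmi) which(is.na(p$bmi)) else integer(0)
  if (!spec$include_bmi && anyNA(p$bmi)) cv$bmi_u[is.na(cv$bmi_u)] <- 0

  # unconstrained parameter layout
  nm_beta <- if (fully) {
    as.vector(outer(outer(.ethnicities, c("prediabetic", "diabetic"),
                          paste, sep = ","), c("male", "female"), paste, sep = ","))
  } else {
    as.vector(outer(.ethnicities, c("prediabetic", "diabetic"), paste, sep = ","))
  }
  sigma_fixed <- spec$fixed_sigma
  names_ <- c(paste0("alpha[", .ethnicities, "]"),
              paste0("beta[", nm_beta, "]"),
              if (!fully) "eta",
              "gamma_sex", "gamma_age", "gamma_diab",
              if (spec$include_bmi) "gamma_bmi",
              if (is.null(sigma_fixed)) "sigma")
  ia <- 1:3
  ib <- 3L + seq_len(n_beta)
  ieta <- if (fully) integer(0) else 3L + n_beta + 1L
  ig0 <- 3L + n_beta + (if (fully) 0L else 1L)
  ng <- if (spec$include_bmi) 4L else 3L
  ig <- ig0 + seq_len(ng)
  isig <- if (is.null(sigma_fixed)) ig0 + ng + 1L else integer(0)
  pos <- ig0 + ng + length(isig)
  add <- function(nms) {
    i <- pos + seq_along(nms); pos <<- pos + length(nms)
    names_ <<- c(names_, nms); i
  }
  imh_mu <- imh_s <- imb_mu <- imb_s <- integer(0)
  ixh <- ixb <- integer(0)
  if (length(idx_mh)) {
    imh_mu <- add(paste0("mu_hba1c[", .ethnicities, "]"))
    imh_s <- add(paste0("s_hba1c[", .ethnicities, "]"))
    ixh <- add(paste0("x_hba1c[", idx_mh, "]"))
  }
  if (length(idx_mb)) {
    imb_mu <- add(paste0("mu_bmi[", .ethnicities, "]"))
    imb_s <- add(paste0("s_bmi[", .ethnicities, "]"))
    ixb <- add(paste0("x_bmi[", idx_mb, "]"))
  }
  ilod <- if (length(idx_lod)) add(paste0("z_lod[", idx_lod, "]")) else integer(0)
  iqc <- if (length(idx_qc)) add(paste0("z_qc[", idx_qc, "]")) else integer(0)

  idx_e <- lapply(1:3, function(g) which(e == g))
  idx_k <- lapply(seq_len(n_beta), function(g) which(k == g))

  list(metabolite = metabolite, spec = spec, priors = spec$priors,
       scaling = scaling, n = nrow(p), d = pos, names = names_,
       t_obs = log(data$conc[idx_obs, metabolite]),
       idx_obs = idx_obs, idx_lod = idx_lod, idx_qc = idx_qc, bound = bound,
       e = e, k = k, idx_e = idx_e, idx_k = idx_k, n_beta = n_beta,
       fully = fully,
       female = cv$female, diabetic = cv$diabetic,
       age_u = cv$age_u, h_u = cv$hba1c_u, b_u = cv$bmi_u,
       include_bmi = spec$include_bmi, sigma_fixed = sigma_fixed,
       idx_mh = idx_mh, idx_mb = idx_mb, e_mh = e[idx_mh], e_mb = e[idx_mb],
       ia = ia, ib = ib, ieta = ieta, ig = ig, isig = isig,
       imh_mu = imh_mu, imh_s = imh_s, ixh = ixh,
       imb_mu = imb_mu, imb_s = imb_s, ixb = ixb,
       ilod = ilod, iqc = iqc)
}

# log-posterior + gradient on the unconstrained scale (includes log-Jacobians
# of the exp / scaled-logit transforms of sigma, hyperparameters and z cells)
lp_grad <- function(u, md) {
  pr <- md$priors
  g <- numeric(md$d)

  alpha <- u[md$ia]
  beta <- u[md$ib]
  eta <- if (length(md$ieta)) u[md$ieta] else 0
  gam <- u[md$ig]
  g_bmi <- if (md$include_bmi) gam[4L] else 0
  sigma <- if (length(md$isig)) exp(u[md$isig]) else md$sigma_fixed

  # missing covariates sampled non-centered: x = mu_x[e] + s_x[e] * raw
  if (length(md$ixh)) {
    mu_h <- exp(u[md$imh_mu]); s_h <- exp(u[md$imh_s])
    x_h <- mu_h[md$e_mh] + s_h[md$e_mh] * u[md$ixh]
  }
  if (length(md$ixb)) {
    mu_b <- exp(u[md$imb_mu]); s_b <- exp(u[md$imb_s])
    x_b <- mu_b[md$e_mb] + s_b[md$e_mb] * u[md$ixb]
  }
  h_u <- md$h_u
  if (length(md$ixh)) h_u[md$idx_mh] <- (x_h - md$scaling$center_hba1c) / 10
  b_u <- md$b_u
  if (length(md$ixb)) b_u[md$idx_mb] <- (x_b - md$scaling$center_bmi) / 5

  slope <- beta[md$k] + if (md$fully) 0 else eta * md$female
  mu <- alpha[md$e] + slope * h_u + gam[1L] * md$female +
    gam[2L] * md$age_u + gam[3L] * md$diabetic +
    if (md$include_bmi) g_bmi * b_u else 0

  t <- numeric(md$n)
  t[md$idx_obs] <- md$t_obs
  jac <- 0
  if (length(md$ilod)) {
    pl <- stats::plogis(u[md$ilod])
    v <- log(md$bound) + log(pl)
    t[md$idx_lod] <- v
    jac <- jac + sum(log(md$bound) + log(pl) + log1p(-pl))
  }
  if (length(md$iqc)) t[md$idx_qc] <- u[md$iqc]

  resid <- t - mu
  sig2 <- sigma^2
  r <- resid / sig2
  ll <- -md$n * (log(sigma) + 0.5 * log(2 * pi)) - sum(resid^2) / (2 * sig2) -
    sum(md$t_obs) - (if (length(md$ilod)) sum(t[md$idx_lod]) else 0) + jac

  # coefficient gradients
  for (i in 1:3) g[md$ia[i]] <- sum(r[md$idx_e[[i]]])
  rh <- r * h_u
  for (i in seq_len(md$n_beta)) g[md$ib[i]] <- sum(rh[md$idx_k[[i]]])
  if (length(md$ieta)) g[md$ieta] <- sum(rh * md$female)
  g[md$ig[1L]] <- sum(r * md$female)
  g[md$ig[2L]] <- sum(r * md$age_u)
  g[md$ig[3L]] <- sum(r * md$diabetic)
  if (md$include_bmi) g[md$ig[4L]] <- sum(r * b_u)
  if (length(md$isig)) g[md$isig] <- sum(resid^2) / sig2 - md$n

  if (length(md$ilod)) {
    g[md$ilod] <- (-r[md$idx_lod] - 1) * (1 - pl) + (1 - 2 * pl)
  }
  if (length(md$iqc)) g[md$iqc] <- -r[md$idx_qc]

  # coefficient priors
  coef_idx <- c(md$ia, md$ib, md$ieta, md$ig)
  th <- u[coef_idx]
  ll <- ll + sum(stats::dnorm(th, 0, pr$coef_sd, log = TRUE))
  g[coef_idx] <- g[coef_idx] - th / pr$coef_sd^2
  # sigma ~ Exponential(rate), sampled as log(sigma)
  if (length(md$isig)) {
    ll <- ll + log(pr$sigma_rate) - pr$sigma_rate * sigma + u[md$isig]
    g[md$isig] <- g[md$isig] - pr$sigma_rate * sigma + 1
  }

  imp_part <- function(imu, is_, ix, ix_rows, e_m, mu_x, s_x, unit,
                       mean_rate, sd_rate, slope_x) {
    raw <- u[ix]
    # x enters the linear predictor through its scaled value; d x / d raw = s_x
    dldx <- r[ix_rows] * slope_x / unit
    g[ix] <<- dldx * s_x[e_m] - raw
    ll <<- ll + sum(stats::dnorm(raw, log = TRUE)) +
      sum(log(mean_rate) - mean_rate * mu_x + u[imu]) +
      sum(log(sd_rate) - sd_rate * s_x + u[is_])
    for (i in 1:3) {
      sel <- e_m == i
      g[imu[i]] <<- sum(dldx[sel]) * mu_x[i] - mean_rate * mu_x[i] + 1
      g[is_[i]] <<- sum(dldx[sel] * raw[sel]) * s_x[i] - sd_rate * s_x[i] + 1
    }
  }
  if (length(md$ixh))
    imp_part(md$imh_mu, md$imh_s, md$ixh, md$idx_mh, md$e_mh, mu_h, s_h,
             10, pr$hba1c_mean_rate, pr$hba1c_sd_rate, slope[md$idx_mh])
  if (length(md$ixb))
    imp_part(md$imb_mu, md$imb_s, md$ixb, md$idx_mb, md$e_mb, mu_b, s_b,
             5, pr$bmi_mean_rate, pr$bmi_sd_rate, g_bmi)
  list(lp = ll, grad = g)
}

# map an unconstrained draw to the constrained (reported) scale
constrain_u <- function(u, md) {
  out <- u
  if (length(md$isig)) out[md$isig] <- exp(u[md$isig])
  for (i in c(md$imh_mu, md$imh_s, md$imb_mu, md$imb_s))
    out[i] <- exp(u[i])
  if (length(md$ixh))
    out[md$ixh] <- out[md$imh_mu][md$e_mh] + out[md$imh_s][md$e_mh] * u[md$ixh]
  if (length(md$ixb))
    out[md$ixb] <- out[md$imb_mu][md$e_mb] + out[md$imb_s][md$e_mb] * u[md$ixb]
  if (length(md$ilod))
    out[md$ilod] <- md$bound * stats::plogis(u[md$ilod])
  if (length(md$iqc))
    out[md$iqc] <- exp(u[md$iqc])
  names(out) <- md$names
  out
}

# structured parameter list from a constrained named vector
structure_params <- function(cp, md) {
  beta <- cp[md$ib]
  if (md$fully) {
    beta <- array(beta, c(3, 2, 2),
                  dimnames = list(.ethnicities, c("prediabetic", "diabetic"),
                                  c("male", "female")))
  } else {
    beta <- matrix(beta, 3, 2,
                   dimnames = list(.ethnicities, c("prediabetic", "diabetic")))
  }
  gam <- cp[md$ig]
  names(gam) <- c("sex", "age", "diab", if (md$include_bmi) "bmi")
  out <- list(alpha = stats::setNames(cp[md$ia], .ethnicities), beta = beta,
              eta = if (length(md$ieta)) unname(cp[md$ieta]) else NULL,
              gamma = gam,
              sigma = if (length(md$isig)) unname(cp[md$isig]) else md$sigma_fixed)
  if (length(md$ixh)) {
    out$imput$hba1c <- list(mu = stats::setNames(cp[md$imh_mu], .ethnicities),
                            s = stats::setNames(cp[md$imh_s], .ethnicities))
    out$x_hba1c <- unname(cp[md$ixh])
  }
  if (length(md$ixb)) {
    out$imput$bmi <- list(mu = stats::setNames(cp[md$imb_mu], .ethnicities),
                          s = stats::setNames(cp[md$imb_s], .ethnicities))
    out$x_bmi <- unname(cp[md$ixb])
  }
  out$z_lod <- unname(cp[md$ilod])
  out$z_qc <- unname(cp[md$iqc])
  out
}
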