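test_that("linear predictor arithmetic", {
  params <- list(
    alpha = c(european = 0, ghanaian = 0, african_surinamese = 0),
    beta = matrix(0, 3, 2, dimnames = list(
      c("european", "ghanaian", "african_surinamese"),
      c("prediabetic", "diabetic"))),
    eta = 0,
    gamma = c(sex = 0, age = 0, diab = 0, bmi = 0), sigma = 1)
  row_male <- data.frame(hba1c_u = 1, age_u = 0, bmi_u = 0, female = 0,
                         diabetic = 0)
  expect_equal(linear_predictor(params, row_male, "european"), 0,
               ignore_attr = TRUE)

  params$beta["european", "prediabetic"] <- 0.14
  expect_equal(linear_predictor(params, row_male, "european"), 0.14,
               ignore_attr = TRUE)

  p2 <- params
  p2$beta[] <- 0.10
  p2$alpha[] <- 0.2
  p2$gamma["age"] <- -0.02
  row2 <- data.frame(hba1c_u = 1.5, age_u = 2, bmi_u = 0, female = 0,
                     diabetic = 0)
  expect_equal(linear_predictor(p2, row2, "european"), 0.31,
               ignore_attr = TRUE)
})

test_that("lognormal log-likelihood values and normalization", {
  expect_equal(loglik_lognormal(1, 0, 1), -0.5 * log(2 * pi))
  expect_equal(loglik_lognormal(exp(1), 1, 1), -1 - 0.5 * log(2 * pi))
  expect_error(loglik_lognormal(-1, 0, 1), "positive")
  # density integrates to 1
  dens <- function(y) exp(loglik_lognormal(y, 0, 0.5))
  expect_equal(integrate(dens, 1e-10, 50)$value, 1, tolerance = 1e-3)
  # change of variables: lognormal density = Normal(log y) - log y
  y <- c(0.3, 1, 2.7, 10)
  expect_equal(loglik_lognormal(y, 0.4, 0.7),
               dnorm(log(y), 0.4, 0.7, log = TRUE) - log(y))
})

test_that("imputation hyperpriors have the intended prior means", {
  m <- imputation_prior_means(prior_spec())
  expect_equal(m[["hba1c_mean"]], 40)
  expect_equal(m[["hba1c_sd"]], 5)
  expect_equal(m[["bmi_mean"]], 25)
  expect_equal(dexp(1, 1, log = TRUE), -1)
  expect_equal(dnorm(0, 0, 1, log = TRUE), -0.5 * log(2 * pi))
})

test_that("log-posterior equals likelihood plus prior on a hand-summed fixture", {
  x <- tiny_cohort(n_per_group = 1, k = 1)
  sc <- compute_scaling(x)
  params <- list(
    alpha = c(european = 4, ghanaian = 4.1, african_surinamese = 3.9),
    beta = matrix(0.1, 3, 2, dimnames = list(
      c("european", "ghanaian", "african_surinamese"),
      c("prediabetic", "diabetic"))),
    eta = 0.01, gamma = c(sex = 0.05, age = -0.02, diab = 0.1, bmi = 0.05),
    sigma = 0.4, z_lod = numeric(0), z_qc = numeric(0))
  lp <- log_posterior(params, x, x$panel$name[1], scaling = sc)
  # independent row-by-row summation
  cv <- scale_covariates(x$participants, sc)
  manual <- 0
  for (i in 1:3) {
    e <- x$participants$ethnicity[i]
    mu <- params$alpha[[e]] +
      (params$beta[e, ifelse(cv$diabetic[i] == 1, "diabetic", "prediabetic")] +
         params$eta * cv$female[i]) * cv$hba1c_u[i] +
      params$gamma[["sex"]] * cv$female[i] +
      params$gamma[["age"]] * cv$age_u[i] +
      params$gamma[["diab"]] * cv$diabetic[i] +
      params$gamma[["bmi"]] * cv$bmi_u[i]
    y <- x$conc[i, 1]
    manual <- manual + (-log(y) - log(0.4) - 0.5 * log(2 * pi) -
                          (log(y) - mu)^2 / (2 * 0.4^2))
  }
  manual <- manual +
    sum(dnorm(c(params$alpha, params$beta, params$eta, params$gamma), 0, 1,
              log = TRUE)) + dexp(0.4, 1, log = TRUE)
  expect_equal(lp, manual, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("below-LOD imputations above the minimal observed value are impossible", {
  x <- tiny_cohort(n_per_group = 4, k = 1)
  x$status[1, 1] <- "below_lod"
  x$conc[1, 1] <- NA_real_
  x <- validate_cohort(x)
  min_obs <- min(x$conc[, 1], na.rm = TRUE)
  params <- list(
    alpha = c(european = 4, ghanaian = 4, african_surinamese = 4),
    beta = matrix(0, 3, 2, dimnames = list(
      c("european", "ghanaian", "african_surinamese"),
      c("prediabetic", "diabetic"))),
    eta = 0, gamma = c(sex = 0, age = 0, diab = 0, bmi = 0), sigma = 0.5,
    z_qc = numeric(0))
  params$z_lod <- min_obs * 1.5
  expect_identical(log_posterior(params, x, x$panel$name[1]), -Inf)
  params$z_lod <- -1
  expect_identical(log_posterior(params, x, x$panel$name[1]), -Inf)
  params$z_lod <- min_obs * 0.5
  expect_true(is.finite(log_posterior(params, x, x$panel$name[1])))
})

test_that("unconstrained density matches the constrained contract up to Jacobians", {
  sim <- simulate_cohort(small_sim_config(seed = 21, lod_quantile = 0.1,
                                          qc_rate = 0.05))
  x <- sim$cohort
  md <- hbametab:::build_model(x, "isoleucine")
  for (s in 1:3) {
    set.seed(s)
    u <- hbametab:::make_init(md)(1)
    cp <- hbametab:::constrain_u(u, md)
    sp <- hbametab:::structure_params(cp, md)
    flat <- hbametab:::lp_grad(u, md)
    jac <- u[md$isig] +
      sum(u[c(md$imh_mu, md$imh_s, md$imb_mu, md$imb_s)])
    if (length(md$ilod)) {
      pl <- plogis(u[md$ilod])
      jac <- jac + sum(log(md$bound) + log(pl) + log1p(-pl))
    }
    if (length(md$iqc)) jac <- jac + sum(u[md$iqc])
    # non-centered covariate imputation contributes d x / d raw = s_x[e]
    if (length(md$ixh)) jac <- jac + sum(log(exp(u[md$imh_s])[md$e_mh]))
    if (length(md$ixb)) jac <- jac + sum(log(exp(u[md$imb_s])[md$e_mb]))
    expect_equal(flat$lp - jac,
                 log_posterior(sp, x, "isoleucine"), tolerance = 1e-8)
  }
})

test_that("analytic gradients match numerical differentiation", {
  sim <- simulate_cohort(small_sim_config(seed = 31, lod_quantile = 0.1,
                                          qc_rate = 0.05))
  x <- sim$cohort
  for (spec in list(model_spec(),
                    model_spec(slope_structure = "fully_crossed"),
                    model_spec(include_bmi = FALSE),
                    model_spec(fixed_sigma = 0.3))) {
    md <- hbametab:::build_model(x, "isoleucine", spec)
    set.seed(41)
    u <- hbametab:::make_init(md)(1)
    an <- hbametab:::lp_grad(u, md)$grad
    h <- 1e-6
    num <- vapply(seq_along(u), function(i) {
      u1 <- u; u1[i] <- u1[i] + h
      u2 <- u; u2[i] <- u2[i] - h
      (hbametab:::lp_grad(u1, md)$lp - hbametab:::lp_grad(u2, md)$lp) / (2 * h)
    }, 0)
    expect_equal(an, num, tolerance = 1e-4)
  }
})

test_that("subgroup slopes compose the female offset", {
  params <- list(
    alpha = c(european = 0, ghanaian = 0, african_surinamese = 0),
    beta = matrix(0.14, 3, 2, dimnames = list(
      c("european", "ghanaian", "african_surinamese"),
      c("prediabetic", "diabetic"))),
    eta = 0.01, gamma = c(sex = 0, age = 0, diab = 0, bmi = 0), sigma = 1)
  expect_equal(subgroup_slope(params, "european", "male", FALSE), 0.14)
  expect_equal(subgroup_slope(params, "european", "female", FALSE), 0.15)
  params$eta <- 0
  for (e in c("european", "ghanaian", "african_surinamese"))
    expect_equal(subgroup_slope(params, e, "female", TRUE),
                 subgroup_slope(params, e, "male", TRUE))
  # fully crossed: direct lookup
  pf <- params
  pf$beta <- array(seq(0.01, 0.12, by = 0.01), c(3, 2, 2), dimnames = list(
    c("european", "ghanaian", "african_surinamese"),
    c("prediabetic", "diabetic"), c("male", "female")))
  pf$eta <- NULL
  expect_equal(subgroup_slope(pf, "ghanaian", "female", TRUE), pf$beta[2, 2, 2])
})

test_that("slopes convert to proportional concentration changes", {
  expect_equal(proportional_change(0), 0)
  expect_equal(proportional_change(0.14), 0.1503, tolerance = 5e-4)
  expect_equal(proportional_change(-0.29), -0.2517, tolerance = 5e-4)
})
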