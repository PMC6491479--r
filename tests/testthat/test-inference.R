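# conjugate subcase: one homogeneous subgroup, all covariates at their
# centers, residual SD known -> the intercept posterior is Normal-Normal
conjugate_cohort <- function(n = 120, alpha_true = 4, sigma = 0.35,
                             seed = 55) {
  panel <- default_panel()[1, ]
  set.seed(seed)
  participants <- data.frame(
    id = sprintf("c%03d", 1:n), ethnicity = "european", sex = "male",
    age_years = 60, bmi = 30, fasting_glucose_mmol_l = 6,
    hba1c_mmol_mol = 45, glycemic_status = "prediabetic",
    stringsAsFactors = FALSE)
  conc <- matrix(exp(rnorm(n, alpha_true, sigma)), n, 1,
                 dimnames = list(NULL, panel$name))
  status <- matrix("observed", n, 1, dimnames = list(NULL, panel$name))
  cohort(participants, conc, status, panel)
}

test_that("the sampler reproduces the closed-form Normal-Normal posterior", {
  sigma <- 0.35
  x <- conjugate_cohort(sigma = sigma)
  n <- nrow(x$participants)
  t <- log(x$conc[, 1])
  s0 <- 1  # prior SD on the intercept
  post_var <- 1 / (n / sigma^2 + 1 / s0^2)
  post_mean <- post_var * sum(t) / sigma^2
  fit <- fit_metabolite(x, x$panel$name[1],
                        spec = model_spec(fixed_sigma = sigma),
                        sampler = fast_sampler(seed = 7, iterations = 1000,
                                               warmup = 500))
  sm <- summary(fit)
  a <- sm[sm$parameter == "alpha[european]", ]
  mcse_mean <- a$sd / sqrt(a$ess)
  expect_lt(abs(a$mean - post_mean), 3 * mcse_mean)
  mcse_sd <- a$sd / sqrt(2 * (a$ess - 1))
  expect_lt(abs(a$sd - sqrt(post_var)), 3 * mcse_sd + 0.02 * sqrt(post_var))
})

test_that("a known slope is recovered from a synthetic cohort", {
  sim <- simulate_cohort(small_sim_config(seed = 61, n_eur = 120, n_gha = 90,
                                          n_sur = 90))
  truth <- sim$truth$params$isoleucine$beta["european", "prediabetic"]
  fit <- fit_metabolite(sim$cohort, "isoleucine",
                        sampler = fast_sampler(seed = 8, iterations = 1000,
                                               warmup = 500))
  sm <- summary(fit)
  b <- sm[sm$parameter == "beta[european,prediabetic]", ]
  expect_lt(abs(b$mean - truth), 3 * b$sd)
  # all retained below-LOD draws inside their bounds
  md <- fit$model
  if (length(md$ilod)) {
    z <- fit$draws[, , md$ilod, drop = FALSE]
    expect_true(all(z > 0 & z < md$bound))
  }
})

test_that("an all-rejected outcome column raises an informative error", {
  x <- tiny_cohort(n_per_group = 5, k = 2)
  x$status[, 1] <- "qc_rejected"
  x$conc[, 1] <- NA_real_
  x <- validate_cohort(x)
  expect_error(fit_metabolite(x, x$panel$name[1]),
               x$panel$name[1])
})

test_that("fits are deterministic given the seed", {
  sim <- simulate_cohort(small_sim_config(seed = 71, n_eur = 30, n_gha = 25,
                                          n_sur = 25))
  f1 <- suppressWarnings(
    fit_metabolite(sim$cohort, "isoleucine",
                   sampler = fast_sampler(seed = 5, iterations = 300,
                                          warmup = 150)))
  f2 <- suppressWarnings(
    fit_metabolite(sim$cohort, "isoleucine",
                   sampler = fast_sampler(seed = 5, iterations = 300,
                                          warmup = 150)))
  expect_identical(f1$draws, f2$draws)
})

test_that("split R-hat flags disjoint chains and passes mixed ones", {
  expect_equal(rhat(matrix(5, 100, 4)), 1)
  disjoint <- cbind(rep(0, 100), rep(10, 100))
  expect_gt(rhat(disjoint), 1.1)
  set.seed(1)
  mixed <- matrix(rnorm(4000), 1000, 4)
  expect_lt(rhat(mixed), 1.01)
  # linear trend within chains inflates split R-hat
  trend <- matrix(rep(seq(0, 1, length.out = 100), 4), 100, 4)
  expect_gt(rhat(trend), 1.1)
})

test_that("effective sample size tracks autocorrelation", {
  set.seed(2)
  iid <- matrix(rnorm(4000), 1000, 4)
  e_iid <- ess(iid)
  expect_gte(e_iid, 3000)
  expect_lte(e_iid, 4000)
  # AR(1) with phi = 0.9: ESS ~ n (1 - phi) / (1 + phi)
  phi <- 0.9
  n <- 20000
  z <- numeric(n)
  set.seed(3)
  innov <- rnorm(n)
  for (i in 2:n) z[i] <- phi * z[i - 1] + innov[i]
  e_ar <- ess(matrix(z, ncol = 1))
  target <- n * (1 - phi) / (1 + phi)
  expect_gt(e_ar, target / 1.5)
  expect_lt(e_ar, target * 1.5)
  expect_equal(ess(matrix(7, 500, 2)), 1000)
})

test_that("posterior summaries report pooled means and percentile intervals", {
  draws <- array(rep(c(1, 2, 3, 4), each = 25), c(100, 2, 1),
                 dimnames = list(NULL, NULL, "theta"))
  draws[, 2, 1] <- rev(draws[, 1, 1])
  sm <- summarize_draws(draws)
  expect_equal(sm$mean, 2.5)
  const <- array(3, c(200, 2, 1), dimnames = list(NULL, NULL, "c"))
  smc <- summarize_draws(const)
  expect_equal(smc$sd, 0)
  expect_equal(smc$q97.5 - smc$q2.5, 0)
  set.seed(4)
  norm <- array(rnorm(4000), c(1000, 4, 1), dimnames = list(NULL, NULL, "z"))
  smn <- summarize_draws(norm)
  expect_equal(smn$q2.5, -1.96, tolerance = 0.1)
  expect_equal(smn$q97.5, 1.96, tolerance = 0.1)
})

test_that("posterior mode matches least squares when priors are diffuse", {
  sim <- simulate_cohort(small_sim_config(seed = 81, n_eur = 150, n_gha = 130,
                                          n_sur = 120, lod_quantile = 0,
                                          qc_rate = 0, hba1c_miss_rate = 0,
                                          bmi_miss_rate = 0))
  x <- sim$cohort
  mode <- map_estimate(x, "isoleucine",
                       spec = model_spec(priors = prior_spec(
                         coef_sd = 1e4, sigma_rate = 1e-8)))
  cv <- scale_covariates(x$participants, compute_scaling(x))
  e <- x$participants$ethnicity
  k <- paste0(e, cv$diabetic)
  df <- data.frame(t = log(x$conc[, 1]), cv, e = e, k = k)
  ols <- lm(t ~ 0 + e + k:hba1c_u + female:hba1c_u + female + age_u +
              diabetic + bmi_u, data = df)
  bo <- coef(ols)
  expect_equal(mode[["alpha[european]"]], bo[["eeuropean"]], tolerance = 1e-3)
  expect_equal(mode[["beta[european,prediabetic]"]],
               bo[["keuropean0:hba1c_u"]], tolerance = 1e-3)
  expect_equal(mode[["beta[ghanaian,diabetic]"]],
               bo[["kghanaian1:hba1c_u"]], tolerance = 1e-3)
  expect_equal(mode[["gamma_age"]], bo[["age_u"]], tolerance = 1e-3)
  expect_equal(mode[["eta"]], bo[["hba1c_u:female"]], tolerance = 1e-3)
})
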