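test_that("with sigma = 0 the generator is an exact linear-predictor evaluation", {
  panel <- default_panel()[1, ]
  tp <- default_true_params(panel, sigma = 0)
  # all coefficients zero except the intercept -> concentration is exp(alpha)
  tp0 <- tp
  tp0$isoleucine$beta[] <- 0
  tp0$isoleucine$eta <- 0
  tp0$isoleucine$gamma[] <- 0
  tp0$isoleucine$alpha[] <- log(60)
  cfg <- small_sim_config(seed = 5, true_params = tp0, lod_quantile = 0,
                          qc_rate = 0, hba1c_miss_rate = 0, bmi_miss_rate = 0)
  gen <- generate_cohort(cfg)
  expect_equal(unname(gen$cohort$conc[, 1]), rep(60, nrow(gen$cohort$participants)))

  # slope 0.14: two participants 10 mmol/mol apart differ by exactly 0.14 in
  # log concentration (same subgroup, all other covariates matched)
  tp1 <- tp
  tp1$isoleucine$eta <- 0
  tp1$isoleucine$gamma[] <- 0
  tp1$isoleucine$beta[] <- 0.14
  cfg1 <- small_sim_config(seed = 6, true_params = tp1, lod_quantile = 0,
                           qc_rate = 0, hba1c_miss_rate = 0, bmi_miss_rate = 0)
  gen1 <- generate_cohort(cfg1)
  x <- gen1$cohort
  cv <- scale_covariates(x$participants, gen1$truth$scaling)
  mu <- linear_predictor(tp1$isoleucine, cv, x$participants$ethnicity)
  expect_equal(log(x$conc[, 1]), mu, ignore_attr = TRUE, tolerance = 1e-12)
  i <- which(x$participants$ethnicity == "european" &
               x$participants$glycemic_status == "prediabetic")[1:2]
  p2 <- x$participants[i, ]
  p2$hba1c_mmol_mol <- c(40, 50)
  cv2 <- scale_covariates(p2, gen1$truth$scaling)
  mu2 <- linear_predictor(tp1$isoleucine, cv2, p2$ethnicity)
  expect_equal(diff(mu2), 0.14, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the generator is deterministic given the seed", {
  a <- simulate_cohort(small_sim_config(seed = 9, k = 2))
  b <- simulate_cohort(small_sim_config(seed = 9, k = 2))
  d <- simulate_cohort(small_sim_config(seed = 10, k = 2))
  expect_identical(a$cohort$conc, b$cohort$conc)
  expect_identical(a$cohort$participants, b$cohort$participants)
  expect_false(identical(a$cohort$conc, d$cohort$conc))
})

test_that("generated concentrations are strictly positive and statuses exclusive", {
  sim <- simulate_cohort(small_sim_config(seed = 2, k = 3, lod_quantile = 0.2,
                                          qc_rate = 0.2, hba1c_miss_rate = 0,
                                          bmi_miss_rate = 0))
  x <- sim$cohort
  expect_true(all(x$conc[x$status == "observed"] > 0))
  expect_true(all(x$status %in% c("observed", "below_lod", "qc_rejected")))
  expect_true(all(is.na(x$conc[x$status != "observed"])))
  # glucose consistent with assigned status
  p <- x$participants
  hba1c_pct <- p$hba1c_mmol_mol / 10.929 + 2.15
  expect_equal(assign_glycemic_status(p$fasting_glucose_mmol_l, hba1c_pct),
               p$glycemic_status)
})

test_that("LOD censoring hits the expected fraction of cells", {
  sim <- generate_cohort(small_sim_config(seed = 4, n_eur = 340, n_gha = 330,
                                          n_sur = 330))
  x <- sim$cohort  # 1000 participants, 1 metabolite
  cens <- apply_lod_censoring(x, 0.10)
  expect_equal(sum(cens$status == "below_lod"), 100, tolerance = 1)
  lod <- attr(cens, "lod_per_metabolite")
  expect_true(all(cens$conc[cens$status == "observed"] >= lod[1]))

  expect_equal(sum(apply_lod_censoring(x, 0)$status == "below_lod"), 0)
  # all-equal values: nothing strictly below the quantile
  xeq <- x
  xeq$conc[] <- 5
  expect_equal(sum(apply_lod_censoring(xeq, 0.5)$status == "below_lod"), 0)
  expect_error(apply_lod_censoring(x, 1), "< 1")
})

test_that("QC rejection is Bernoulli at the configured rate", {
  sim <- generate_cohort(small_sim_config(seed = 8, k = 10, n_eur = 340,
                                          n_gha = 330, n_sur = 330))
  x <- sim$cohort  # 10 000 cells
  expect_identical(apply_qc_rejection(x, 0, seed = 1)$status, x$status)
  all_rej <- apply_qc_rejection(x, 1, seed = 1)
  expect_true(all(all_rej$status == "qc_rejected"))
  hit <- sum(apply_qc_rejection(x, 0.05, seed = 3)$status == "qc_rejected")
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.05)
  expect_gte(hit, bounds[1])
  expect_lte(hit, bounds[2])
})

test_that("subgroup regression on a large noise-free-covariate simulation recovers the slope", {
  cfg <- sim_config(group_sizes = c(european = 10000, ghanaian = 5000,
                                    african_surinamese = 5000),
                    panel = {
                      p <- default_panel()[1, ]
                      class(p) <- c("metabolite_panel", "data.frame"); p
                    },
                    lod_quantile = 0, qc_rate = 0, hba1c_miss_rate = 0,
                    bmi_miss_rate = 0, seed = 77)
  gen <- generate_cohort(cfg)
  x <- gen$cohort
  truth <- gen$truth$params$isoleucine
  p <- x$participants
  sel <- p$ethnicity == "european" & p$glycemic_status == "prediabetic" &
    p$sex == "male"
  cv <- scale_covariates(p[sel, ], gen$truth$scaling)
  fitlm <- lm(log(x$conc[sel, 1]) ~ hba1c_u + age_u + bmi_u, data = cv)
  est <- coef(summary(fitlm))["hba1c_u", ]
  expect_lt(abs(est["Estimate"] - truth$beta["european", "prediabetic"]),
            2 * est["Std. Error"])
})

test_that("the truth sidecar records parameters, LODs and masked cells", {
  f_cohort <- withr::local_tempfile(fileext = ".csv")
  f_truth <- withr::local_tempfile(fileext = ".json")
  sim <- simulate_cohort(small_sim_config(seed = 12, k = 2), path = f_cohort,
                         truth_path = f_truth)
  tr <- jsonlite::fromJSON(f_truth)
  expect_named(tr, c("params", "scaling", "lod_per_metabolite", "qc_cells",
                     "seed"), ignore.order = TRUE)
  expect_equal(tr$params$isoleucine$sigma, 0.3)
  expect_equal(length(tr$lod_per_metabolite), 2L)
  y <- read_cohort(f_cohort, sim$cohort$panel)
  expect_equal(y$status, sim$cohort$status)
})
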