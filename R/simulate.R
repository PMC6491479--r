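# Synthetic three-group cohort generator. The generator draws demographics to
# match the study's per-group composition (sizes, sex mix, age/BMI/HbA1c
# moments, diabetic fractions), then produces each metabolite from the same
# lognormal linear predictor the model fits, and finally applies the two
# missingness mechanisms the model handles: below-LOD left-censoring at a
# per-metabolite empirical quantile, and completely-at-random QC rejection.

.tbl1 <- list(
  group_sizes = c(european = 301L, ghanaian = 255L, african_surinamese = 217L),
  female_prop = c(european = 0.445, ghanaian = 0.525, african_surinamese = 0.659),
  age_mean = c(european = 67.1, ghanaian = 51.2, african_surinamese = 55.2),
  age_sd = c(european = 5.4, ghanaian = 8.3, african_surinamese = 7.2),
  bmi_mean = c(european = 30.7, ghanaian = 29.6, african_surinamese = 31.2),
  bmi_sd = c(european = 3.5, ghanaian = 4.4, african_surinamese = 5.8),
  hba1c_mean = c(european = 41.7, ghanaian = 56.1, african_surinamese = 46.6),
  hba1c_sd = c(european = 7.9, ghanaian = 19.7, african_surinamese = 15.4),
  diabetic_prop = c(european = 0.126, ghanaian = 0.388, african_surinamese = 0.705)
)

#' Simulation configuration
#'
#' Defaults reproduce the study conditions: group sizes 301/255/217
#' (European / Ghanaian / African Surinamese), the corresponding female
#' fractions, age/BMI/HbA1c means and SDs, and diabetic fractions
#' 0.126/0.388/0.705. Diabetic participants draw HbA1c from a normal shifted
#' upward by `diabetic_hba1c_shift` (default +15 mmol/mol) so that diabetic
#' status and HbA1c correlate. Missingness defaults are a 5% below-LOD
#' quantile per metabolite, 2% QC rejection per cell, and 2% missing
#' HbA1c/BMI covariates.
#'
#' @param group_sizes,female_prop,diabetic_prop named per-group vectors.
#' @param age_mean,age_sd,bmi_mean,bmi_sd,hba1c_mean,hba1c_sd named per-group
#'   vectors in natural units.
#' @param diabetic_hba1c_shift mmol/mol added to the HbA1c mean of diabetics.
#' @param true_params ground-truth parameters, see [default_true_params()].
#' @param lod_quantile per-metabolite censoring quantile in `[0, 1)`.
#' @param qc_rate per-cell QC rejection probability.
#' @param hba1c_miss_rate,bmi_miss_rate per-participant covariate missingness
#'   probabilities.
#' @param panel a `metabolite_panel`.
#' @param seed integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(group_sizes = .tbl1$group_sizes,
                       female_prop = .tbl1$female_prop,
                       age_mean = .tbl1$age_mean, age_sd = .tbl1$age_sd,
                       bmi_mean = .tbl1$bmi_mean, bmi_sd = .tbl1$bmi_sd,
                       hba1c_mean = .tbl1$hba1c_mean,
                       hba1c_sd = .tbl1$hba1c_sd,
                       diabetic_prop = .tbl1$diabetic_prop,
                       diabetic_hba1c_shift = 15,
                       true_params = default_true_params(panel),
                       lod_quantile = 0.05, qc_rate = 0.02,
                       hba1c_miss_rate = 0.02, bmi_miss_rate = 0.02,
                       panel = default_panel(), seed = 1L) {
  need <- function(v) {
    stopifnot(all(.ethnicities %in% names(v)))
    v[.ethnicities]
  }
  stopifnot(all(group_sizes >= 2), all(female_prop >= 0 & female_prop <= 1),
            all(diabetic_prop >= 0 & diabetic_prop <= 1),
            all(age_sd > 0), all(bmi_sd > 0), all(hba1c_sd > 0),
            lod_quantile >= 0, lod_quantile < 1,
            qc_rate >= 0, qc_rate <= 1,
            hba1c_miss_rate >= 0, hba1c_miss_rate < 1,
            bmi_miss_rate >= 0, bmi_miss_rate < 1)
  structure(list(group_sizes = need(group_sizes),
                 female_prop = need(female_prop),
                 age_mean = need(age_mean), age_sd = need(age_sd),
                 bmi_mean = need(bmi_mean), bmi_sd = need(bmi_sd),
                 hba1c_mean = need(hba1c_mean), hba1c_sd = need(hba1c_sd),
                 diabetic_prop = need(diabetic_prop),
                 diabetic_hba1c_shift = diabetic_hba1c_shift,
                 true_params = true_params, lod_quantile = lod_quantile,
                 qc_rate = qc_rate, hba1c_miss_rate = hba1c_miss_rate,
                 bmi_miss_rate = bmi_miss_rate, panel = validate_panel(panel),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# slope magnitudes echoing the reported coefficient scale per analyte
.base_slopes <- c(
  isoleucine = 0.14, leucine = 0.06, valine = 0.06, tyrosine = 0.05,
  alanine = 0.10, phenylalanine = 0.05, glutamine = 0.04, histidine = 0.04,
  acetoacetate = -0.29, hydroxybutyrate_3 = -0.20,
  extremely_large_vldl_p = 0.47, very_large_vldl_p = 0.35,
  large_vldl_p = 0.30, medium_vldl_p = 0.20, small_vldl_p = 0.12,
  very_small_vldl_p = 0.08, idl_p = 0.04, large_ldl_p = 0.04,
  medium_ldl_p = 0.04, small_ldl_p = 0.06, very_large_hdl_p = -0.10,
  large_hdl_p = -0.20, medium_hdl_p = -0.05, small_hdl_p = 0.03)

.base_conc <- c(
  isoleucine = 60, leucine = 90, valine = 220, tyrosine = 70, alanine = 350,
  phenylalanine = 80, glutamine = 500, histidine = 80,
  acetoacetate = 40, hydroxybutyrate_3 = 100,
  extremely_large_vldl_p = 0.8, very_large_vldl_p = 2, large_vldl_p = 10,
  medium_vldl_p = 25, small_vldl_p = 40, very_small_vldl_p = 60,
  idl_p = 120, large_ldl_p = 180, medium_ldl_p = 140, small_ldl_p = 160,
  very_large_hdl_p = 300, large_hdl_p = 800, medium_hdl_p = 1600,
  small_hdl_p = 4500)

#' Default ground-truth parameters
#'
#' One structured parameter set per panel metabolite, on the coefficient scale
#' the model reports (log-concentration change per 10 mmol/mol HbA1c). Slope
#' magnitudes echo the reported per-analyte scale (e.g. 0.14 for isoleucine
#' and -0.29 for acetoacetate in prediabetic Europeans; triglyceride-rich
#' VLDL subclasses up to 0.47); the remaining subgroups scale that base slope
#' by a fixed attenuation grid (weaker in diabetics and in the non-European
#' groups). The female slope offset is `eta = 0.01`, covariate effects are
#' modest (`gamma_sex = 0.05`, `gamma_age = -0.02`, `gamma_diab = 0.1`,
#' `gamma_bmi = 0.05`) and the residual log-scale SD is `sigma = 0.3` for
#' every metabolite.
#'
#' @param panel a `metabolite_panel`.
#' @param sigma residual SD on the log scale.
#' @return A named list (class `true_params`) of per-metabolite parameter
#'   lists as consumed by [linear_predictor()].
#' @export
default_true_params <- function(panel = default_panel(), sigma = 0.3) {
  panel <- validate_panel(panel)
  # attenuation per ethnicity (rows) x status (cols); European prediabetic = 1
  atten <- matrix(c(1.0, 0.6, 0.7,
                    0.6, 0.45, 0.35),
                  3, 2, dimnames = list(.ethnicities,
                                        c("prediabetic", "diabetic")))
  out <- lapply(seq_len(nrow(panel)), function(j) {
    nm <- panel$name[j]
    b0 <- if (nm %in% names(.base_slopes)) .base_slopes[[nm]] else 0.05
    c0 <- if (nm %in% names(.base_conc)) .base_conc[[nm]] else 100
    list(alpha = stats::setNames(log(c0) + c(0, 0.05, -0.05), .ethnicities),
         beta = b0 * atten,
         eta = 0.01,
         gamma = c(sex = 0.05, age = -0.02, diab = 0.1, bmi = 0.05),
         sigma = sigma)
  })
  names(out) <- panel$name
  structure(out, class = "true_params")
}

# centers implied by the configured group means (diabetic HbA1c shift included)
implied_scaling <- function(config) {
  w <- config$group_sizes / sum(config$group_sizes)
  scaling_spec(
    center_hba1c = sum(w * (config$hba1c_mean +
                              config$diabetic_hba1c_shift * config$diabetic_prop)),
    center_age = sum(w * config$age_mean),
    center_bmi = sum(w * config$bmi_mean))
}

rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a complete synthetic cohort
#'
#' Draws demographics per ethnic group (sex and diabetic status Bernoulli,
#' age/BMI/HbA1c normal truncated at zero, fasting glucose consistent with the
#' assigned glycemic status), then each metabolite concentration as
#' `exp(linear_predictor + Normal(0, sigma))` with the configured ground-truth
#' parameters, using the centers implied by the configured group means. No
#' missingness is applied here; see [apply_lod_censoring()] and
#' [apply_qc_rejection()], or the end-to-end wrapper [simulate_cohort()].
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` (complete [cohort()]), `truth`
#'   (ground-truth parameters and the implied `scaling_spec`).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  abbrev <- c(european = "eur", ghanaian = "gha", african_surinamese = "sur")
  rows <- lapply(.ethnicities, function(eth) {
    n <- config$group_sizes[[eth]]
    female <- stats::rbinom(n, 1L, config$female_prop[[eth]])
    diab <- stats::rbinom(n, 1L, config$diabetic_prop[[eth]])
    hba1c <- rnorm_pos(n, config$hba1c_mean[[eth]] +
                         config$diabetic_hba1c_shift * diab,
                       config$hba1c_sd[[eth]])
    # fasting glucose consistent with status: diabetic > 7, prediabetic (5, 7]
    glucose <- numeric(n)
    todo <- rep(TRUE, n)
    while (any(todo)) {
      idx <- which(todo)
      d <- diab[idx]
      glucose[idx] <- stats::rnorm(length(idx), ifelse(d == 1L, 8.5, 5.9),
                                   ifelse(d == 1L, 1.0, 0.5))
      g <- glucose[idx]
      todo[idx] <- (d == 1L & g <= 7) | (d == 0L & (g <= 5 | g > 7))
    }
    data.frame(id = sprintf("%s_%04d", abbrev[[eth]], seq_len(n)),
               ethnicity = eth,
               sex = ifelse(female == 1L, "female", "male"),
               age_years = rnorm_pos(n, config$age_mean[[eth]],
                                     config$age_sd[[eth]]),
               bmi = rnorm_pos(n, config$bmi_mean[[eth]], config$bmi_sd[[eth]]),
               fasting_glucose_mmol_l = glucose,
               hba1c_mmol_mol = hba1c,
               glycemic_status = ifelse(diab == 1L, "diabetic", "prediabetic"),
               stringsAsFactors = FALSE)
  })
  participants <- do.call(rbind, rows)
  n <- nrow(participants)
  scaling <- implied_scaling(config)
  covars <- scale_covariates(participants, scaling)
  panel <- config$panel
  conc <- matrix(NA_real_, n, nrow(panel), dimnames = list(NULL, panel$name))
  for (j in seq_len(nrow(panel))) {
    tp <- config$true_params[[panel$name[j]]]
    mu <- linear_predictor(tp, covars, participants$ethnicity)
    noise <- if (tp$sigma > 0) stats::rnorm(n, 0, tp$sigma) else 0
    conc[, j] <- exp(mu + noise)
  }
  status <- matrix("observed", n, nrow(panel), dimnames = list(NULL, panel$name))
  list(cohort = cohort(participants, conc, status, panel),
       truth = list(params = config$true_params, scaling = scaling))
}

#' Left-censor a cohort below per-metabolite detection limits
#'
#' For each metabolite the LOD is the empirical quantile (`lod_quantile`) of
#' that metabolite's complete simulated values; every value strictly below the
#' LOD becomes a `below_lod` cell with absent concentration. The applied LODs
#' are attached as attribute `lod_per_metabolite`.
#'
#' @param x a complete [cohort()].
#' @param lod_quantile quantile in `[0, 1)`.
#' @param seed unused (censoring is deterministic given the values); kept for
#'   interface symmetry with [apply_qc_rejection()].
#' @return the censored [cohort()].
#' @export
apply_lod_censoring <- function(x, lod_quantile, seed = NULL) {
  if (lod_quantile >= 1) stop("lod_quantile must be < 1")
  stopifnot(inherits(x, "cohort"))
  lods <- apply(x$conc, 2L, stats::quantile, probs = lod_quantile, names = FALSE)
  for (j in seq_len(ncol(x$conc))) {
    hit <- !is.na(x$conc[, j]) & x$conc[, j] < lods[j]
    x$status[hit, j] <- "below_lod"
    x$conc[hit, j] <- NA_real_
  }
  x <- validate_cohort(x)
  attr(x, "lod_per_metabolite") <- stats::setNames(lods, x$panel$name)
  x
}

#' Reject measurement cells completely at random
#'
#' Each still-observed metabolite cell independently becomes `qc_rejected`
#' with probability `qc_rate` (missing completely at random — a special case
#' of the missing-at-random assumption the model makes). Optionally also
#' masks HbA1c and BMI covariates at the given per-participant rates. Masked
#' cell indices are attached as attribute `qc_cells`.
#'
#' @param x a [cohort()].
#' @param qc_rate probability in `[0, 1]`.
#' @param seed integer seed.
#' @param hba1c_miss_rate,bmi_miss_rate covariate masking probabilities.
#' @return the masked [cohort()].
#' @export
apply_qc_rejection <- function(x, qc_rate, seed = 1L, hba1c_miss_rate = 0,
                               bmi_miss_rate = 0) {
  stopifnot(inherits(x, "cohort"), qc_rate >= 0, qc_rate <= 1)
  lods <- attr(x, "lod_per_metabolite")
  set.seed(seed)
  obs <- x$status == "observed"
  hit <- obs & matrix(stats::runif(length(obs)) < qc_rate, nrow(obs))
  x$status[hit] <- "qc_rejected"
  x$conc[hit] <- NA_real_
  n <- nrow(x$participants)
  if (hba1c_miss_rate > 0)
    x$participants$hba1c_mmol_mol[stats::runif(n) < hba1c_miss_rate] <- NA_real_
  if (bmi_miss_rate > 0)
    x$participants$bmi[stats::runif(n) < bmi_miss_rate] <- NA_real_
  x <- validate_cohort(x)
  attr(x, "lod_per_metabolite") <- lods
  attr(x, "qc_cells") <- which(hit)
  x
}

#' Simulate a study-conditions cohort end to end
#'
#' [generate_cohort()], then below-LOD censoring and QC rejection at the
#' configured rates. Optionally writes the cohort CSV and a ground-truth
#' sidecar JSON (true parameters, per-metabolite LODs, masked cell indices,
#' implied centers, seed) for parameter-recovery tests.
#'
#' @param config a [sim_config()].
#' @param path optional cohort CSV output path.
#' @param truth_path optional truth sidecar JSON output path.
#' @return list with `cohort` and `truth` (params, scaling,
#'   `lod_per_metabolite`, `qc_cells`).
#' @export
simulate_cohort <- function(config = sim_config(), path = NULL,
                            truth_path = NULL) {
  gen <- generate_cohort(config)
  x <- apply_lod_censoring(gen$cohort, config$lod_quantile)
  x <- apply_qc_rejection(x, config$qc_rate, seed = config$seed + 1L,
                          hba1c_miss_rate = config$hba1c_miss_rate,
                          bmi_miss_rate = config$bmi_miss_rate)
  truth <- gen$truth
  truth$lod_per_metabolite <- attr(x, "lod_per_metabolite")
  truth$qc_cells <- attr(x, "qc_cells")
  truth$seed <- config$seed
  if (!is.null(path)) write_cohort(x, path)
  if (!is.null(truth_path)) {
    tr <- truth
    tr$params <- lapply(tr$params, function(p) {
      list(alpha = as.list(p$alpha),
           beta = as.data.frame(p$beta),
           eta = p$eta, gamma = as.list(p$gamma), sigma = p$sigma)
    })
    tr$scaling <- unclass(tr$scaling)
    jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  list(cohort = x, truth = truth)
}
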