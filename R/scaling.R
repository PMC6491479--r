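# Centering and scaling of the continuous covariates. Units are fixed so that
# regression coefficients read as: per 10 mmol/mol HbA1c, per 10 years of age,
# per 5 kg/m^2 of BMI.

.unit_hba1c <- 10
.unit_age <- 10
.unit_bmi <- 5

#' Compute the centering/scaling specification for a cohort
#'
#' Centers are full-cohort arithmetic means over the observed values of HbA1c,
#' age and BMI (a single center per covariate, not per ethnic group, so that
#' group-specific intercepts stay comparable); the scale divisors are the fixed
#' unit sizes 10 mmol/mol, 10 years and 5 kg/m^2.
#'
#' @param x a [cohort()].
#' @return A `scaling_spec`: list with `center_hba1c`, `center_age`,
#'   `center_bmi` and the fixed `unit_*` divisors.
#' @export
compute_scaling <- function(x) {
  p <- x$participants
  ctr <- function(v, what) {
    v <- v[!is.na(v)]
    if (!length(v)) stop("no observed values of ", what, "; cannot center")
    mean(v)
  }
  scaling_spec(center_hba1c = ctr(p$hba1c_mmol_mol, "hba1c"),
               center_age = ctr(p$age_years, "age"),
               center_bmi = ctr(p$bmi, "bmi"))
}

#' @rdname compute_scaling
#' @param center_hba1c,center_age,center_bmi centers in natural units
#'   (mmol/mol, years, kg/m^2).
#' @export
scaling_spec <- function(center_hba1c, center_age, center_bmi) {
  stopifnot(is.finite(center_hba1c), is.finite(center_age), is.finite(center_bmi))
  structure(list(center_hba1c = center_hba1c, center_age = center_age,
                 center_bmi = center_bmi,
                 unit_hba1c = .unit_hba1c, unit_age = .unit_age,
                 unit_bmi = .unit_bmi),
            class = "scaling_spec")
}

#' Scale covariates of a cohort
#'
#' Maps each participant to the covariate tuple the regression consumes:
#' `hba1c_u = (hba1c - center)/10`, `age_u = (age - center)/10`,
#' `bmi_u = (bmi - center)/5`, `female` (1 = female) and `diabetic`
#' (1 = diabetic, 0 = prediabetic). Missing HbA1c/BMI propagate as `NA` and are
#' imputed inside the model.
#'
#' @param x a [cohort()] (or its `participants` data frame).
#' @param spec a `scaling_spec` from [compute_scaling()].
#' @return data frame with columns `hba1c_u`, `age_u`, `bmi_u`, `female`,
#'   `diabetic`.
#' @export
scale_covariates <- function(x, spec) {
  stopifnot(inherits(spec, "scaling_spec"))
  p <- if (inherits(x, "cohort")) x$participants else x
  data.frame(
    hba1c_u = (p$hba1c_mmol_mol - spec$center_hba1c) / spec$unit_hba1c,
    age_u = (p$age_years - spec$center_age) / spec$unit_age,
    bmi_u = (p$bmi - spec$center_bmi) / spec$unit_bmi,
    female = as.numeric(p$sex == "female"),
    diabetic = as.numeric(p$glycemic_status == "diabetic")
  )
}
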