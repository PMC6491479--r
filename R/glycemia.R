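# Glycemic-status classification and HbA1c unit conversion.

#' Classify glycemic status from fasting glucose and HbA1c
#'
#' Diabetic if fasting glucose exceeds 7 mmol/L; otherwise prediabetic if
#' fasting glucose exceeds 5 mmol/L or HbA1c exceeds 5.7%; otherwise
#' normoglycemic. (The study strata contain only prediabetic and diabetic
#' participants; the synthetic generator never emits normoglycemic rows, but
#' the classifier covers the full rule.)
#'
#' @param fasting_glucose fasting glucose, mmol/L (> 0).
#' @param hba1c_percent HbA1c in NGSP percent (> 0).
#' @return character vector in `{"diabetic", "prediabetic", "normoglycemic"}`.
#' @examples
#' assign_glycemic_status(7.5, 5.0)  # diabetic
#' assign_glycemic_status(5.5, 5.0)  # prediabetic
#' @export
assign_glycemic_status <- function(fasting_glucose, hba1c_percent) {
  if (any(fasting_glucose <= 0) || any(hba1c_percent <= 0))
    stop("fasting glucose and HbA1c must be positive")
  ifelse(fasting_glucose > 7, "diabetic",
         ifelse(fasting_glucose > 5 | hba1c_percent > 5.7,
                "prediabetic", "normoglycemic"))
}

#' Convert HbA1c from NGSP percent to IFCC mmol/mol
#'
#' Applies the IFCC master-equation conversion
#' `(percent - 2.15) * 10.929`, rounded to one decimal.
#'
#' @param value HbA1c in percent (> 0).
#' @return HbA1c in mmol/mol, one decimal.
#' @examples
#' hba1c_percent_to_mmol_mol(5.7)  # 38.8
#' @export
hba1c_percent_to_mmol_mol <- function(value) {
  if (any(value <= 0)) stop("HbA1c percent must be positive")
  round((value - 2.15) * 10.929, 1)
}
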