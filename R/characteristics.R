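# Baseline-characteristics ("table one") summaries per ethnic group:
# Kruskal-Wallis tests for continuous rows, chi-squared tests for categorical
# rows, matching the conventional cohort-description layout.

#' Baseline characteristics by ethnic group
#'
#' Produces a per-group characteristics table: group sizes, female percentage,
#' mean +/- SD of age, BMI and HbA1c, diabetic count (percentage), and a P
#' value per row. Continuous rows are compared across groups with the
#' (tie-corrected) Kruskal-Wallis rank test; categorical rows (sex, diabetes)
#' with the chi-squared test of independence without continuity correction.
#' Percentages are rounded to one decimal.
#'
#' @param x a [cohort()].
#' @return data frame with one row per characteristic and columns
#'   `characteristic`, one column per ethnic group present, and `p_value`.
#' @export
summarize_characteristics <- function(x) {
  p <- x$participants
  g <- factor(p$ethnicity, intersect(.ethnicities, unique(p$ethnicity)))
  if (nlevels(g) < 2L) stop("need at least two ethnic groups")
  if (any(table(g) < 2L)) stop("each group needs at least 2 participants")
  groups <- levels(g)

  pct1 <- function(num, den) round(100 * num / den, 1)
  n_g <- as.integer(table(g))

  cont_row <- function(label, v) {
    cells <- vapply(groups, function(lev) {
      vi <- v[g == lev & !is.na(v)]
      sprintf("%.1f ± %.1f", mean(vi), stats::sd(vi))
    }, character(1))
    keep <- !is.na(v)
    pv <- stats::kruskal.test(v[keep], droplevels(g[keep]))$p.value
    c(label, cells, format_p(pv))
  }
  cat_row <- function(label, ind) {
    tab <- table(ind, g)
    if (nrow(tab) < 2L) stop("degenerate categorical row '", label,
                             "': no variation")
    num <- as.integer(tab["1", ]); den <- n_g
    cells <- sprintf("%d (%.1f)", num, pct1(num, den))
    pv <- stats::chisq.test(tab, correct = FALSE)$p.value
    c(label, cells, format_p(pv))
  }

  female <- as.integer(p$sex == "female")
  diab <- as.integer(p$glycemic_status == "diabetic")
  rows <- rbind(
    c("N", as.character(n_g), ""),
    cat_row("Female (%)", female),
    cont_row("Age (years)", p$age_years),
    cont_row("BMI", p$bmi),
    cont_row("HbA1c (mmol/mol)", p$hba1c_mmol_mol),
    cat_row("Diabetes (%)", diab)
  )
  out <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(out) <- c("characteristic", groups, "p_value")
  rownames(out) <- NULL
  out
}

format_p <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "<0.0001" else sprintf("%.4f", p)
}

#' Diabetic percentages per group
#'
#' Convenience accessor behind the characteristics table: diabetic count and
#' percentage (one decimal) per ethnic group, in cohort group order.
#'
#' @param x a [cohort()].
#' @return data frame with columns `ethnicity`, `n`, `diabetic_n`,
#'   `diabetic_pct`.
#' @export
diabetic_breakdown <- function(x) {
  p <- x$participants
  g <- factor(p$ethnicity, intersect(.ethnicities, unique(p$ethnicity)))
  n <- as.integer(table(g))
  d <- as.integer(tapply(p$glycemic_status == "diabetic", g, sum))
  data.frame(ethnicity = levels(g), n = n, diabetic_n = d,
             diabetic_pct = round(100 * d / n, 1), stringsAsFactors = FALSE)
}
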