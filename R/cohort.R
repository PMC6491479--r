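# Cohort container: per-participant demographics/glycemia plus a participant x
# metabolite grid of measurements, each cell either an observed positive
# concentration, below the limit of detection, or rejected by quality control.

.ethnicities <- c("european", "ghanaian", "african_surinamese")
.sexes <- c("male", "female")
.glycemic <- c("prediabetic", "diabetic")
.demo_cols <- c("id", "ethnicity", "sex", "age_years", "bmi",
                "fasting_glucose_mmol_l", "hba1c_mmol_mol", "glycemic_status")

#' Construct a cohort table
#'
#' @param participants data frame with columns `id`, `ethnicity`
#'   (`european`/`ghanaian`/`african_surinamese`), `sex` (`male`/`female`),
#'   `age_years`, `bmi`, `fasting_glucose_mmol_l`, `hba1c_mmol_mol`,
#'   `glycemic_status` (`prediabetic`/`diabetic`). `bmi`, `fasting_glucose_mmol_l`
#'   and `hba1c_mmol_mol` may contain `NA` (missing covariates).
#' @param conc numeric matrix, participants x panel metabolites, `NA` where the
#'   cell is not observed.
#' @param status character matrix of the same shape with values `observed`,
#'   `below_lod` or `qc_rejected`; `conc` is non-`NA` exactly where `status ==
#'   "observed"`.
#' @param panel a `metabolite_panel` (see [default_panel()]).
#' @return An object of class `cohort`: a list with elements `participants`,
#'   `conc`, `status`, `panel`.
#' @export
cohort <- function(participants, conc, status, panel = default_panel()) {
  panel <- validate_panel(panel)
  conc <- as.matrix(conc)
  status <- as.matrix(status)
  x <- structure(list(participants = participants, conc = conc,
                      status = status, panel = panel),
                 class = "cohort")
  validate_cohort(x)
}

validate_cohort <- function(x) {
  p <- x$participants
  miss <- setdiff(.demo_cols, names(p))
  if (length(miss)) stop("participants lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(p$id)) stop("duplicated participant id: ",
                                p$id[duplicated(p$id)][1L])
  chk_enum <- function(v, allowed, what) {
    bad <- setdiff(unique(as.character(v)), allowed)
    if (length(bad)) stop("unknown ", what, " token: ", bad[1L])
  }
  chk_enum(p$ethnicity, .ethnicities, "ethnicity")
  chk_enum(p$sex, .sexes, "sex")
  chk_enum(p$glycemic_status, .glycemic, "glycemic_status")
  pos <- function(v, what) {
    if (any(!is.na(v) & v <= 0)) stop("non-positive ", what)
  }
  pos(p$age_years, "age_years"); pos(p$bmi, "bmi"); pos(p$hba1c_mmol_mol, "hba1c")
  if (anyNA(p$age_years)) stop("age_years must be observed for all participants")
  n <- nrow(p); m <- nrow(x$panel)
  if (!identical(dim(x$conc), c(n, m)) || !identical(dim(x$status), c(n, m)))
    stop("measurement grids must be ", n, " x ", m)
  chk_enum(x$status, c("observed", "below_lod", "qc_rejected"), "measurement status")
  obs <- x$status == "observed"
  if (any(obs & is.na(x$conc)) || any(!obs & !is.na(x$conc)))
    stop("concentration must be present iff status == 'observed'")
  if (any(x$conc[obs] <= 0)) stop("non-positive observed concentration")
  colnames(x$conc) <- colnames(x$status) <- x$panel$name
  x
}

#' @export
print.cohort <- function(x, ...) {
  n <- nrow(x$participants)
  cat("<cohort> ", n, " participants x ", nrow(x$panel), " metabolites\n", sep = "")
  tab <- table(x$participants$ethnicity)
  cat("  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  st <- table(factor(x$status, c("observed", "below_lod", "qc_rejected")))
  cat("  cells:  ", paste(names(st), st, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort <- function(x) c(nrow(x$participants), nrow(x$panel))

# minimal observed concentration per metabolite (the upper truncation bound for
# below-LOD imputation); NA where a column has no observed value
min_observed <- function(x) {
  m <- suppressWarnings(apply(x$conc, 2L, min, na.rm = TRUE))
  m[!is.finite(m)] <- NA_real_
  m
}

#' Read a cohort CSV
#'
#' The dialect is UTF-8, comma-separated, `.` decimal, with header
#' `id,ethnicity,sex,age_years,bmi,fasting_glucose_mmol_l,hba1c_mmol_mol,`
#' `glycemic_status,<metabolite 1>,...,<metabolite 24>`. Metabolite cells hold a
#' decimal literal, the sentinel `<LOD` (below the limit of detection), the
#' sentinel `QCFAIL` (rejected by quality control), or are empty. Empty
#' `bmi`/`hba1c_mmol_mol`/`fasting_glucose_mmol_l` cells are missing covariates.
#'
#' @param path CSV file path.
#' @param panel expected `metabolite_panel`; the file's metabolite columns must
#'   match its names in order.
#' @return A [cohort()].
#' @export
read_cohort <- function(path, panel = default_panel()) {
  panel <- validate_panel(panel)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  expected <- c(.demo_cols, panel$name)
  if (!identical(names(raw), expected))
    stop("cohort CSV header mismatch; expected: ", paste(expected, collapse = ","))
  n <- nrow(raw)
  num <- function(v, col) {
    v[v == ""] <- NA
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop("row ", bad[1L], ", column '", col, "': not a number: '", v[bad[1L]], "'")
    out
  }
  enum <- function(v, allowed, col) {
    bad <- which(!(v %in% allowed))
    if (length(bad))
      stop("row ", bad[1L], ", column '", col, "': unknown token '", v[bad[1L]], "'")
    v
  }
  participants <- data.frame(
    id = raw$id,
    ethnicity = enum(raw$ethnicity, .ethnicities, "ethnicity"),
    sex = enum(raw$sex, .sexes, "sex"),
    age_years = num(raw$age_years, "age_years"),
    bmi = num(raw$bmi, "bmi"),
    fasting_glucose_mmol_l = num(raw$fasting_glucose_mmol_l, "fasting_glucose_mmol_l"),
    hba1c_mmol_mol = num(raw$hba1c_mmol_mol, "hba1c_mmol_mol"),
    glycemic_status = enum(raw$glycemic_status, .glycemic, "glycemic_status"),
    stringsAsFactors = FALSE
  )
  m <- nrow(panel)
  conc <- matrix(NA_real_, n, m, dimnames = list(NULL, panel$name))
  status <- matrix("observed", n, m, dimnames = list(NULL, panel$name))
  for (j in seq_len(m)) {
    v <- raw[[panel$name[j]]]
    status[v == "<LOD", j] <- "below_lod"
    status[v == "QCFAIL", j] <- "qc_rejected"
    ok <- !(v %in% c("<LOD", "QCFAIL"))
    if (any(v[ok] == ""))
      stop("row ", which(ok & v == "")[1L], ", column '", panel$name[j],
           "': empty metabolite cell (use <LOD or QCFAIL for missing)")
    conc[ok, j] <- num(v[ok], panel$name[j])
  }
  cohort(participants, conc, status, panel)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: below-LOD cells are written as the literal token
#' `<LOD`, QC-rejected cells as `QCFAIL`, missing covariates as empty cells.
#' Column order is fixed: demographics, then the panel in order.
#'
#' @param x a [cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  x <- validate_cohort(x)
  fmt <- function(v) ifelse(is.na(v), "", format(v, digits = 15, trim = TRUE,
                                                 scientific = FALSE))
  p <- x$participants
  out <- data.frame(id = p$id, ethnicity = p$ethnicity, sex = p$sex,
                    age_years = fmt(p$age_years), bmi = fmt(p$bmi),
                    fasting_glucose_mmol_l = fmt(p$fasting_glucose_mmol_l),
                    hba1c_mmol_mol = fmt(p$hba1c_mmol_mol),
                    glycemic_status = p$glycemic_status,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(nrow(x$panel))) {
    cell <- fmt(x$conc[, j])
    cell[x$status[, j] == "below_lod"] <- "<LOD"
    cell[x$status[, j] == "qc_rejected"] <- "QCFAIL"
    out[[x$panel$name[j]]] <- cell
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
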