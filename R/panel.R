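# Metabolite panel definitions: 24 analytes measured on a high-throughput NMR
# platform — 8 amino acids, 2 ketone bodies and 14 lipoprotein subclasses
# identified by average particle diameter.

# Lipoprotein subclass diameters (nm); the extremely-large VLDL class is
# defined as ">75 nm" and stored as 75.
.default_lipoproteins <- data.frame(
  name = c("extremely_large_vldl_p", "very_large_vldl_p", "large_vldl_p",
           "medium_vldl_p", "small_vldl_p", "very_small_vldl_p",
           "idl_p",
           "large_ldl_p", "medium_ldl_p", "small_ldl_p",
           "very_large_hdl_p", "large_hdl_p", "medium_hdl_p", "small_hdl_p"),
  diameter_nm = c(75, 64.0, 53.6, 44.5, 36.8, 31.3,
                  28.6,
                  25.5, 23.0, 18.7,
                  14.3, 12.1, 10.9, 8.7),
  apolipoprotein = c(rep("B", 10), rep("A1", 4)),
  stringsAsFactors = FALSE
)

#' Default 24-analyte metabolite panel
#'
#' Builds the default panel of 24 analytes: 8 amino acids, 2 ketone bodies
#' (acetoacetate and 3-hydroxybutyrate) and 14 lipoprotein subclass particle
#' concentrations distinguished by average particle diameter (six VLDL
#' subclasses from extremely large, >75 nm, down to very small; IDL; three LDL
#' subclasses; four HDL subclasses). The extremely-large VLDL class has no
#' single diameter and is recorded as 75 nm, the lower edge of its ">75 nm"
#' definition.
#'
#' Only five of the eight amino acids (isoleucine, leucine, valine, tyrosine,
#' alanine) are fixed by the analysis the package targets; the remaining three
#' default to phenylalanine, glutamine and histidine and can be replaced via
#' `amino_acids`.
#'
#' @param amino_acids character vector of 8 amino-acid names.
#' @return A `metabolite_panel`: a data frame with columns `name`, `class`
#'   (`amino_acid`, `ketone_body`, `lipoprotein`), `diameter_nm` (NA except
#'   lipoproteins) and `apolipoprotein` (`A1`, `B` or `none`).
#' @examples
#' p <- default_panel()
#' table(p$class)
#' @export
default_panel <- function(amino_acids = c("isoleucine", "leucine", "valine",
                                          "phenylalanine", "tyrosine",
                                          "alanine", "glutamine", "histidine")) {
  if (length(amino_acids) != 8L || anyDuplicated(amino_acids))
    stop("`amino_acids` must be 8 distinct names")
  aa <- data.frame(name = amino_acids, class = "amino_acid",
                   diameter_nm = NA_real_, apolipoprotein = "none",
                   stringsAsFactors = FALSE)
  kb <- data.frame(name = c("acetoacetate", "hydroxybutyrate_3"),
                   class = "ketone_body", diameter_nm = NA_real_,
                   apolipoprotein = "none", stringsAsFactors = FALSE)
  lp <- cbind(.default_lipoproteins[, "name", drop = FALSE],
              class = "lipoprotein",
              .default_lipoproteins[, c("diameter_nm", "apolipoprotein")])
  panel <- rbind(aa, kb, lp)
  rownames(panel) <- NULL
  class(panel) <- c("metabolite_panel", "data.frame")
  validate_panel(panel)
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("name", "class", "diameter_nm", "apolipoprotein") %in%
                  names(panel)))
  if (anyDuplicated(panel$name)) stop("duplicated metabolite names in panel")
  bad <- setdiff(unique(panel$class),
                 c("amino_acid", "ketone_body", "lipoprotein"))
  if (length(bad)) stop("unknown metabolite class: ", paste(bad, collapse = ", "))
  if (any(panel$class == "lipoprotein" & !is.finite(panel$diameter_nm)))
    stop("lipoprotein entries require a diameter_nm")
  if (!inherits(panel, "metabolite_panel"))
    class(panel) <- c("metabolite_panel", "data.frame")
  panel
}

#' Read / write a panel definition as JSON
#'
#' The JSON form is a list of objects `{name, class, diameter_nm?,
#' apolipoprotein}`; `diameter_nm` is omitted for non-lipoproteins.
#'
#' @param path file path.
#' @param panel a `metabolite_panel`.
#' @return `read_panel` returns a `metabolite_panel`; `write_panel` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (is.null(x$diameter_nm)) x$diameter_nm <- NA_real_
  x$diameter_nm <- as.numeric(x$diameter_nm)
  if (is.null(x$apolipoprotein)) x$apolipoprotein <- "none"
  x$apolipoprotein[is.na(x$apolipoprotein)] <- "none"
  validate_panel(x[, c("name", "class", "diameter_nm", "apolipoprotein")])
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  jsonlite::write_json(panel, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
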