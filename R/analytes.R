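#' Analyte metadata
#'
#' An [analyte_definition()] records what the pipeline needs to know about one
#' blood analyte before it sees any data: its units, whether negative values
#' are physically impossible, an optional lower limit of quantitation (values
#' below it are reported *at* the limit by the assay, i.e. left-censored), and
#' an optional analytical coefficient of variation (CVa) taken from published
#' assay-precision studies rather than estimated from the data.
#'
#' @param name Analyte identifier (non-empty string, used as a column name).
#' @param units Measurement units, e.g. `"mg/dl"`; purely descriptive.
#' @param nonnegative Logical; if `TRUE`, negative values are invalid input.
#' @param quantitation_floor Lower reporting limit in analyte units, or `NA`.
#'   Must be positive when present.
#' @param analytical_cv Analytical CV as a proportion in (0, 1), or `NA` when
#'   no published value exists.
#'
#' @return A one-row data frame with columns `analyte`, `units`, `nonnegative`,
#'   `floor`, `cva`.
#' @export
#' @examples
#' analyte_definition("uric_acid", "mg/dl", nonnegative = TRUE,
#'                    quantitation_floor = 0.8)
analyte_definition <- function(name, units = "", nonnegative = TRUE,
                               quantitation_floor = NA_real_,
                               analytical_cv = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.na(quantitation_floor) && quantitation_floor <= 0) {
    stop("quantitation_floor for '", name, "' must be > 0 when present")
  }
  if (!is.na(analytical_cv) &&
      (analytical_cv <= 0 || analytical_cv >= 1)) {
    stop("analytical_cv for '", name, "' must lie in (0, 1)")
  }
  data.frame(analyte = name, units = units,
             nonnegative = isTRUE(nonnegative),
             floor = as.numeric(quantitation_floor),
             cva = as.numeric(analytical_cv),
             stringsAsFactors = FALSE)
}

#' The 16-analyte clinical pathology panel
#'
#' The default panel covers the standard chelonian health-assessment analytes:
#' packed cell volume (PCV), total solids (TS), total and differential white
#' cell counts, the heterophil:lymphocyte stress index, calcium, phosphorus and
#' their ratio, bile acids, uric acid, creatine kinase and AST. Leukocyte
#' counts carry an analytical CV of 8.2% from published avian hematology
#' precision work; uric acid carries a 0.8 mg/dl quantitation floor (the
#' biochemistry analyzer reports lower concentrations at that limit).
#'
#' @return Data frame with one row per analyte: `analyte`, `units`,
#'   `nonnegative`, `floor`, `cva`.
#' @export
default_analyte_panel <- function() {
  rbind(
    analyte_definition("pcv",         "%"),
    analyte_definition("ts",          "g/dl"),
    analyte_definition("wbc",         "/ul", analytical_cv = 0.082),
    analyte_definition("heterophils", "/ul"),
    analyte_definition("lymphocytes", "/ul", analytical_cv = 0.082),
    analyte_definition("monocytes",   "/ul", analytical_cv = 0.082),
    analyte_definition("eosinophils", "/ul"),
    analyte_definition("basophils",   "/ul", analytical_cv = 0.082),
    analyte_definition("hl_ratio",    ""),
    analyte_definition("calcium",     "mg/dl"),
    analyte_definition("phosphorus",  "mg/dl"),
    analyte_definition("cap_ratio",   ""),
    analyte_definition("bile_acids",  "umol/L"),
    analyte_definition("uric_acid",   "mg/dl", quantitation_floor = 0.8),
    analyte_definition("ck",          "U/L"),
    analyte_definition("ast",         "U/L")
  )
}

#' Published summary statistics for the Blanding's turtle panel
#'
#' Per-analyte summary statistics from a two-year field study of free-ranging
#' Blanding's turtles (393 samples, 227 animals, two Illinois Lake Plain
#' sites): sample size, mean, SD, the Shapiro-Wilk distribution call, and — for
#' the seven analytes the study resolved longitudinally — the within-animal
#' (CVi) and between-animal (CVg) coefficients of variation. These values seed
#' the synthetic-data generator's defaults and provide the printed inputs for
#' the index-of-individuality / reference-change-value arithmetic.
#'
#' `ri_type` records which kind of reference interval the study assigned:
#' `"population"` where between-animal variation dominates (index of
#' individuality > 0.6), `"subject"` otherwise.
#'
#' @return Data frame with columns `analyte`, `n`, `mean`, `sd`,
#'   `distribution` (`"normal"`/`"non-normal"`), `cvi`, `cvg` (proportions, NA
#'   for population-type analytes), `ri_type`.
#' @export
reference_summary <- function() {
  df <- read.csv(text = "
analyte,n,mean,sd,distribution,cvi,cvg,ri_type
pcv,393,18.6,6.2,normal,NA,NA,population
ts,393,3.5,1.1,normal,NA,NA,population
heterophils,389,1473,1034,non-normal,NA,NA,population
eosinophils,389,1055,859,non-normal,NA,NA,population
hl_ratio,391,0.183,0.185,normal,NA,NA,population
calcium,393,10.7,5.8,normal,NA,NA,population
phosphorus,392,3.5,1.6,non-normal,NA,NA,population
cap_ratio,366,3.24,1.39,non-normal,NA,NA,population
bile_acids,349,3.6,3.1,non-normal,NA,NA,population
wbc,389,20131,18809,non-normal,0.46,0.93,subject
lymphocytes,389,14559,15743,non-normal,0.52,1.08,subject
monocytes,389,659,904,non-normal,0.78,1.37,subject
basophils,389,2371,3063,non-normal,0.63,1.29,subject
uric_acid,390,2.8,0.2,non-normal,0.66,1.14,subject
ck,391,897.6,1055.1,non-normal,0.58,1.17,subject
ast,393,64.7,36.0,non-normal,0.33,0.56,subject
", stringsAsFactors = FALSE, strip.white = TRUE)
  df
}
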