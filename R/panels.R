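#' Expert panel of continuous DKD predictors
#'
#' The nine routinely measured continuous predictors that domain experts
#' consider key for DKD progression: eGFR, urine albumin-creatinine ratio,
#' systolic and diastolic blood pressure, hemoglobin, total serum
#' cholesterol, body mass index, HbA1c and age.
#'
#' @return Data frame with columns \code{marker} and \code{name}.
#' @export
expert_panel <- function() {
  data.frame(
    marker = c("eGFR", "UACR", "SBP", "DBP", "HB", "TOTCHOL", "BMI", "HBA1C", "AGE"),
    name = c("Estimated glomerular filtration rate",
             "Urine albumin-creatinine ratio",
             "Systolic blood pressure",
             "Diastolic blood pressure",
             "Hemoglobin",
             "Total serum cholesterol",
             "Body mass index",
             "Glycated hemoglobin HbA1c",
             "Age"),
    stringsAsFactors = FALSE
  )
}

#' Reduced nine-marker consensus panel
#'
#' The consensus panel obtained by merging the top PLS-ranked markers of the
#' expert set with those of the extended (full) candidate set and re-ranking
#' the union: eGFR, DPP4, ICAM1, LEP, AGE, ADIPOQ, TOTCHOL, SBP, SERPINE1.
#' The \code{source} column records whether a marker entered through the
#' expert or the extended set.
#'
#' @return Data frame with columns \code{marker}, \code{name}, \code{source}.
#' @export
reduced_panel <- function() {
  data.frame(
    marker = c("eGFR", "DPP4", "ICAM1", "LEP", "AGE", "ADIPOQ", "TOTCHOL",
               "SBP", "SERPINE1"),
    name = c("Estimated glomerular filtration rate",
             "Dipeptidyl peptidase-4",
             "Intercellular adhesion molecule 1",
             "Leptin",
             "Age",
             "Adiponectin",
             "Total serum cholesterol",
             "Systolic blood pressure",
             "Plasminogen activator inhibitor-1"),
    source = c("expert", "extended", "extended", "extended", "expert",
               "extended", "expert", "expert", "extended"),
    stringsAsFactors = FALSE
  )
}
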