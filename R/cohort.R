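#' Cohort accounting: exclusions and treatment-status fractions
#'
#' Bookkeeping for a diagnosis-questionnaire case-control cohort: subjects
#' never examined for the diagnosis or not answering the question are
#' excluded, the remainder form the genetic analysis set, and cases in
#' complete remission are additionally removed from clinical/lifestyle
#' analyses (genetics are unchanged by treatment, lifestyle is not).
#'
#' @param n_enrolled total enrolled participants.
#' @param n_not_examined participants never examined for the diagnosis.
#' @param n_no_answer participants not answering the diagnosis question.
#' @param n_cases cases among the analysis set.
#' @param n_remission cases in complete remission at survey.
#' @return list with `n_excluded`, `n_analysis`, `n_controls`,
#'   `n_lifestyle_cases` (cases retained for clinical/lifestyle analyses)
#'   and `remission_pct` (percent of cases in complete remission).
#' @export
cohort_accounting <- function(n_enrolled, n_not_examined, n_no_answer,
                              n_cases, n_remission) {
  stopifnot(n_enrolled > 0, n_not_examined >= 0, n_no_answer >= 0,
            n_cases >= 0, n_remission >= 0, n_remission <= n_cases)
  n_excluded <- n_not_examined + n_no_answer
  n_analysis <- n_enrolled - n_excluded
  stopifnot(n_cases <= n_analysis)
  list(n_excluded = n_excluded,
       n_analysis = n_analysis,
       n_controls = n_analysis - n_cases,
       n_lifestyle_cases = n_cases - n_remission,
       remission_pct = 100 * n_remission / n_cases)
}
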