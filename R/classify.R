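#' Significant blood-pressure change between baseline and discharge
#'
#' A patient shows a significant change when systolic blood pressure falls by
#' at least 20 mmHg or diastolic blood pressure falls by at least 10 mmHg
#' (both thresholds inclusive).
#'
#' @param cohort A cohort data frame (see [read_cohort()]).
#' @return Logical vector, one element per patient.
#' @export
significant_bp_change <- function(cohort) {
  cohort <- validate_cohort(cohort)
  (cohort$sbp_baseline - cohort$sbp_discharge) >= 20 |
    (cohort$dbp_baseline - cohort$dbp_discharge) >= 10
}

#' Direction of medication-count change
#'
#' @param cohort A cohort data frame.
#' @return Factor with levels `"decreased"`, `"unchanged"`, `"increased"`,
#'   comparing discharge to baseline medication counts.
#' @export
med_change <- function(cohort) {
  cohort <- validate_cohort(cohort)
  d <- cohort$meds_discharge - cohort$meds_baseline
  factor(ifelse(d < 0, "decreased", ifelse(d > 0, "increased", "unchanged")),
         levels = c("decreased", "unchanged", "increased"))
}

#' Four-group treatment-response classification
#'
#' Patients are cross-classified by the blood-pressure axis (significant
#' change vs not) and the medication axis (count decreased vs not decreased):
#'
#' * Group 1: BP down, drugs down
#' * Group 2: BP down, drugs not reduced
#' * Group 3: BP unchanged, drugs down
#' * Group 4: BP unchanged, drugs not reduced
#'
#' "Not reduced" pools unchanged and increased medication counts so the four
#' groups partition any cohort.
#'
#' @param cohort A cohort data frame.
#' @return Integer vector of group labels in `1:4`.
#' @seealso [significant_bp_change()], [med_change()], [is_success()]
#' @export
classify_group <- function(cohort) {
  bp_down <- significant_bp_change(cohort)
  drugs_down <- med_change(cohort) == "decreased"
  ifelse(bp_down,
         ifelse(drugs_down, 1L, 2L),
         ifelse(drugs_down, 3L, 4L))
}

#' Successful-intervention label
#'
#' An intervention is successful when the patient achieves a significant
#' blood-pressure change without additional antihypertensive medications, or
#' any reduction in medication load without an increase in (systolic) blood
#' pressure. The "no increase in blood pressure" clause is evaluated on
#' systolic pressure, ties allowed.
#'
#' Success is computed directly from this definition, independently of the
#' group labels: a patient whose pressure improves but whose medications are
#' added is Group 2 yet not a success.
#'
#' @param cohort A cohort data frame.
#' @return Logical vector, one element per patient.
#' @export
is_success <- function(cohort) {
  cohort <- validate_cohort(cohort)
  sig <- significant_bp_change(cohort)
  med <- med_change(cohort)
  (sig & med != "increased") |
    (med == "decreased" & cohort$sbp_discharge <= cohort$sbp_baseline)
}

#' Attach response labels to a cohort
#'
#' Convenience wrapper adding `significant_bp_change`, `med_change`, `group`
#' and `success` columns to a cohort table.
#'
#' @param cohort A cohort data frame.
#' @return The cohort with four label columns appended.
#' @examples
#' coh <- generate_cohort(seed = 1)
#' table(classify_cohort(coh)$group)
#' @export
classify_cohort <- function(cohort) {
  cohort <- validate_cohort(cohort)
  cohort$significant_bp_change <- significant_bp_change(cohort)
  cohort$med_change <- med_change(cohort)
  cohort$group <- classify_group(cohort)
  cohort$success <- is_success(cohort)
  cohort
}

#' Cohort-level response summary
#'
#' Counts and proportions of patients per response group and per success
#' label.
#'
#' @param cohort A non-empty cohort data frame.
#' @return A list with components `n`, `group_counts` (named integer vector
#'   over groups 1-4), `group_proportions`, `n_success`, `prop_success`.
#' @export
cohort_response_summary <- function(cohort) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  grp <- factor(classify_group(cohort), levels = 1:4)
  counts <- table(grp)
  counts <- stats::setNames(as.integer(counts), paste0("group", 1:4))
  succ <- is_success(cohort)
  list(
    n = nrow(cohort),
    group_counts = counts,
    group_proportions = counts / nrow(cohort),
    n_success = sum(succ),
    prop_success = mean(succ)
  )
}
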