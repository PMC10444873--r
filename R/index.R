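#' Compute the Hypertensive Index (or a variant)
#'
#' The Hypertensive Index jointly scores excess blood pressure and the
#' medication load required to achieve it:
#' \deqn{\mathrm{HTi} = (\mathrm{SBP} - 120) \times (\mathrm{n\ meds} + 1).}
#' A systolic pressure of exactly 120 mmHg scores 0 regardless of medication
#' count, and pressures below 120 yield negative scores (a possible marker of
#' over-treatment); negative values are returned unchanged.
#'
#' @param sbp Systolic blood pressure (mmHg). Vectorised.
#' @param n_meds Number of distinct prescribed antihypertensive agents
#'   (non-negative integers). A fixed-dose combination pill counts as the
#'   number of agents it contains.
#' @param definition An [hti_definition()]; defaults to the published HTi
#'   (systolic, reference 120, offset 1).
#' @param dbp Diastolic blood pressure (mmHg); required for definitions whose
#'   component is not `"systolic"`, optional otherwise (validated when given).
#' @return Numeric vector of index scores (dimensionless).
#' @examples
#' hti(145, 2)  # 75
#' hti(130, 4)  # 50
#' hti(120, 7)  # 0
#' hti(110, 0)  # -10
#' @export
hti <- function(sbp, n_meds, definition = hti_definition(), dbp = NULL) {
  stopifnot(inherits(definition, "hti_definition"))
  if (length(sbp) != length(n_meds)) {
    stop("'sbp' and 'n_meds' must have equal length", call. = FALSE)
  }
  check_measure(sbp, dbp, n_meds)
  bp <- bp_component_value(sbp, dbp, definition$bp_component)
  (bp - definition$bp_reference) * (n_meds + definition$med_offset)
}

#' Treated-blood-pressure comparator score
#'
#' A comparator phenotype used in large genetic studies of blood pressure:
#' systolic blood pressure supplemented by a flat 10 mmHg if the patient is
#' prescribed any number of antihypertensive drugs. The supplement does not
#' scale with the medication count.
#'
#' @inheritParams hti
#' @return Numeric vector of mmHg-equivalent scores.
#' @examples
#' gwas_score(145, 2)  # 155
#' gwas_score(145, 0)  # 145
#' @export
gwas_score <- function(sbp, n_meds) {
  if (length(sbp) != length(n_meds)) {
    stop("'sbp' and 'n_meds' must have equal length", call. = FALSE)
  }
  check_measure(sbp, n_meds = n_meds)
  sbp + 10 * (n_meds >= 1)
}

#' Per-patient improvement (change) scores
#'
#' For each patient, computes baseline-minus-discharge differences so that
#' positive values always mean improvement: systolic and diastolic pressure
#' drops (`d_sbp`, `d_dbp`), medication reduction (`d_meds`), index
#' improvement (`d_hti`, using `definition`), and the comparator score
#' improvement (`d_gwas`).
#'
#' @param cohort A cohort data frame as returned by [read_cohort()] or
#'   [generate_cohort()], with paired baseline/discharge columns.
#' @param definition An [hti_definition()] used for `d_hti`.
#' @return A data frame with columns `patient_id`, `d_sbp`, `d_dbp`,
#'   `d_meds`, `d_hti`, `d_gwas`.
#' @examples
#' coh <- generate_cohort(seed = 1)
#' head(change_scores(coh))
#' @export
change_scores <- function(cohort, definition = hti_definition()) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  hti_b <- hti(cohort$sbp_baseline, cohort$meds_baseline, definition,
               dbp = cohort$dbp_baseline)
  hti_d <- hti(cohort$sbp_discharge, cohort$meds_discharge, definition,
               dbp = cohort$dbp_discharge)
  data.frame(
    patient_id = cohort$patient_id,
    d_sbp = cohort$sbp_baseline - cohort$sbp_discharge,
    d_dbp = cohort$dbp_baseline - cohort$dbp_discharge,
    d_meds = cohort$meds_baseline - cohort$meds_discharge,
    d_hti = hti_b - hti_d,
    d_gwas = gwas_score(cohort$sbp_baseline, cohort$meds_baseline) -
      gwas_score(cohort$sbp_discharge, cohort$meds_discharge),
    stringsAsFactors = FALSE
  )
}

#' Hypertensive Index from cohort-level summary means
#'
#' Applies the index formula to published cohort-level summary statistics
#' (mean systolic blood pressure and mean medication count), as used to score
#' external trials from their reported tables. Note that because the index is
#' a product, the index of the means is not the mean of per-patient indices;
#' this helper is for the summary-level comparison only.
#'
#' @param sbp_mean Mean systolic blood pressure (mmHg).
#' @param meds_mean Mean antihypertensive medication count (may be
#'   fractional, being a mean).
#' @param definition An [hti_definition()].
#' @return Numeric index score.
#' @examples
#' # CORAL trial stent arm at entry: mean SBP 150 mmHg on a mean of 2.1 drugs
#' hti_from_summary(150, 2.1)  # 93
#' @export
hti_from_summary <- function(sbp_mean, meds_mean,
                             definition = hti_definition()) {
  stopifnot(inherits(definition, "hti_definition"))
  if (!is.numeric(sbp_mean) || any(!is.finite(sbp_mean)) || any(sbp_mean <= 0)) {
    stop("'sbp_mean' must be positive finite numeric", call. = FALSE)
  }
  if (!is.numeric(meds_mean) || any(!is.finite(meds_mean)) || any(meds_mean < 0)) {
    stop("'meds_mean' must be non-negative finite numeric", call. = FALSE)
  }
  if (definition$bp_component != "systolic") {
    stop("summary-level scoring is defined for the systolic component only",
         call. = FALSE)
  }
  (sbp_mean - definition$bp_reference) * (meds_mean + definition$med_offset)
}
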