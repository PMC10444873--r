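#' Full cohort analysis with the Hypertensive Index
#'
#' One-call driver that scores a cohort, attaches the response labels,
#' builds the whole-cohort and per-group summary tables, runs the ROC
#' comparison of improvement scores against the successful-intervention
#' label, and computes the baseline-burden vs benefit rank correlation.
#'
#' @param cohort A cohort data frame ([read_cohort()], [generate_cohort()]).
#' @param definition An [hti_definition()].
#' @param policy A [test_policy()].
#' @param predictors Improvement scores entering the ROC comparison; see
#'   [compare_predictors()].
#' @return An object of class `"hti_analysis"`: list with `cohort` (labelled
#'   and scored), `definition`, `response` (group/success counts), `summary`
#'   (whole-cohort table), `groups` (per-group table), `roc`
#'   ([compare_predictors()] result), `baseline_benefit`.
#' @examples
#' fit <- hti_analysis(generate_cohort(seed = 1))
#' fit
#' summary(fit)
#' @export
hti_analysis <- function(cohort, definition = hti_definition(),
                         policy = test_policy(),
                         predictors = c("d_hti", "d_sbp", "d_dbp",
                                        "d_meds", "d_gwas")) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  labelled <- classify_cohort(cohort)
  labelled$hti_baseline <- hti(cohort$sbp_baseline, cohort$meds_baseline,
                               definition, dbp = cohort$dbp_baseline)
  labelled$hti_discharge <- hti(cohort$sbp_discharge, cohort$meds_discharge,
                                definition, dbp = cohort$dbp_discharge)
  labelled <- cbind(labelled, change_scores(cohort, definition)[-1])
  structure(
    list(cohort = labelled,
         definition = definition,
         response = cohort_response_summary(cohort),
         summary = summary_table(cohort, definition, policy),
         groups = group_summary(cohort, definition, policy),
         roc = compare_predictors(cohort, definition,
                                  predictors = predictors),
         baseline_benefit = tryCatch(baseline_vs_benefit(cohort, definition),
                                     error = function(e) NULL)),
    class = "hti_analysis"
  )
}

#' @export
print.hti_analysis <- function(x, ...) {
  r <- x$response
  cat("Hypertensive Index cohort analysis (", r$n, " patients)\n", sep = "")
  cat("  response groups 1-4: ",
      paste(r$group_counts, collapse = " / "),
      sprintf("  (%.0f%% successful)\n", 100 * r$prop_success), sep = "")
  cat("  top improvement score by AUC: ",
      x$roc$summary$predictor[1], " (",
      format(x$roc$summary$auc[1], digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.hti_analysis <- function(object, ...) {
  cat("Baseline vs discharge (whole cohort):\n")
  print(object$summary, row.names = FALSE, digits = 4)
  cat("\nROC comparison of improvement scores:\n")
  print(object$roc$summary, row.names = FALSE, digits = 4)
  if (!is.null(object$baseline_benefit)) {
    cat(sprintf("\nSpearman rho (baseline index vs improvement): %.2f (n = %d)\n",
                object$baseline_benefit$rho, object$baseline_benefit$n))
  }
  invisible(object)
}

#' @export
plot.hti_analysis <- function(x, which = c("response", "roc"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    plot(x$roc, ...)
    return(invisible(x))
  }
  coh <- x$cohort
  old <- graphics::par(mfrow = c(2, 2))
  on.exit(graphics::par(old))
  panels <- list(
    list(b = coh$sbp_baseline, d = coh$sbp_discharge,
         lab = "Systolic BP (mmHg)"),
    list(b = coh$dbp_baseline, d = coh$dbp_discharge,
         lab = "Diastolic BP (mmHg)"),
    list(b = coh$meds_baseline, d = coh$meds_discharge,
         lab = "Antihypertensive drugs"),
    list(b = coh$hti_baseline, d = coh$hti_discharge,
         lab = x$definition$name)
  )
  for (p in panels) {
    graphics::boxplot(list(baseline = p$b, discharge = p$d),
                      ylab = p$lab, col = c("grey85", "grey60"))
  }
  invisible(x)
}
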