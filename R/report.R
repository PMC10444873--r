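#' Test-selection policy for summary comparisons
#'
#' Distributional gate used throughout the reporting pipeline: normality is
#' assessed with the Shapiro-Wilk test, and the comparison then uses the
#' parametric test (paired t-test, or Welch two-sample t-test for unpaired
#' contrasts) when the gate passes, or the rank test (Wilcoxon signed-rank,
#' or Mann-Whitney U for unpaired contrasts) when it fails.
#'
#' @param normality_alpha Significance level of the normality gate.
#' @param paired Whether comparisons are paired (before/after within patient).
#' @return An object of class `"hti_test_policy"`.
#' @export
test_policy <- function(normality_alpha = 0.05, paired = TRUE) {
  if (!is.numeric(normality_alpha) || length(normality_alpha) != 1L ||
      normality_alpha <= 0 || normality_alpha >= 1) {
    stop("'normality_alpha' must be in (0, 1)", call. = FALSE)
  }
  structure(list(normality_alpha = normality_alpha, paired = isTRUE(paired)),
            class = "hti_test_policy")
}

# Shapiro-Wilk gate; returns TRUE when the sample is compatible with
# normality at the policy alpha. Sample sizes beyond the test's range are
# treated as normal (the t-test is robust there).
passes_normality <- function(x, alpha) {
  if (length(x) > 5000L) return(TRUE)
  stats::shapiro.test(x)$p.value > alpha
}

#' Paired (or two-sample) comparison with a normality-gated test choice
#'
#' In paired mode the within-patient differences are tested for normality;
#' if compatible with normality a paired t-test is used, otherwise the
#' Wilcoxon signed-rank test (the paired analogue of the Mann-Whitney U
#' test). In unpaired mode both samples are gated and the Welch two-sample
#' t-test or Mann-Whitney U test is used.
#'
#' @param before,after Numeric vectors; equal length (>= 3) in paired mode.
#' @param policy A [test_policy()].
#' @return A list with `statistic`, `p_value`, `test_name`.
#' @examples
#' set.seed(1)
#' x <- rnorm(30, 10); paired_comparison(x + 10, x)
#' @export
paired_comparison <- function(before, after, policy = test_policy()) {
  stopifnot(inherits(policy, "hti_test_policy"))
  if (!is.numeric(before) || !is.numeric(after) ||
      anyNA(before) || anyNA(after)) {
    stop("'before' and 'after' must be numeric without missing values",
         call. = FALSE)
  }
  if (policy$paired) {
    if (length(before) != length(after)) {
      stop("paired comparison requires equal-length vectors", call. = FALSE)
    }
    if (length(before) < 3L) {
      stop("insufficient data: paired comparison requires n >= 3",
           call. = FALSE)
    }
    d <- before - after
    if (stats::var(d) == 0) {
      stop("degenerate input: within-pair differences have zero variance",
           call. = FALSE)
    }
    if (passes_normality(d, policy$normality_alpha)) {
      ht <- stats::t.test(before, after, paired = TRUE)
      nm <- "paired t-test"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(before, after, paired = TRUE))
      nm <- "Wilcoxon signed-rank test"
    }
  } else {
    if (length(before) < 3L || length(after) < 3L) {
      stop("insufficient data: each sample requires n >= 3", call. = FALSE)
    }
    if (stats::var(before) == 0 && stats::var(after) == 0) {
      stop("degenerate input: both samples have zero variance", call. = FALSE)
    }
    normal <- stats::var(before) > 0 && stats::var(after) > 0 &&
      passes_normality(before, policy$normality_alpha) &&
      passes_normality(after, policy$normality_alpha)
    if (normal) {
      ht <- stats::t.test(before, after, var.equal = FALSE)
      nm <- "Welch two-sample t-test"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(before, after))
      nm <- "Mann-Whitney U test"
    }
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value, test_name = nm)
}

# One summary row for a before/after variable pair. Center policy follows
# the normality gate on the differences; dispersion is the t-based 95% CI
# half-width of the mean at each timepoint. Degenerate or too-small samples
# report NA p-values rather than failing the whole table.
summarise_pair <- function(variable, before, after, policy) {
  n <- length(before)
  ci_half <- function(x) {
    if (length(x) < 2L || stats::sd(x) == 0) return(0)
    stats::qt(0.975, length(x) - 1L) * stats::sd(x) / sqrt(length(x))
  }
  center_policy <- "mean"
  if (n >= 3L && stats::var(before - after) > 0 &&
      !passes_normality(before - after, policy$normality_alpha)) {
    center_policy <- "median"
  }
  center <- if (center_policy == "mean") mean else stats::median
  cmp <- tryCatch(paired_comparison(before, after, policy),
                  error = function(e) list(statistic = NA_real_,
                                           p_value = NA_real_,
                                           test_name = paste0("none (",
                                             conditionMessage(e), ")")))
  data.frame(variable = variable, n = n,
             baseline_center = center(before),
             discharge_center = center(after),
             baseline_dispersion = ci_half(before),
             discharge_dispersion = ci_half(after),
             center_policy = center_policy,
             p_value = cmp$p_value, test_name = cmp$test_name,
             stringsAsFactors = FALSE)
}

# Baseline/discharge vectors for the four reported variables.
variable_pairs <- function(cohort, definition) {
  list(
    sbp = list(b = cohort$sbp_baseline, d = cohort$sbp_discharge),
    dbp = list(b = cohort$dbp_baseline, d = cohort$dbp_discharge),
    meds = list(b = cohort$meds_baseline, d = cohort$meds_discharge),
    hti = list(
      b = hti(cohort$sbp_baseline, cohort$meds_baseline, definition,
              dbp = cohort$dbp_baseline),
      d = hti(cohort$sbp_discharge, cohort$meds_discharge, definition,
              dbp = cohort$dbp_discharge))
  )
}

#' Whole-cohort baseline vs discharge summary table
#'
#' One row per variable (systolic BP, diastolic BP, medication count, index)
#' with baseline and discharge centers, t-based 95% CI half-widths of the
#' mean, the paired p-value, and which test and center policy the normality
#' gate selected.
#'
#' @param cohort A non-empty cohort data frame.
#' @param definition An [hti_definition()].
#' @param policy A [test_policy()].
#' @return Data frame of summary rows.
#' @examples
#' summary_table(generate_cohort(seed = 1))
#' @export
summary_table <- function(cohort, definition = hti_definition(),
                          policy = test_policy()) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  vp <- variable_pairs(cohort, definition)
  out <- do.call(rbind, lapply(names(vp), function(v) {
    summarise_pair(v, vp[[v]]$b, vp[[v]]$d, policy)
  }))
  rownames(out) <- NULL
  out
}

#' Per-response-group summary table
#'
#' Summarises each response group separately: the index by its median (with
#' an approximate 95% CI half-width of the mean as the dispersion measure)
#' and the raw variables by mean with sd, each with the paired p-value from
#' the gated comparison. Groups with no patients are reported with `n = 0`
#' and no tests.
#'
#' @inheritParams summary_table
#' @return Data frame with columns `group`, `variable`, `n`,
#'   `baseline_center`, `discharge_center`, `baseline_dispersion`,
#'   `discharge_dispersion`, `center_policy`, `p_value`, `test_name`.
#'   Raw-variable dispersions are sds; index rows use the CI half-width.
#' @export
group_summary <- function(cohort, definition = hti_definition(),
                          policy = test_policy()) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  grp <- classify_group(cohort)
  out <- list()
  for (g in 1:4) {
    sub <- cohort[grp == g, , drop = FALSE]
    if (nrow(sub) == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        group = g, variable = c("sbp", "dbp", "meds", "hti"), n = 0L,
        baseline_center = NA_real_, discharge_center = NA_real_,
        baseline_dispersion = NA_real_, discharge_dispersion = NA_real_,
        center_policy = NA_character_, p_value = NA_real_,
        test_name = NA_character_, stringsAsFactors = FALSE)
      next
    }
    vp <- variable_pairs(sub, definition)
    rows <- lapply(names(vp), function(v) {
      row <- summarise_pair(v, vp[[v]]$b, vp[[v]]$d, policy)
      if (v == "hti") {
        row$baseline_center <- stats::median(vp[[v]]$b)
        row$discharge_center <- stats::median(vp[[v]]$d)
        row$center_policy <- "median"
      } else {
        row$baseline_center <- mean(vp[[v]]$b)
        row$discharge_center <- mean(vp[[v]]$d)
        row$baseline_dispersion <- stats::sd(vp[[v]]$b)
        row$discharge_dispersion <- stats::sd(vp[[v]]$d)
        row$center_policy <- "mean"
      }
      row
    })
    block <- do.call(rbind, rows)
    block <- cbind(group = g, block)
    out[[length(out) + 1L]] <- block
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Rank correlation of baseline index with index improvement
#'
#' Spearman correlation between each patient's baseline index and their
#' index improvement (baseline minus discharge): do the patients with the
#' highest pre-intervention burden gain the most?
#'
#' @inheritParams summary_table
#' @return List with `rho`, `p_value`, `n`.
#' @export
baseline_vs_benefit <- function(cohort, definition = hti_definition()) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) < 3L) {
    stop("insufficient data: correlation requires n >= 3", call. = FALSE)
  }
  b <- hti(cohort$sbp_baseline, cohort$meds_baseline, definition,
           dbp = cohort$dbp_baseline)
  d <- change_scores(cohort, definition)$d_hti
  if (stats::var(b) == 0 || stats::var(d) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(b, d, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(b))
}
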