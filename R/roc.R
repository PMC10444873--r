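#' ROC curve and AUC for a candidate improvement score
#'
#' Evaluates a numeric score as a detector of a binary outcome, with the
#' convention that higher scores carry more evidence of success. The area
#' under the curve is computed by the rank (concordant-pair) statistic: the
#' probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties credited one half. Operating points are reported at
#' every distinct score threshold plus `Inf`/`-Inf` sentinels, predicting
#' positive when `score >= threshold`.
#'
#' @param scores Numeric vector of scores.
#' @param labels Logical vector of outcomes (`TRUE` = positive/success).
#' @param name Label for the predictor.
#' @return An object of class `"hti_roc"`: a list with `predictor_name`,
#'   `auc`, `operating_points` (data frame of threshold, sensitivity,
#'   specificity), `n_pos`, `n_neg`.
#' @examples
#' roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc  # 1
#' @export
roc_curve <- function(scores, labels, name = "score") {
  if (length(scores) != length(labels)) {
    stop("'scores' and 'labels' must have equal length", call. = FALSE)
  }
  if (!is.logical(labels)) stop("'labels' must be logical", call. = FALSE)
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    stop("'scores' must be finite numeric", call. = FALSE)
  }
  if (anyNA(labels)) stop("'labels' must not contain NA", call. = FALSE)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L) {
    stop("degenerate input: no positive labels", call. = FALSE)
  }
  if (n_neg == 0L) {
    stop("degenerate input: no negative labels", call. = FALSE)
  }
  r <- rank(scores)  # midranks: ties credited 0.5 in the pair count
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(t) sum(labels & scores >= t) / n_pos, 0)
  spec <- vapply(thr, function(t) sum(!labels & scores < t) / n_neg, 0)
  structure(
    list(predictor_name = name, auc = auc,
         operating_points = data.frame(threshold = thr, sensitivity = sens,
                                       specificity = spec),
         n_pos = n_pos, n_neg = n_neg),
    class = "hti_roc"
  )
}

#' @export
print.hti_roc <- function(x, ...) {
  cat("ROC for ", x$predictor_name, ": AUC = ", format(x$auc, digits = 4),
      " (", x$n_pos, " positive, ", x$n_neg, " negative)\n", sep = "")
  invisible(x)
}

#' @export
plot.hti_roc <- function(x, add = FALSE, col = 1, ...) {
  op <- x$operating_points
  fpr <- 1 - op$specificity
  o <- order(fpr, op$sensitivity)
  if (add) {
    graphics::lines(fpr[o], op$sensitivity[o], col = col, ...)
  } else {
    graphics::plot(fpr[o], op$sensitivity[o], type = "l", col = col,
                   xlab = "1 - specificity", ylab = "Sensitivity",
                   main = paste0(x$predictor_name, " (AUC ",
                                 format(x$auc, digits = 3), ")"),
                   xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  }
  invisible(x)
}

#' Compare candidate improvement scores by ROC analysis
#'
#' Computes per-patient improvement scores (index improvement, systolic and
#' diastolic pressure drops, medication reduction, comparator-score
#' improvement), labels each patient by the successful-intervention rule, and
#' runs ROC analysis for each predictor on the identical labels. All
#' predictors are oriented so that larger values mean greater improvement.
#'
#' @param cohort A cohort data frame.
#' @param definition An [hti_definition()] used for `d_hti`.
#' @param predictors Character vector drawn from
#'   `c("d_hti", "d_sbp", "d_dbp", "d_meds", "d_gwas")`.
#' @param variants Optional list of additional [hti_definition()] objects;
#'   each contributes a predictor `d_<name>` (its index improvement).
#' @return An object of class `"hti_roc_comparison"`: list with `results`
#'   (named list of [roc_curve()] objects) and `summary` (data frame of
#'   predictor, auc, n_pos, n_neg, ordered by AUC descending).
#' @examples
#' coh <- generate_cohort(seed = 1)
#' compare_predictors(coh)
#' @export
compare_predictors <- function(cohort, definition = hti_definition(),
                               predictors = c("d_hti", "d_sbp", "d_dbp",
                                              "d_meds", "d_gwas"),
                               variants = NULL) {
  allowed <- c("d_hti", "d_sbp", "d_dbp", "d_meds", "d_gwas")
  if (!all(predictors %in% allowed)) {
    stop("unknown predictor(s): ",
         paste(setdiff(predictors, allowed), collapse = ", "), call. = FALSE)
  }
  cs <- change_scores(cohort, definition)
  labels <- is_success(cohort)
  scores <- cs[predictors]
  for (v in variants) {
    stopifnot(inherits(v, "hti_definition"))
    nm <- paste0("d_", v$name)
    scores[[nm]] <- change_scores(cohort, v)$d_hti
  }
  results <- lapply(names(scores), function(nm) {
    roc_curve(scores[[nm]], labels, name = nm)
  })
  names(results) <- names(scores)
  smry <- data.frame(
    predictor = names(results),
    auc = vapply(results, `[[`, 0, "auc"),
    n_pos = vapply(results, `[[`, 0L, "n_pos"),
    n_neg = vapply(results, `[[`, 0L, "n_neg"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  smry <- smry[order(-smry$auc), ]
  rownames(smry) <- NULL
  structure(list(results = results, summary = smry),
            class = "hti_roc_comparison")
}

#' @export
print.hti_roc_comparison <- function(x, ...) {
  cat("ROC comparison of improvement scores (labels: successful intervention)\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.hti_roc_comparison <- function(x, ...) {
  nms <- x$summary$predictor
  cols <- seq_along(nms)
  plot(x$results[[nms[1]]], col = cols[1],
       main = "ROC comparison of improvement scores", ...)
  if (length(nms) > 1) {
    for (i in 2:length(nms)) plot(x$results[[nms[i]]], add = TRUE, col = cols[i])
  }
  graphics::legend("bottomright", bty = "n", col = cols, lty = 1,
                   legend = sprintf("%s (AUC %.3f)", nms,
                                    x$summary$auc))
  invisible(x)
}
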