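#' Define a composite hypertensive index
#'
#' An index definition parameterises the composite score
#' `(BP component - reference) * (medication count + offset)`. The default is
#' the Hypertensive Index (HTi): systolic blood pressure, reference 120 mmHg,
#' medication offset 1, so that a patient on no antihypertensives still has a
#' nonzero multiplier.
#'
#' Variant components use reference values equal to the component's value at
#' an ideal 120/80 mmHg pressure: 80 for diastolic, 93.33 (= 80 + 40/3) for
#' mean arterial pressure, and 40 for pulse pressure. These defaults are
#' conventions of this package and can be overridden via `bp_reference`.
#'
#' @param name Label used in output tables. Defaults to `"HTi"` for the
#'   systolic index and `"HTi(<component>)"` otherwise.
#' @param bp_component Blood-pressure component entering the score: one of
#'   `"systolic"`, `"diastolic"`, `"mean_arterial"`, `"pulse_pressure"`.
#' @param bp_reference Reference pressure (mmHg) subtracted before
#'   multiplication; must be positive. Defaults per component as described.
#' @param med_offset Integer added to the medication count; must be >= 1 so
#'   that zero-medication patients retain a nonzero multiplier.
#' @return An object of class `"hti_definition"`.
#' @examples
#' hti_definition()                       # the HTi as published
#' hti_definition(bp_component = "pulse_pressure")
#' @seealso [hti()], [compare_predictors()]
#' @export
hti_definition <- function(name = NULL,
                           bp_component = c("systolic", "diastolic",
                                            "mean_arterial", "pulse_pressure"),
                           bp_reference = NULL,
                           med_offset = 1L) {
  bp_component <- match.arg(bp_component)
  if (is.null(bp_reference)) {
    bp_reference <- switch(bp_component,
      systolic = 120,
      diastolic = 80,
      mean_arterial = 80 + 40 / 3,
      pulse_pressure = 40
    )
  }
  if (!is.numeric(bp_reference) || length(bp_reference) != 1L ||
      !is.finite(bp_reference) || bp_reference <= 0) {
    stop("'bp_reference' must be a single positive finite number", call. = FALSE)
  }
  if (!is.numeric(med_offset) || length(med_offset) != 1L ||
      !is.finite(med_offset) || med_offset < 1 || med_offset != round(med_offset)) {
    stop("'med_offset' must be a single integer >= 1", call. = FALSE)
  }
  if (is.null(name)) {
    name <- if (bp_component == "systolic") "HTi" else
      paste0("HTi(", bp_component, ")")
  }
  structure(
    list(name = name, bp_component = bp_component,
         bp_reference = bp_reference, med_offset = as.integer(med_offset)),
    class = "hti_definition"
  )
}

#' @export
print.hti_definition <- function(x, ...) {
  cat("Index definition: ", x$name, "\n", sep = "")
  cat("  (", x$bp_component, " BP - ", format(x$bp_reference), ") x (n meds + ",
      x$med_offset, ")\n", sep = "")
  invisible(x)
}

#' Extract a blood-pressure component from paired systolic/diastolic readings
#'
#' @param sbp Systolic blood pressure (mmHg), numeric vector.
#' @param dbp Diastolic blood pressure (mmHg), numeric vector.
#' @param component One of `"systolic"`, `"diastolic"`, `"mean_arterial"`,
#'   `"pulse_pressure"`. Mean arterial pressure uses the one-third rule
#'   `dbp + (sbp - dbp)/3`.
#' @return Numeric vector of component values in mmHg.
#' @examples
#' bp_component_value(120, 80, "mean_arterial")  # 93.33
#' bp_component_value(120, 80, "pulse_pressure") # 40
#' @export
bp_component_value <- function(sbp, dbp,
                               component = c("systolic", "diastolic",
                                             "mean_arterial", "pulse_pressure")) {
  if (length(component) != 1L || !component %in%
      c("systolic", "diastolic", "mean_arterial", "pulse_pressure")) {
    component <- tryCatch(match.arg(component),
      error = function(e) stop("unknown blood-pressure component: ",
                               paste(component, collapse = ", "), call. = FALSE))
  }
  if (component != "systolic" && (is.null(dbp) || all(is.na(dbp)))) {
    stop("component '", component, "' requires diastolic blood pressure ('dbp')",
         call. = FALSE)
  }
  switch(component,
    systolic = sbp,
    diastolic = dbp,
    mean_arterial = dbp + (sbp - dbp) / 3,
    pulse_pressure = sbp - dbp
  )
}

# Validate one timepoint's measurements; errors name the offending field.
# dbp may be NULL when only systolic-based scores are needed.
check_measure <- function(sbp, dbp = NULL, n_meds = NULL, where = "measure") {
  if (!is.numeric(sbp) || any(!is.finite(sbp))) {
    stop(where, ": 'sbp' must be finite numeric", call. = FALSE)
  }
  if (any(sbp <= 0)) stop(where, ": 'sbp' must be positive", call. = FALSE)
  if (!is.null(dbp)) {
    if (!is.numeric(dbp) || any(!is.finite(dbp))) {
      stop(where, ": 'dbp' must be finite numeric", call. = FALSE)
    }
    if (any(dbp <= 0)) stop(where, ": 'dbp' must be positive", call. = FALSE)
    if (any(sbp <= dbp)) {
      stop(where, ": 'sbp' must exceed 'dbp'", call. = FALSE)
    }
  }
  if (!is.null(n_meds)) {
    if (!is.numeric(n_meds) || any(!is.finite(n_meds))) {
      stop(where, ": 'n_meds' must be finite numeric", call. = FALSE)
    }
    if (any(n_meds < 0)) {
      stop(where, ": 'n_meds' must be non-negative", call. = FALSE)
    }
    if (any(n_meds != round(n_meds))) {
      stop(where, ": 'n_meds' must be a whole number of prescribed agents",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
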