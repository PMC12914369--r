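# Patient-selection rules: a candidate inclusion rule combines a symptom-set
# variant with a minimum summary score, a "more than mild" requirement, and
# (optionally) documented pyuria.

#' Define a candidate diagnostic / inclusion rule
#'
#' The recommended rule for enrolling women with suspected uncomplicated
#' acute cystitis combines a minimum summary score of 6 on the six typical
#' ACSS symptoms with at least one symptom more than mild (severity >= 2)
#' and documented pyuria (>= 10 WBC/mm3 in mid-stream urine). All components
#' are configurable so competing rules (EMA three-symptom, FDA four-symptom,
#' score-only, pyuria-only) can be compared on the same cohort.
#'
#' @param variant symptom-set variant, see [variant_indices()].
#' @param min_summary minimum summary score over the variant's items
#'   (inclusive).
#' @param require_more_than_mild require at least one variant symptom with
#'   severity >= 2 (moderate or severe).
#' @param require_pyuria require WBC >= `pyuria_threshold`.
#' @param pyuria_threshold WBC per mm3; inclusive boundary.
#' @param mild_blood_qualifies if `TRUE`, mild visible blood (severity >= 1
#'   on the sixth typical item) also satisfies the more-than-mild
#'   requirement. Off by default: hematuria discriminates cases from
#'   controls even when mild, but it is evidence, not a stated inclusion
#'   criterion.
#' @param exclude_differential if `TRUE`, any differential-domain item with
#'   severity >= 2 renders the patient ineligible. Off by default: the
#'   differential domain guides work-up and carries no published cut-off.
#' @param name optional label used in reports.
#' @return an object of class `diagnostic_rule`.
#' @examples
#' diagnostic_rule() # the recommended ACSS6 score >= 6 + pyuria rule
#' @export
diagnostic_rule <- function(variant = "ACSS6",
                            min_summary = 6L,
                            require_more_than_mild = TRUE,
                            require_pyuria = TRUE,
                            pyuria_threshold = 10,
                            mild_blood_qualifies = FALSE,
                            exclude_differential = FALSE,
                            name = NULL) {
  idx <- variant_indices(variant)
  min_summary <- as.integer(min_summary)
  if (min_summary < 0L || min_summary > 3L * length(idx)) {
    stop("min_summary must lie in [0, ", 3L * length(idx), "] for variant ", variant)
  }
  if (require_pyuria && pyuria_threshold <= 0) {
    stop("pyuria_threshold must be positive when pyuria is required")
  }
  structure(list(
    variant = variant, min_summary = min_summary,
    require_more_than_mild = isTRUE(require_more_than_mild),
    require_pyuria = isTRUE(require_pyuria),
    pyuria_threshold = pyuria_threshold,
    mild_blood_qualifies = isTRUE(mild_blood_qualifies),
    exclude_differential = isTRUE(exclude_differential),
    name = name %||% sprintf("%s>=%d%s%s", variant, min_summary,
                             if (require_more_than_mild) "+mtm" else "",
                             if (require_pyuria) "+pyuria" else "")
  ), class = "diagnostic_rule")
}

#' @export
print.diagnostic_rule <- function(x, ...) {
  cat("Diagnostic rule:", x$name, "\n")
  cat(sprintf("  summary score over %s >= %d\n", x$variant, x$min_summary))
  if (x$require_more_than_mild) cat("  at least one symptom more than mild (>= 2)\n")
  if (x$require_pyuria) cat(sprintf("  pyuria >= %g WBC/mm3\n", x$pyuria_threshold))
  invisible(x)
}

#' Assess documented pyuria
#'
#' @param wbc leukocyte density, WBC per mm3 (mid-stream specimen).
#' @param threshold inclusive threshold, default 10 WBC/mm3.
#' @return `TRUE` iff `wbc >= threshold`.
#' @examples
#' assess_pyuria(10) # boundary is inclusive
#' @export
assess_pyuria <- function(wbc, threshold = 10) {
  if (any(is.na(wbc)) || any(wbc < 0)) stop("wbc must be a non-negative count per mm3")
  wbc >= threshold
}

eligibility_decision <- function(reasons) {
  structure(list(eligible = all(reasons$satisfied), reasons = reasons),
            class = "eligibility_decision")
}

#' @export
print.eligibility_decision <- function(x, ...) {
  cat(if (x$eligible) "ELIGIBLE" else "NOT ELIGIBLE", "\n")
  for (i in seq_len(nrow(x$reasons))) {
    cat(sprintf("  [%s] %s\n", if (x$reasons$satisfied[i]) "pass" else "fail",
                x$reasons$criterion[i]))
  }
  invisible(x)
}

symptom_reasons <- function(response, rule) {
  sc <- variant_score(response, rule$variant)
  mx <- max_severity(response, rule$variant)
  reasons <- data.frame(
    criterion = sprintf("summary score %s >= %d (observed %d)",
                        rule$variant, rule$min_summary, sc),
    satisfied = sc >= rule$min_summary,
    stringsAsFactors = FALSE
  )
  if (rule$require_more_than_mild) {
    mtm <- mx >= 2L ||
      (rule$mild_blood_qualifies && response$typical[6L] >= 1L)
    reasons <- rbind(reasons, data.frame(
      criterion = sprintf("at least one symptom more than mild (max severity %d)", mx),
      satisfied = mtm, stringsAsFactors = FALSE))
  }
  if (rule$exclude_differential) {
    reasons <- rbind(reasons, data.frame(
      criterion = "no differential-domain item moderate or worse",
      satisfied = all(response$differential < 2L), stringsAsFactors = FALSE))
  }
  reasons
}

#' Assess the symptom component of an inclusion rule
#'
#' Applies the score and severity criteria of a [diagnostic_rule] to a
#' baseline Part A response. Pyuria is not considered here; see [enroll()].
#'
#' @param response baseline Part A [acss_response].
#' @param rule a [diagnostic_rule].
#' @return an `eligibility_decision` with per-criterion reasons.
#' @examples
#' assess_symptoms(acss_response(c(2, 1, 1, 1, 1, 0)), diagnostic_rule())
#' @export
assess_symptoms <- function(response, rule = diagnostic_rule()) {
  stopifnot(inherits(response, "acss_response"), inherits(rule, "diagnostic_rule"))
  if (response$part != "A") stop("eligibility is assessed on baseline Part A responses")
  eligibility_decision(symptom_reasons(response, rule))
}

#' Full enrolment decision for one patient
#'
#' Conjunction of the symptom criteria and, when the rule requires it,
#' documented pyuria from the urinalysis of the same visit.
#'
#' @inheritParams assess_symptoms
#' @param urine a [urine_result] from the same patient and visit.
#' @return an `eligibility_decision`.
#' @export
enroll <- function(response, urine, rule = diagnostic_rule()) {
  stopifnot(inherits(response, "acss_response"), inherits(urine, "urine_result"))
  if (response$part != "A") stop("eligibility is assessed on baseline Part A responses")
  if (!is.na(response$patient_id) && !is.na(urine$patient_id) &&
      response$patient_id != urine$patient_id) {
    stop("questionnaire and urinalysis belong to different patients")
  }
  reasons <- symptom_reasons(response, rule)
  if (rule$require_pyuria) {
    reasons <- rbind(reasons, data.frame(
      criterion = sprintf("pyuria >= %g WBC/mm3 (observed %g)",
                          rule$pyuria_threshold, urine$wbc),
      satisfied = assess_pyuria(urine$wbc, rule$pyuria_threshold),
      stringsAsFactors = FALSE))
  }
  eligibility_decision(reasons)
}

# Vectorised rule application over a cohort table (t1..t6 + wbc columns).
# Used by the diagnostic-accuracy sweep and the trial engine funnel.
apply_rule_matrix <- function(typ, wbc, rule, differential = NULL) {
  idx <- variant_indices(rule$variant)
  sub <- typ[, idx, drop = FALSE]
  ok <- rowSums(sub) >= rule$min_summary
  if (rule$require_more_than_mild) {
    mtm <- apply(sub, 1L, max) >= 2L
    if (rule$mild_blood_qualifies) mtm <- mtm | typ[, 6L] >= 1L
    ok <- ok & mtm
  }
  if (rule$exclude_differential && !is.null(differential)) {
    ok <- ok & apply(differential, 1L, max) < 2L
  }
  if (rule$require_pyuria) ok <- ok & (wbc >= rule$pyuria_threshold)
  unname(ok)
}

cohort_typical_matrix <- function(df) {
  as.matrix(df[paste0("t", 1:6)])
}

#' Apply an inclusion rule to a cohort table
#'
#' @param cohort data frame with questionnaire columns `t1..t6` and, when the
#'   rule requires pyuria, a `wbc_mm3` column.
#' @param rule a [diagnostic_rule].
#' @return logical vector of enrolment decisions, one per row.
#' @export
apply_rule <- function(cohort, rule) {
  stopifnot(inherits(rule, "diagnostic_rule"))
  typ <- cohort_typical_matrix(cohort)
  wbc <- if ("wbc_mm3" %in% names(cohort)) cohort$wbc_mm3 else rep(NA_real_, nrow(cohort))
  if (rule$require_pyuria && anyNA(wbc)) {
    stop("rule requires pyuria but cohort lacks complete wbc_mm3 data")
  }
  dif <- if (all(paste0("d", 1:4) %in% names(cohort))) as.matrix(cohort[paste0("d", 1:4)]) else NULL
  apply_rule_matrix(typ, wbc, rule, differential = dif)
}
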