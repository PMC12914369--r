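# Visit-window classification and cure/failure adjudication. The follow-up
# schedule and all cure thresholds operate on Part B ACSS responses.

VISIT_WINDOWS <- c("early", "end_of_treatment", "toc", "late_fu")

#' Classify a visit day into the follow-up schedule
#'
#' Windows, in days since start of treatment: early effect 2-4; end of
#' treatment 5-9; test of cure (TOC) 5-7 days after the end of treatment;
#' late follow-up 24-33. Days outside every window are `"unscheduled"`. When
#' a day falls into overlapping windows (possible for short treatments) the
#' later-stage label wins, since later windows are analytically primary.
#'
#' @param day integer day since start of treatment (>= 0).
#' @param treatment_end_day last day of treatment (>= 1).
#' @return one of `"early"`, `"end_of_treatment"`, `"toc"`, `"late_fu"`,
#'   `"unscheduled"`.
#' @examples
#' classify_visit(3, treatment_end_day = 5)  # early
#' classify_visit(11, treatment_end_day = 5) # toc
#' @export
classify_visit <- function(day, treatment_end_day = 5L) {
  if (any(is.na(day)) || any(day < 0)) stop("visit day must be a non-negative integer")
  if (treatment_end_day < 1) stop("treatment_end_day must be >= 1")
  one <- function(d) {
    if (d >= 24 && d <= 33) return("late_fu")
    if (d - treatment_end_day >= 5 && d - treatment_end_day <= 7) return("toc")
    if (d >= 5 && d <= 9) return("end_of_treatment")
    if (d >= 2 && d <= 4) return("early")
    "unscheduled"
  }
  vapply(day, one, character(1))
}

#' Cure/failure thresholds on the ACSS
#'
#' Five competing definitions of clinical cure at a follow-up visit:
#' \describe{
#'   \item{`ACSS5`}{summary score of the five typical ACSS symptoms <= 5,
#'     no symptom more than mild (severity <= 1), and no visible blood in
#'     urine. Its complement is the failure rule: score >= 6 or any symptom
#'     at severity >= 2. The favoured primary definition.}
#'   \item{`FDA4`}{the four FDA symptoms, score <= 4, same per-item cap and
#'     blood exclusion (failure at score >= 5).}
#'   \item{`EMA3`}{the three EMA symptoms, score <= 3 (failure at
#'     score >= 4).}
#'   \item{`ACSS5_QOL`}{`ACSS5` plus every quality-of-life item at most
#'     `qol_max_item` (default mild); adding QoL tightens the definition and
#'     lowers apparent success rates.}
#'   \item{`DYNAMICS_ONLY`}{the patient's overall assessment alone:
#'     success iff the Dynamics item is in `dynamics_success_levels`
#'     (default: fully recovered only). Included for comparability; on its
#'     own it is not sensitive enough to be a suitable outcome measure.}
#' }
#'
#' @param name threshold name.
#' @param qol_max_item per-item QoL cap for `ACSS5_QOL`.
#' @param dynamics_success_levels Dynamics levels counted as success for
#'   `DYNAMICS_ONLY` (scale 0 = fully recovered ... 4 = worse).
#' @return an object of class `outcome_threshold`.
#' @export
outcome_threshold <- function(name = c("ACSS5", "FDA4", "EMA3",
                                       "ACSS5_QOL", "DYNAMICS_ONLY"),
                              qol_max_item = 1L,
                              dynamics_success_levels = 0L) {
  name <- match.arg(name)
  spec <- switch(name,
    ACSS5 = list(variant = "ACSS5", max_summary = 5L, max_item = 1L,
                 forbid_visible_blood = TRUE, qol_max_item = NA_integer_),
    FDA4 = list(variant = "FDA4", max_summary = 4L, max_item = 1L,
                forbid_visible_blood = TRUE, qol_max_item = NA_integer_),
    EMA3 = list(variant = "EMA3", max_summary = 3L, max_item = 1L,
                forbid_visible_blood = TRUE, qol_max_item = NA_integer_),
    ACSS5_QOL = list(variant = "ACSS5", max_summary = 5L, max_item = 1L,
                     forbid_visible_blood = TRUE,
                     qol_max_item = as.integer(qol_max_item)),
    DYNAMICS_ONLY = list(variant = NA_character_, max_summary = NA_integer_,
                         max_item = NA_integer_, forbid_visible_blood = FALSE,
                         qol_max_item = NA_integer_)
  )
  structure(c(list(name = name), spec,
              list(dynamics_success_levels = as.integer(dynamics_success_levels))),
            class = "outcome_threshold")
}

#' Adjudicate clinical cure or failure at one follow-up visit
#'
#' Rescue therapy (switching to another antibiotic) is always clinical
#' failure. Otherwise, under a score threshold, failure is declared when the
#' variant summary score exceeds `max_summary`, any variant symptom exceeds
#' `max_item` (i.e. is moderate or severe), visible blood is present (when
#' the threshold forbids it), a QoL item exceeds the QoL cap (`ACSS5_QOL`),
#' or the Dynamics item is outside the success levels (`DYNAMICS_ONLY`).
#' Everything else is success.
#'
#' Visible blood of any severity additionally raises `hematuria_flag`,
#' independently of the adjudicated status: persistent visible hematuria
#' raises the suspicion that the bleeding source is not the infection and
#' requires differential-diagnostic work-up.
#'
#' @param response Part B [acss_response] with complete scored items.
#' @param threshold an [outcome_threshold] (or its name).
#' @param rescue_taken logical; `TRUE` when the patient switched to rescue
#'   antibiotic therapy on or before the visit.
#' @return an object of class `adjudication`: `status` (`"success"` /
#'   `"failure"`), `hematuria_flag`, and the `reasons` that fired.
#' @examples
#' adjudicate(acss_response(c(1, 1, 1, 1, 1, 0), part = "B", visit_day = 11,
#'                          dynamics = 1), "ACSS5")
#' @export
adjudicate <- function(response, threshold = "ACSS5", rescue_taken = FALSE) {
  stopifnot(inherits(response, "acss_response"))
  if (is.character(threshold)) threshold <- outcome_threshold(threshold)
  stopifnot(inherits(threshold, "outcome_threshold"))
  if (response$part != "B") stop("outcome is adjudicated on follow-up Part B responses")

  reasons <- character()
  blood <- response$typical[[6L]]
  if (threshold$name == "DYNAMICS_ONLY") {
    if (is.na(response$dynamics)) stop("DYNAMICS_ONLY threshold requires the Dynamics item")
    if (!response$dynamics %in% threshold$dynamics_success_levels) {
      reasons <- c(reasons, sprintf("dynamics level %d not a success level", response$dynamics))
    }
  } else {
    sc <- variant_score(response, threshold$variant)
    mx <- max_severity(response, threshold$variant)
    if (sc > threshold$max_summary) {
      reasons <- c(reasons, sprintf("%s summary score %d > %d",
                                    threshold$variant, sc, threshold$max_summary))
    }
    if (mx > threshold$max_item) {
      reasons <- c(reasons, sprintf("symptom severity %d > %d (more than mild)",
                                    mx, threshold$max_item))
    }
    if (threshold$forbid_visible_blood && blood >= 1L) {
      reasons <- c(reasons, "visible blood in urine present")
    }
    if (!is.na(threshold$qol_max_item) && any(response$qol > threshold$qol_max_item)) {
      reasons <- c(reasons, sprintf("QoL item above %d", threshold$qol_max_item))
    }
  }
  if (isTRUE(rescue_taken)) {
    reasons <- c("rescue antibiotic therapy taken", reasons)
  }
  structure(list(
    status = if (length(reasons)) "failure" else "success",
    hematuria_flag = blood >= 1L,
    reasons = reasons
  ), class = "adjudication")
}

#' @export
print.adjudication <- function(x, ...) {
  cat("Adjudication:", toupper(x$status),
      if (x$hematuria_flag) "(hematuria flagged)" else "", "\n")
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

# Vectorised adjudication over a typical-severity matrix (n x 6). Returns a
# logical success vector; the scalar adjudicate() is the reference semantics.
adjudicate_matrix <- function(typ, threshold, rescue = rep(FALSE, nrow(typ)),
                              qol = NULL, dynamics = NULL) {
  if (is.character(threshold)) threshold <- outcome_threshold(threshold)
  if (threshold$name == "DYNAMICS_ONLY") {
    if (is.null(dynamics) || anyNA(dynamics)) stop("DYNAMICS_ONLY threshold requires the Dynamics item")
    success <- dynamics %in% threshold$dynamics_success_levels
  } else {
    idx <- variant_indices(threshold$variant)
    sub <- typ[, idx, drop = FALSE]
    success <- rowSums(sub) <= threshold$max_summary &
      apply(sub, 1L, max) <= threshold$max_item
    if (threshold$forbid_visible_blood) success <- success & typ[, 6L] == 0L
    if (!is.na(threshold$qol_max_item)) {
      if (is.null(qol)) stop("threshold requires QoL items")
      success <- success & apply(qol, 1L, max) <= threshold$qol_max_item
    }
  }
  success & !rescue
}

#' Smallest summary score incompatible with clinical cure
#'
#' Exhaustively enumerates every severity vector over a threshold's symptom
#' set (4^k vectors, severities 0-3, visible blood absent) and returns the
#' smallest summary score attained by no cure-classified vector. Because
#' cure caps every item at mild, this floor equals the failure cut of the
#' corresponding failure rule: 6 for the five-symptom score, 5 for the
#' four-symptom FDA set, 4 for the three-symptom EMA set, so cure and
#' failure definitions tile the score range without gap or overlap.
#'
#' @param threshold a score-based [outcome_threshold()] or its name.
#' @return integer score floor.
#' @examples
#' cure_score_floor("ACSS5")
#' @export
cure_score_floor <- function(threshold = "ACSS5") {
  if (is.character(threshold)) threshold <- outcome_threshold(threshold)
  if (threshold$name == "DYNAMICS_ONLY") stop("score floor needs a score-based threshold")
  k <- length(variant_indices(threshold$variant))
  grid <- as.matrix(expand.grid(rep(list(0:3), k), KEEP.OUT.ATTRS = FALSE))
  typ <- cbind(grid, matrix(0L, nrow(grid), 6L - k))
  qol <- matrix(0L, nrow(grid), 3L)
  cure <- adjudicate_matrix(typ, threshold, qol = qol)
  scores <- rowSums(grid)
  min(setdiff(0:(3L * k), unique(scores[cure])))
}

#' Tabulate adjudicated success by threshold and visit window
#'
#' @param adjudications data frame with columns `patient_id`, `window`,
#'   `threshold` and `status` (`"success"`/`"failure"`), at most one row per
#'   patient, window and threshold.
#' @return data frame of `threshold`, `window`, `n_success`, `n_total`,
#'   `proportion`.
#' @export
success_table <- function(adjudications) {
  need <- c("patient_id", "window", "threshold", "status")
  stopifnot(all(need %in% names(adjudications)))
  if (nrow(adjudications) == 0) {
    return(data.frame(threshold = character(), window = character(),
                      n_success = integer(), n_total = integer(),
                      proportion = numeric(), stringsAsFactors = FALSE))
  }
  key <- interaction(adjudications$patient_id, adjudications$window,
                     adjudications$threshold, drop = TRUE)
  if (anyDuplicated(key)) stop("duplicate patient-window-threshold adjudications")
  agg <- stats::aggregate(status ~ threshold + window, data = adjudications,
                          FUN = function(s) c(succ = sum(s == "success"), tot = length(s)))
  out <- data.frame(threshold = agg$threshold, window = agg$window,
                    n_success = as.integer(agg$status[, "succ"]),
                    n_total = as.integer(agg$status[, "tot"]),
                    stringsAsFactors = FALSE)
  out$proportion <- out$n_success / out$n_total
  ord <- order(match(out$threshold, c("ACSS5", "FDA4", "EMA3", "ACSS5_QOL", "DYNAMICS_ONLY")),
               match(out$window, VISIT_WINDOWS))
  out[ord, , drop = FALSE]
}
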