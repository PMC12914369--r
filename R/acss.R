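#' @keywords internal
"_PACKAGE"

# Canonical item order of the ACSS "Typical" domain. Column order in all
# tabular interfaces follows this vector; files carry explicit column names
# (t1..t6) so that order mistakes are detectable.
ACSS_TYPICAL_ITEMS <- c(
  "frequency", "urgency", "dysuria",
  "suprapubic_pain", "incomplete_emptying", "visible_blood"
)

ACSS_DOMAIN_SIZES <- c(typical = 6L, differential = 4L, qol = 3L, additional = 5L)

# Nested symptom-set variants used for eligibility and outcome thresholds.
ACSS_VARIANTS <- list(
  EMA3  = 1:3, # frequency, urgency, dysuria
  FDA4  = 1:4, # + suprapubic pain
  ACSS5 = 1:5, # + sense of incomplete bladder emptying
  ACSS6 = 1:6  # + visible blood in urine
)

#' Symptom-set variants of the ACSS typical domain
#'
#' The six "typical" cystitis symptoms of the ACSS (urinary frequency,
#' urgency, dysuria, suprapubic pain, sense of incomplete bladder emptying,
#' visible blood in urine) admit four nested sub-scores: the three symptoms
#' named by the EMA guideline (`"EMA3"`), the four named by the FDA guideline
#' (`"FDA4"`), the first five ACSS symptoms (`"ACSS5"`), and all six
#' (`"ACSS6"`).
#'
#' @param variant one of `"EMA3"`, `"FDA4"`, `"ACSS5"`, `"ACSS6"`.
#' @return integer indices into the typical-domain item vector
#'   (order: frequency, urgency, dysuria, suprapubic pain, incomplete
#'   emptying, visible blood).
#' @examples
#' variant_indices("EMA3")
#' @export
variant_indices <- function(variant) {
  variant <- match.arg(variant, names(ACSS_VARIANTS))
  ACSS_VARIANTS[[variant]]
}

check_severity <- function(x, n, what) {
  msgs <- character()
  if (length(x) != n) {
    msgs <- c(msgs, sprintf("%s: expected %d items, got %d (missing item)", what, n, length(x)))
    return(msgs)
  }
  bad_na <- is.na(x)
  if (any(bad_na)) {
    msgs <- c(msgs, sprintf("%s: missing value at item %s", what,
                            paste(which(bad_na), collapse = ", ")))
  }
  ok <- !bad_na
  if (any(x[ok] != as.integer(x[ok]) | x[ok] < 0 | x[ok] > 3)) {
    msgs <- c(msgs, sprintf("%s: severity out of range (must be integer 0-3)", what))
  }
  msgs
}

#' Construct one ACSS questionnaire administration
#'
#' One completed ACSS form: Part A at baseline (diagnosis) or Part B at a
#' follow-up visit. Each item of the Typical, Differential and QoL domains is
#' an ordinal severity on a 4-point scale: 0 (absent), 1 (mild), 2 (moderate),
#' 3 (severe). The Additional domain holds five yes/no condition flags that
#' are stored but never scored. Part B additionally carries a "Dynamics" item
#' summarising overall symptom evolution, encoded here on an ordinal 0-4
#' scale (0 = fully recovered ... 4 = worse).
#'
#' @param typical integer vector of 6 severities, in the order frequency,
#'   urgency, dysuria, suprapubic pain, incomplete emptying, visible blood.
#' @param differential integer vector of 4 severities (differential-diagnosis
#'   items).
#' @param qol integer vector of 3 severities (quality-of-life items).
#' @param additional logical vector of 5 yes/no flags.
#' @param part `"A"` (baseline/diagnostic) or `"B"` (follow-up).
#' @param visit_day integer day relative to treatment start (<= 0 for
#'   baseline).
#' @param dynamics optional ordinal 0-4; Part B only.
#' @param patient_id optional identifier.
#' @return an object of class `acss_response`.
#' @examples
#' acss_response(c(2, 2, 3, 1, 1, 0))
#' @export
acss_response <- function(typical,
                          differential = rep(0L, 4),
                          qol = rep(0L, 3),
                          additional = rep(FALSE, 5),
                          part = c("A", "B"),
                          visit_day = 0L,
                          dynamics = NULL,
                          patient_id = NA_character_) {
  part <- match.arg(part)
  rec <- list(
    patient_id = as.character(patient_id), part = part,
    visit_day = as.integer(visit_day),
    typical = as.integer(typical), differential = as.integer(differential),
    qol = as.integer(qol), additional = as.logical(additional),
    dynamics = if (is.null(dynamics) || is.na(dynamics)) NA_integer_ else as.integer(dynamics)
  )
  v <- response_violations(rec)
  if (length(v)) {
    stop("invalid ACSS response: ", paste(v, collapse = "; "), call. = FALSE)
  }
  names(rec$typical) <- ACSS_TYPICAL_ITEMS
  structure(rec, class = "acss_response")
}

response_violations <- function(rec) {
  v <- character()
  v <- c(v, check_severity(rec$typical, 6L, "typical"))
  v <- c(v, check_severity(rec$differential, 4L, "differential"))
  v <- c(v, check_severity(rec$qol, 3L, "qol"))
  if (length(rec$additional) != 5L) {
    v <- c(v, sprintf("additional: expected 5 items, got %d (missing item)", length(rec$additional)))
  } else if (any(is.na(rec$additional))) {
    v <- c(v, "additional: missing value")
  }
  if (!rec$part %in% c("A", "B")) v <- c(v, "part must be 'A' or 'B'")
  if (!is.na(rec$dynamics)) {
    if (identical(rec$part, "A")) v <- c(v, "dynamics item present on Part A")
    else if (rec$dynamics < 0 || rec$dynamics > 4) v <- c(v, "dynamics out of range (must be integer 0-4)")
  }
  v
}

#' Validate a raw questionnaire record
#'
#' Checks a raw key-value record (a named list or one-row data frame in the
#' `t1..t6, d1..d4, q1..q3, a1..a5, dyn` column layout) against all ACSS
#' response constraints. Never raises on invalid content: violations are
#' returned as values so that batch imports can report every problem.
#'
#' @param record named list or one-row data frame.
#' @return a list with `response` (an [acss_response] or `NULL`) and
#'   `violations` (character vector, empty when valid).
#' @examples
#' rec <- list(patient_id = "p1", part = "A", visit_day = 0,
#'             t1 = 2, t2 = 2, t3 = 1, t4 = 1, t5 = 0, t6 = 0,
#'             d1 = 0, d2 = 0, d3 = 0, d4 = 0, q1 = 1, q2 = 1, q3 = 0,
#'             a1 = 0, a2 = 0, a3 = 0, a4 = 0, a5 = 0, dyn = NA)
#' validate_response(rec)$violations
#' @export
validate_response <- function(record) {
  record <- as.list(record)
  pick <- function(prefix, n) {
    keys <- paste0(prefix, seq_len(n))
    present <- keys %in% names(record)
    out <- rep(NA_real_, n)
    for (i in which(present)) {
      val <- suppressWarnings(as.numeric(record[[keys[i]]]))
      out[i] <- if (length(val) == 1L) val else NA_real_
    }
    # trailing absent keys shorten the vector so they surface as a
    # "missing item" violation rather than a missing value
    if (!all(present)) out <- out[seq_len(max(c(0L, which(present))))]
    out
  }
  typ <- pick("t", 6L); dif <- pick("d", 4L); qol <- pick("q", 3L); add <- pick("a", 5L)
  part <- if (!is.null(record$part)) as.character(record$part) else NA_character_
  dyn <- if (!is.null(record$dyn)) suppressWarnings(as.numeric(record$dyn)) else NA_real_
  rec <- list(
    patient_id = as.character(record$patient_id %||% NA_character_),
    part = part,
    visit_day = as.integer(record$visit_day %||% 0L),
    typical = typ, differential = dif, qol = qol,
    additional = as.logical(add),
    dynamics = if (is.na(dyn)) NA_integer_ else as.integer(dyn)
  )
  if (is.na(rec$part) || !rec$part %in% c("A", "B")) {
    probe <- rec; probe$part <- "B" # item checks only; part-dependent rules skipped
    v <- c("part must be 'A' or 'B'", response_violations(probe))
    return(list(response = NULL, violations = unique(v)))
  }
  v <- response_violations(rec)
  if (length(v)) return(list(response = NULL, violations = v))
  resp <- acss_response(rec$typical, rec$differential, rec$qol, rec$additional,
                        part = rec$part, visit_day = rec$visit_day,
                        dynamics = if (is.na(rec$dynamics)) NULL else rec$dynamics,
                        patient_id = rec$patient_id)
  list(response = resp, violations = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.acss_response <- function(x, ...) {
  cat(sprintf("ACSS Part %s response (patient %s, day %d)\n",
              x$part, x$patient_id, x$visit_day))
  cat("  typical:     ", paste(sprintf("%s=%d", ACSS_TYPICAL_ITEMS, x$typical), collapse = " "), "\n")
  cat("  differential:", paste(x$differential, collapse = " "),
      " qol:", paste(x$qol, collapse = " "), "\n")
  if (!is.na(x$dynamics)) cat("  dynamics:", x$dynamics, "\n")
  invisible(x)
}

#' Summary score of one ACSS domain
#'
#' Sum of the ordinal item severities of the named domain. The Additional
#' domain is dichotomous and has no score.
#'
#' @param response an [acss_response].
#' @param domain `"typical"`, `"differential"` or `"qol"`.
#' @return integer summary score in `[0, 3k]` for a k-item domain.
#' @examples
#' score_domain(acss_response(c(1, 1, 1, 1, 1, 0)), "typical")
#' @export
score_domain <- function(response, domain = c("typical", "differential", "qol")) {
  stopifnot(inherits(response, "acss_response"))
  domain <- match.arg(domain)
  sum(response[[domain]])
}

#' Summary score over a symptom-set variant
#'
#' Sum of the typical-domain severities restricted to the items of a nested
#' symptom-set variant. `variant_score(x, "ACSS6")` equals
#' `score_domain(x, "typical")`.
#'
#' @inheritParams score_domain
#' @param variant variant name, see [variant_indices()].
#' @return integer score in `[0, 3 * |variant|]`.
#' @examples
#' variant_score(acss_response(c(2, 1, 1, 3, 0, 0)), "EMA3")
#' @export
variant_score <- function(response, variant = "ACSS6") {
  stopifnot(inherits(response, "acss_response"))
  sum(response$typical[variant_indices(variant)])
}

#' Maximum symptom severity over a symptom-set variant
#'
#' @inheritParams variant_score
#' @return the largest severity (0-3) among the variant's items.
#' @examples
#' max_severity(acss_response(c(1, 2, 0, 0, 0, 0)), "EMA3")
#' @export
max_severity <- function(response, variant = "ACSS6") {
  stopifnot(inherits(response, "acss_response"))
  max(response$typical[variant_indices(variant)])
}
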