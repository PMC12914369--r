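# Shared fixtures and independent brute-force oracles. The oracles stay
# deliberately naive (loops, enumeration) so they cannot share a defect with
# the vectorised implementation paths they check.

resp <- function(typical, part = "A", visit_day = 0L, dynamics = NULL, ...) {
  acss_response(typical, part = part, visit_day = visit_day,
                dynamics = dynamics, ...)
}

respB <- function(typical, dynamics = 1L, visit_day = 11L, ...) {
  acss_response(typical, part = "B", visit_day = visit_day,
                dynamics = dynamics, ...)
}

# every severity vector of length k as a matrix (4^k rows)
all_severity_vectors <- function(k) {
  as.matrix(expand.grid(rep(list(0:3), k), KEEP.OUT.ATTRS = FALSE))
}

# all-pairs AUC with ties counted one half
oracle_auc <- function(cases, controls) {
  s <- 0
  for (a in cases) for (b in controls) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(cases) * length(controls))
}

# naive per-subject eligibility for the six-symptom score>=6 more-than-mild rule
oracle_eligible <- function(v) sum(v) >= 6 && max(v) >= 2

# a small labelled cohort data frame in the questionnaire + urinalysis layout
make_cohort_df <- function(typ, wbc, reference) {
  df <- data.frame(patient_id = sprintf("c%03d", seq_len(nrow(typ))))
  df[paste0("t", 1:6)] <- as.data.frame(typ)
  df$wbc_mm3 <- wbc
  df$reference <- reference
  df
}
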