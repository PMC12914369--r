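# Synthetic-data generator. Emulates (a) a diagnostic case/control study of
# women presenting with urinary symptoms and (b) a two-arm longitudinal
# outcome trial, so that scoring, eligibility, adjudication and analysis are
# exercisable end to end without patient data. All draws are seeded;
# identical parameters and seed reproduce byte-identical outputs.

#' Build a per-item severity distribution matrix
#'
#' Stacks one categorical distribution over severities 0-3 per item; every
#' row must sum to 1 (within 1e-9). Used to configure the generators.
#'
#' @param rows list of length-4 probability vectors, one per item.
#' @param items item names.
#' @return numeric matrix (items x severities 0-3).
#' @examples
#' severity_dist_matrix(rep(list(c(0.7, 0.3, 0, 0)), 6),
#'                      paste0("t", 1:6))
#' @export
severity_dist_matrix <- function(rows, items) {
  m <- do.call(rbind, rows)
  rownames(m) <- items
  colnames(m) <- as.character(0:3)
  bad <- abs(rowSums(m) - 1) > 1e-9 | apply(m < 0, 1, any)
  if (any(bad)) stop("severity distributions must be non-negative and sum to 1: ",
                     paste(items[bad], collapse = ", "))
  m
}

# Default per-item severity distributions (columns: severity 0,1,2,3).
# Cases: the classic triad (frequency, urgency, dysuria) usually moderate or
# worse; suprapubic pain and incomplete emptying frequent but milder;
# visible blood uncommon and mostly mild. Controls: occasional mild
# complaints, hematuria rare. Calibrated so the six-symptom score >= 6 rule
# with the more-than-mild requirement operates near sensitivity 0.85 /
# specificity 0.88, the published range for symptom-only rules.
default_case_typical <- function(blood_mild_prob = 0.22) {
  severity_dist_matrix(list(
    c(0.08, 0.27, 0.40, 0.25),
    c(0.08, 0.30, 0.40, 0.22),
    c(0.12, 0.28, 0.35, 0.25),
    c(0.28, 0.37, 0.24, 0.11),
    c(0.38, 0.36, 0.19, 0.07),
    c(1 - blood_mild_prob, blood_mild_prob, 0, 0)
  ), ACSS_TYPICAL_ITEMS)
}

default_control_typical <- function(blood_mild_prob = 0.03) {
  severity_dist_matrix(list(
    c(0.46, 0.34, 0.16, 0.04),
    c(0.45, 0.36, 0.15, 0.04),
    c(0.61, 0.27, 0.09, 0.03),
    c(0.63, 0.25, 0.09, 0.03),
    c(0.59, 0.29, 0.09, 0.03),
    c(1 - blood_mild_prob, blood_mild_prob, 0, 0)
  ), ACSS_TYPICAL_ITEMS)
}

default_differential <- function() {
  severity_dist_matrix(rep(list(c(0.80, 0.14, 0.05, 0.01)), 4), paste0("d", 1:4))
}

default_case_qol <- function() {
  severity_dist_matrix(rep(list(c(0.10, 0.30, 0.40, 0.20)), 3), paste0("q", 1:3))
}

default_control_qol <- function() {
  severity_dist_matrix(rep(list(c(0.75, 0.18, 0.05, 0.02)), 3), paste0("q", 1:3))
}

DEFAULT_SPECIES_FREQ <- c(
  "Escherichia coli" = 0.70,
  "Staphylococcus saprophyticus" = 0.10,
  "Klebsiella pneumoniae" = 0.08,
  "Proteus mirabilis" = 0.05,
  "Enterococcus faecalis" = 0.07
)

#' Parameters of the synthetic diagnostic case/control cohort
#'
#' The `"study2019"` preset mirrors the size of the diagnostic development
#' cohort: 285 women with uncomplicated acute cystitis and 232 controls
#' (517 respondents). Severities are drawn independently per item from
#' status-specific categorical distributions over 0-3; WBC densities from
#' status-specific log-normal distributions calibrated so that pyuria alone
#' (>= 10 WBC/mm3) operates near sensitivity 0.85 / specificity 0.72, the
#' published operating point of the pyuria test; colony counts are
#' log-uniform over 1e1-1e8 CFU/mL.
#'
#' @param n_cases,n_controls subject counts.
#' @param case_typical,control_typical 6 x 4 per-item severity distributions
#'   (rows items, columns severities 0-3).
#' @param blood_mild_prob length-2 numeric `c(case, control)` probability of
#'   (mild) visible blood; overrides row 6 of the typical distributions.
#' @param case_qol,control_qol 3 x 4 QoL severity distributions.
#' @param differential 4 x 4 severity distribution shared by both groups.
#' @param case_wbc,control_wbc `c(meanlog, sdlog)` of the log-normal WBC/mm3
#'   distribution.
#' @param case_culture_pos,control_culture_pos probability of bacterial
#'   growth on culture.
#' @param species_freq named probability vector over uropathogen species.
#' @param cfu_log10_range range of log10 CFU/mL for grown isolates.
#' @param latent_mixing optional in `[0, 1)`: when positive, a shared
#'   patient-level latent severity shifts all typical items jointly,
#'   inducing item correlation for stress-testing rules. Default off; no
#'   published correlation structure exists.
#' @return object of class `cohort_params`.
#' @export
cohort_params <- function(n_cases = 285L, n_controls = 232L,
                          case_typical = NULL, control_typical = NULL,
                          blood_mild_prob = c(0.22, 0.03),
                          case_qol = default_case_qol(),
                          control_qol = default_control_qol(),
                          differential = default_differential(),
                          case_wbc = c(meanlog = 3.55, sdlog = 1.2),
                          control_wbc = c(meanlog = 1.72, sdlog = 1.0),
                          case_culture_pos = 0.85, control_culture_pos = 0.10,
                          species_freq = DEFAULT_SPECIES_FREQ,
                          cfu_log10_range = c(1, 8),
                          latent_mixing = 0) {
  if (n_cases < 0 || n_controls < 0) stop("cohort sizes must be non-negative")
  if (is.null(case_typical)) case_typical <- default_case_typical(blood_mild_prob[1])
  if (is.null(control_typical)) control_typical <- default_control_typical(blood_mild_prob[2])
  for (m in list(case_typical, control_typical, case_qol, control_qol, differential)) {
    if (any(abs(rowSums(m) - 1) > 1e-9)) stop("severity distributions must sum to 1 per item")
  }
  if (abs(sum(species_freq) - 1) > 1e-9) stop("species frequencies must sum to 1")
  if (latent_mixing < 0 || latent_mixing >= 1) stop("latent_mixing must lie in [0, 1)")
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    case_typical = case_typical, control_typical = control_typical,
    case_qol = case_qol, control_qol = control_qol, differential = differential,
    case_wbc = case_wbc, control_wbc = control_wbc,
    case_culture_pos = case_culture_pos, control_culture_pos = control_culture_pos,
    species_freq = species_freq, cfu_log10_range = cfu_log10_range,
    latent_mixing = latent_mixing
  ), class = "cohort_params")
}

#' @rdname cohort_params
#' @param preset preset name; `"study2019"` is the 285-case / 232-control
#'   diagnostic cohort.
#' @export
cohort_preset <- function(preset = "study2019") {
  preset <- match.arg(preset, "study2019")
  cohort_params(n_cases = 285L, n_controls = 232L)
}

# Draw an n x k severity matrix, each column j from dist[j, ]. With
# latent mixing, a per-subject uniform latent u shifts every item's draw
# toward the same tail via a Gaussian copula-style blend.
draw_severities <- function(n, dist, latent = NULL, mixing = 0) {
  k <- nrow(dist)
  out <- matrix(0L, n, k)
  if (n == 0) return(out)
  for (j in seq_len(k)) {
    u <- stats::runif(n)
    if (!is.null(latent) && mixing > 0) u <- (1 - mixing) * u + mixing * latent
    out[, j] <- findInterval(u, cumsum(dist[j, ]), left.open = TRUE)
  }
  storage.mode(out) <- "integer"
  out
}

#' Generate a labelled synthetic diagnostic cohort
#'
#' Emulates a case/control accuracy study: each subject contributes a
#' baseline Part A questionnaire, a urinalysis with culture, and the
#' physician reference diagnosis used as the accuracy gold standard.
#'
#' @param params a [cohort_params].
#' @param seed integer seed; identical params and seed reproduce the cohort
#'   exactly.
#' @return list of class `diagnostic_cohort` with `subjects` (questionnaire
#'   columns `t1..t6, d1..d4, q1..q3, a1..a5`, plus `wbc_mm3` and logical
#'   `reference`) and `cultures` (culture CSV layout).
#' @examples
#' cohort <- generate_diagnostic_cohort(cohort_preset("study2019"), seed = 1)
#' nrow(cohort$subjects)
#' @export
generate_diagnostic_cohort <- function(params = cohort_params(), seed = 1L) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(seed)
  n <- params$n_cases + params$n_controls
  is_case <- rep(c(TRUE, FALSE), c(params$n_cases, params$n_controls))
  ids <- sprintf("S%04d", seq_len(n))

  lat <- stats::runif(n)
  draw_group <- function(sel, typ_dist, qol_dist) {
    m <- sum(sel)
    list(
      typ = draw_severities(m, typ_dist, lat[sel], params$latent_mixing),
      dif = draw_severities(m, params$differential),
      qol = draw_severities(m, qol_dist, lat[sel], params$latent_mixing)
    )
  }
  g_case <- draw_group(is_case, params$case_typical, params$case_qol)
  g_ctrl <- draw_group(!is_case, params$control_typical, params$control_qol)
  typ <- matrix(0L, n, 6); dif <- matrix(0L, n, 4); qol <- matrix(0L, n, 3)
  typ[is_case, ] <- g_case$typ; typ[!is_case, ] <- g_ctrl$typ
  dif[is_case, ] <- g_case$dif; dif[!is_case, ] <- g_ctrl$dif
  qol[is_case, ] <- g_case$qol; qol[!is_case, ] <- g_ctrl$qol

  wbc <- numeric(n)
  wbc[is_case] <- stats::rlnorm(sum(is_case), params$case_wbc[["meanlog"]],
                                params$case_wbc[["sdlog"]])
  wbc[!is_case] <- stats::rlnorm(sum(!is_case), params$control_wbc[["meanlog"]],
                                 params$control_wbc[["sdlog"]])
  wbc <- round(wbc, 1)

  pos_prob <- ifelse(is_case, params$case_culture_pos, params$control_culture_pos)
  grown <- stats::runif(n) < pos_prob
  species <- rep("", n)
  cfu <- rep(0, n)
  if (any(grown)) {
    species[grown] <- sample(names(params$species_freq), sum(grown),
                             replace = TRUE, prob = params$species_freq)
    cfu[grown] <- signif(10^stats::runif(sum(grown), params$cfu_log10_range[1],
                                         params$cfu_log10_range[2]), 3)
  }

  subjects <- data.frame(
    patient_id = ids, part = "A", visit_day = 0L, stringsAsFactors = FALSE
  )
  subjects[paste0("t", 1:6)] <- as.data.frame(typ)
  subjects[paste0("d", 1:4)] <- as.data.frame(dif)
  subjects[paste0("q", 1:3)] <- as.data.frame(qol)
  subjects[paste0("a", 1:5)] <- 0L
  subjects$dyn <- NA_integer_
  subjects$wbc_mm3 <- wbc
  subjects$reference <- is_case

  cultures <- data.frame(patient_id = ids, visit_day = 0L, wbc_mm3 = wbc,
                         species = species, cfu_per_ml = cfu,
                         stringsAsFactors = FALSE)
  structure(list(subjects = subjects, cultures = cultures, params = params,
                 seed = seed),
            class = "diagnostic_cohort")
}

default_resolved_typical <- function() {
  severity_dist_matrix(c(rep(list(c(0.65, 0.35, 0, 0)), 5),
                         list(c(1, 0, 0, 0))), ACSS_TYPICAL_ITEMS)
}

default_unresolved_typical <- function() {
  severity_dist_matrix(c(rep(list(c(0.10, 0.30, 0.40, 0.20)), 3),
                         rep(list(c(0.25, 0.35, 0.30, 0.10)), 2),
                         list(c(0.85, 0.10, 0.04, 0.01))), ACSS_TYPICAL_ITEMS)
}

default_resolved_qol <- function() {
  severity_dist_matrix(rep(list(c(0.80, 0.20, 0, 0)), 3), paste0("q", 1:3))
}

default_unresolved_qol <- function() {
  severity_dist_matrix(rep(list(c(0.15, 0.35, 0.35, 0.15)), 3), paste0("q", 1:3))
}

#' Parameters of the synthetic two-arm outcome trial
#'
#' The `"outcome2023"` preset mirrors the size of the outcome development
#' cohort: 134 patients with diagnosed uncomplicated acute cystitis
#' (67 per arm). Each patient carries an eligible baseline Part A record; at
#' each follow-up window a latent resolved/unresolved state is drawn from
#' the per-arm `visit_success_prob`, and the observed Part B severities are
#' drawn from the state's distribution. Rescue antibiotic therapy (drawn per
#' arm) forces the unresolved state from the rescue day onward. Asymptomatic
#' bacteriuria (ABU) at test of cure is drawn among clinical resolvers; when
#' `relapse_prob` is a matrix, relapse at late follow-up is drawn per ABU
#' status and arm for patients resolved at test of cure, otherwise
#' (`relapse_prob = NULL`) the late-window state is drawn directly from
#' `visit_success_prob` like every other window (the configuration used for
#' parameter-recovery checks).
#'
#' @param n_per_arm patients per arm.
#' @param arms two arm labels; the first is the investigational arm.
#' @param visit_success_prob 2 x 4 matrix (rows arms, columns windows
#'   `early, end_of_treatment, toc, late_fu`) of latent resolution
#'   probabilities.
#' @param rescue_prob per-arm probability of switching to rescue antibiotic
#'   therapy (always adjudicated failure).
#' @param abu_prob_given_success probability of significant bacteriuria at
#'   test of cure given clinical resolution.
#' @param relapse_prob 2 x 2 matrix (rows `abu`, `no_abu`; columns arms) of
#'   relapse probability at late follow-up for patients resolved at test of
#'   cure, or `NULL` to disable the relapse mechanism.
#' @param resolved_typical,unresolved_typical 6 x 4 severity distributions
#'   by latent state. The resolved default is cure-compatible under every
#'   score threshold (all items at most mild, no visible blood).
#' @param resolved_qol,unresolved_qol 3 x 4 QoL distributions by state.
#' @param dynamics_resolved,dynamics_unresolved length-5 distributions of
#'   the Dynamics item (0 = fully recovered ... 4 = worse) by state.
#' @param baseline_typical baseline severity distribution used for
#'   screening draws (defaults to the diagnostic-case distribution).
#' @param baseline_wbc `c(meanlog, sdlog)` of baseline WBC/mm3.
#' @param eligibility_rule [diagnostic_rule] applied at screening.
#' @param culture_pos_prob probability of bacterial growth at baseline.
#' @param species_freq,cfu_log10_range as in [cohort_params()].
#' @param persist_prob probability that the baseline species is re-isolated
#'   at a visit in the unresolved state.
#' @param abu_persist_prob probability that ABU found at test of cure is
#'   still present at late follow-up.
#' @param dose_prob probability a randomised patient takes at least one
#'   dose (clinical-ITT membership).
#' @param treatment_end_day last treatment day.
#' @param visit_days named days of the four follow-up visits.
#' @param rescue_day day from which rescue therapy (when drawn) applies.
#' @param block_size permuted-block size for 1:1 randomisation.
#' @return object of class `trial_params`.
#' @export
trial_params <- function(n_per_arm = 67L,
                         arms = c("test", "reference"),
                         visit_success_prob = NULL,
                         rescue_prob = c(0.08, 0.04),
                         abu_prob_given_success = 0.25,
                         relapse_prob = NULL,
                         resolved_typical = default_resolved_typical(),
                         unresolved_typical = default_unresolved_typical(),
                         resolved_qol = default_resolved_qol(),
                         unresolved_qol = default_unresolved_qol(),
                         dynamics_resolved = c(0.75, 0.20, 0.05, 0, 0),
                         dynamics_unresolved = c(0.02, 0.13, 0.35, 0.35, 0.15),
                         baseline_typical = default_case_typical(),
                         baseline_wbc = c(meanlog = 3.55, sdlog = 1.2),
                         eligibility_rule = diagnostic_rule(),
                         culture_pos_prob = 0.85,
                         species_freq = DEFAULT_SPECIES_FREQ,
                         cfu_log10_range = c(1, 8),
                         persist_prob = 0.7,
                         abu_persist_prob = 0.6,
                         dose_prob = 0.98,
                         treatment_end_day = 5L,
                         visit_days = c(early = 3L, end_of_treatment = 7L,
                                        toc = 11L, late_fu = 28L),
                         rescue_day = 5L,
                         block_size = 4L) {
  if (length(arms) != 2) stop("exactly two arms are required")
  if (is.null(visit_success_prob)) {
    visit_success_prob <- rbind(c(0.50, 0.72, 0.78, 0.75),
                                c(0.55, 0.78, 0.84, 0.80))
  }
  dimnames(visit_success_prob) <- list(arms, VISIT_WINDOWS)
  if (any(visit_success_prob < 0 | visit_success_prob > 1)) {
    stop("visit_success_prob entries must lie in [0, 1]")
  }
  rescue_prob <- stats::setNames(rescue_prob, arms)
  if (any(rescue_prob < 0 | rescue_prob > 1)) stop("rescue_prob must lie in [0, 1]")
  if (!is.null(relapse_prob)) {
    relapse_prob <- matrix(relapse_prob, 2, 2,
                           dimnames = list(c("abu", "no_abu"), arms))
    if (any(relapse_prob < 0 | relapse_prob > 1)) stop("relapse_prob must lie in [0, 1]")
  }
  for (p in c(abu_prob_given_success, culture_pos_prob, persist_prob,
              abu_persist_prob, dose_prob)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  for (d in list(dynamics_resolved, dynamics_unresolved)) {
    if (length(d) != 5 || abs(sum(d) - 1) > 1e-9) stop("dynamics distributions must be length 5 and sum to 1")
  }
  structure(list(
    n_per_arm = as.integer(n_per_arm), arms = arms,
    visit_success_prob = visit_success_prob, rescue_prob = rescue_prob,
    abu_prob_given_success = abu_prob_given_success, relapse_prob = relapse_prob,
    resolved_typical = resolved_typical, unresolved_typical = unresolved_typical,
    resolved_qol = resolved_qol, unresolved_qol = unresolved_qol,
    dynamics_resolved = dynamics_resolved, dynamics_unresolved = dynamics_unresolved,
    baseline_typical = baseline_typical, baseline_wbc = baseline_wbc,
    eligibility_rule = eligibility_rule,
    culture_pos_prob = culture_pos_prob, species_freq = species_freq,
    cfu_log10_range = cfu_log10_range, persist_prob = persist_prob,
    abu_persist_prob = abu_persist_prob, dose_prob = dose_prob,
    treatment_end_day = as.integer(treatment_end_day),
    visit_days = visit_days, rescue_day = as.integer(rescue_day),
    block_size = as.integer(block_size)
  ), class = "trial_params")
}

#' @rdname trial_params
#' @param preset preset name; `"outcome2023"` is the 134-patient outcome
#'   cohort (67 per arm).
#' @export
trial_preset <- function(preset = "outcome2023") {
  preset <- match.arg(preset, "outcome2023")
  trial_params(n_per_arm = 67L,
               relapse_prob = matrix(c(0.05, 0.15, 0.05, 0.15), 2, 2))
}

#' Seeded 1:1 permuted-block randomisation
#'
#' @param n number of patients (allocation order).
#' @param arms two arm labels.
#' @param block_size even block size.
#' @return character vector of arm assignments; arm sizes differ by at most
#'   `block_size / 2`.
#' @export
randomize_blocks <- function(n, arms = c("test", "reference"), block_size = 4L) {
  if (block_size %% 2 != 0) stop("block size must be even for 1:1 allocation")
  n_blocks <- ceiling(n / block_size)
  assign <- unlist(lapply(seq_len(n_blocks), function(b) {
    sample(rep(arms, block_size / 2))
  }))
  assign[seq_len(n)]
}

#' Generate a synthetic two-arm outcome trial
#'
#' Simulates screening (drawing presenting patients until the target number
#' is eligible under the screening rule), permuted-block randomisation,
#' dosing, per-window latent resolution, rescue therapy, baseline and
#' follow-up cultures, ABU at test of cure, and relapse at late follow-up.
#'
#' @param params a [trial_params].
#' @param seed integer seed.
#' @return list of class `trial_data`: `subjects` (one row per randomised
#'   patient: arm, dosing, baseline culture, rescue, ABU and latent states),
#'   `responses` (questionnaire layout; baseline Part A plus four Part B
#'   visits), `cultures` (culture layout: baseline, test of cure, late
#'   follow-up), `funnel` (screening counts), and the `params`/`seed` used.
#' @examples
#' trial <- generate_trial(trial_preset("outcome2023"), seed = 42)
#' nrow(trial$subjects)
#' @export
generate_trial <- function(params = trial_params(), seed = 1L) {
  stopifnot(inherits(params, "trial_params"))
  set.seed(seed)
  n <- 2L * params$n_per_arm

  # --- screening: draw presenting patients until n are eligible -----------
  rule <- params$eligibility_rule
  sym_rule <- rule; sym_rule$require_pyuria <- FALSE
  typ_all <- matrix(0L, 0, 6); wbc_all <- numeric(0)
  elig <- logical(0)
  while (sum(elig) < n) {
    b <- max(64L, n)
    typ_b <- draw_severities(b, params$baseline_typical)
    wbc_b <- round(stats::rlnorm(b, params$baseline_wbc[["meanlog"]],
                                 params$baseline_wbc[["sdlog"]]), 1)
    typ_all <- rbind(typ_all, typ_b)
    wbc_all <- c(wbc_all, wbc_b)
    elig <- apply_rule_matrix(typ_all, wbc_all, rule)
  }
  nth <- which(elig)[n]
  screened <- nth # patients drawn up to and including the n-th eligible
  typ_all <- typ_all[seq_len(screened), , drop = FALSE]
  wbc_all <- wbc_all[seq_len(screened)]
  sym_elig <- apply_rule_matrix(typ_all, wbc_all, sym_rule)
  keep <- which(elig[seq_len(screened)])
  typ0 <- typ_all[keep, , drop = FALSE]
  wbc0 <- wbc_all[keep]
  funnel <- c(screened = screened,
              symptom_eligible = sum(sym_elig),
              eligible = n, randomized = n)

  ids <- sprintf("P%04d", seq_len(n))
  arm <- randomize_blocks(n, params$arms, params$block_size)
  dosed <- stats::runif(n) < params$dose_prob
  funnel <- c(funnel, dosed = sum(dosed))

  # --- baseline culture ---------------------------------------------------
  grown <- stats::runif(n) < params$culture_pos_prob
  base_species <- rep("", n); base_cfu <- rep(0, n)
  base_species[grown] <- sample(names(params$species_freq), sum(grown),
                                replace = TRUE, prob = params$species_freq)
  base_cfu[grown] <- signif(10^stats::runif(sum(grown), params$cfu_log10_range[1],
                                            params$cfu_log10_range[2]), 3)

  # --- latent resolution states per window --------------------------------
  p_succ <- params$visit_success_prob[arm, , drop = FALSE]
  resolved <- matrix(stats::runif(n * 4) < p_succ, n, 4,
                     dimnames = list(NULL, VISIT_WINDOWS))
  rescue <- stats::runif(n) < params$rescue_prob[arm]
  rescue_windows <- params$visit_days >= params$rescue_day
  resolved[rescue, rescue_windows] <- FALSE

  abu <- rep(FALSE, n)
  abu[resolved[, "toc"]] <- stats::runif(sum(resolved[, "toc"])) <
    params$abu_prob_given_success
  if (!is.null(params$relapse_prob)) {
    at_risk <- which(resolved[, "toc"] & !rescue)
    pr <- params$relapse_prob[cbind(ifelse(abu[at_risk], "abu", "no_abu"), arm[at_risk])]
    relapse <- stats::runif(length(at_risk)) < pr
    resolved[at_risk, "late_fu"] <- !relapse
  }

  # --- Part B responses ---------------------------------------------------
  resp_rows <- vector("list", 5L)
  baseline <- data.frame(patient_id = ids, part = "A", visit_day = 0L,
                         stringsAsFactors = FALSE)
  baseline[paste0("t", 1:6)] <- as.data.frame(typ0)
  baseline[paste0("d", 1:4)] <- as.data.frame(draw_severities(n, default_differential()))
  baseline[paste0("q", 1:3)] <- as.data.frame(draw_severities(n, default_unresolved_qol()))
  baseline[paste0("a", 1:5)] <- 0L
  baseline$dyn <- NA_integer_
  resp_rows[[1]] <- baseline

  for (w in seq_along(VISIT_WINDOWS)) {
    state <- resolved[, w]
    typ_res <- draw_severities(n, params$resolved_typical)
    typ_un <- draw_severities(n, params$unresolved_typical)
    qol_res <- draw_severities(n, params$resolved_qol)
    qol_un <- draw_severities(n, params$unresolved_qol)
    dyn_res <- sample(0:4, n, replace = TRUE, prob = params$dynamics_resolved)
    dyn_un <- sample(0:4, n, replace = TRUE, prob = params$dynamics_unresolved)
    typ <- typ_un; typ[state, ] <- typ_res[state, ]
    qol <- qol_un; qol[state, ] <- qol_res[state, ]
    dyn <- ifelse(state, dyn_res, dyn_un)
    df <- data.frame(patient_id = ids, part = "B",
                     visit_day = unname(params$visit_days[w]),
                     stringsAsFactors = FALSE)
    df[paste0("t", 1:6)] <- as.data.frame(typ)
    df[paste0("d", 1:4)] <- as.data.frame(draw_severities(n, default_differential()))
    df[paste0("q", 1:3)] <- as.data.frame(qol)
    df[paste0("a", 1:5)] <- 0L
    df$dyn <- as.integer(dyn)
    resp_rows[[w + 1L]] <- df
  }
  responses <- do.call(rbind, resp_rows)

  # --- follow-up cultures (test of cure and late follow-up) ---------------
  fu_culture <- function(window) {
    species <- rep("", n); cfu <- rep(0, n)
    state <- resolved[, window]
    # unresolved: baseline species (when any) persists with persist_prob
    unres <- which(!state & nzchar(base_species))
    persists <- unres[stats::runif(length(unres)) < params$persist_prob]
    species[persists] <- base_species[persists]
    cfu[persists] <- signif(10^stats::runif(length(persists), 3, 8), 3)
    # resolved with ABU: significant bacteriuria despite clinical success
    if (window == "toc") {
      carriers <- which(abu)
    } else {
      carriers <- which(abu & state)
      carriers <- carriers[stats::runif(length(carriers)) < params$abu_persist_prob]
    }
    sp <- ifelse(nzchar(base_species[carriers]), base_species[carriers],
                 names(params$species_freq)[1])
    species[carriers] <- sp
    cfu[carriers] <- signif(10^stats::runif(length(carriers), 5, 8), 3)
    wbc_fu <- round(ifelse(state, stats::rlnorm(n, 1.5, 0.8), stats::rlnorm(n, 3.2, 1.0)), 1)
    data.frame(patient_id = ids, visit_day = unname(params$visit_days[window]),
               wbc_mm3 = wbc_fu, species = species, cfu_per_ml = cfu,
               stringsAsFactors = FALSE)
  }
  cultures <- rbind(
    data.frame(patient_id = ids, visit_day = 0L, wbc_mm3 = wbc0,
               species = base_species, cfu_per_ml = base_cfu,
               stringsAsFactors = FALSE),
    fu_culture("toc"),
    fu_culture("late_fu")
  )

  subjects <- data.frame(
    patient_id = ids, arm = arm, randomized = TRUE, dosed = dosed,
    symptom_eligible = TRUE,
    baseline_species = base_species, baseline_cfu = base_cfu,
    baseline_wbc = wbc0,
    rescue = rescue,
    rescue_day = ifelse(rescue, params$rescue_day, NA_integer_),
    abu_toc = abu, stringsAsFactors = FALSE
  )
  subjects[paste0("latent_", VISIT_WINDOWS)] <- as.data.frame(resolved)

  structure(list(subjects = subjects, responses = responses,
                 cultures = cultures, funnel = funnel,
                 params = params, seed = seed),
            class = "trial_data")
}

#' Monte-Carlo recovery of the generator's success probabilities
#'
#' Repeatedly generates trials, adjudicates every follow-up window under a
#' score threshold, and compares the mean adjudicated success proportion per
#' arm and window against the generating `visit_success_prob`. With the
#' resolved severity distribution cure-compatible and the unresolved one
#' failure-compatible, the adjudicated proportion is an unbiased binomial
#' estimate of the latent probability.
#'
#' @param params a [trial_params].
#' @param replicates number of simulated trials.
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param threshold score threshold used for adjudication.
#' @return data frame: `arm`, `window`, `true_prob`, `mean_success`,
#'   `mc_se` (Monte-Carlo standard error of the mean), `replicates`.
#' @export
recovery_harness <- function(params = trial_params(), replicates = 100L,
                             seed = 1L, threshold = "ACSS5") {
  if (replicates < 1) stop("replicates must be >= 1")
  thr <- outcome_threshold(threshold)
  acc <- array(NA_real_, dim = c(replicates, 2L, 4L),
               dimnames = list(NULL, params$arms, VISIT_WINDOWS))
  for (r in seq_len(replicates)) {
    trial <- generate_trial(params, seed = seed + r)
    adj <- adjudicate_trial(trial, thresholds = threshold)
    for (a in params$arms) for (w in VISIT_WINDOWS) {
      sel <- adj$window == w &
        adj$arm == a & adj$threshold == threshold
      acc[r, a, w] <- mean(adj$status[sel] == "success")
    }
  }
  out <- expand.grid(arm = params$arms, window = VISIT_WINDOWS,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$true_prob <- params$visit_success_prob[cbind(out$arm, out$window)]
  out$mean_success <- mapply(function(a, w) mean(acc[, a, w]), out$arm, out$window)
  out$mc_se <- mapply(function(a, w) stats::sd(acc[, a, w]) / sqrt(replicates),
                      out$arm, out$window)
  out$replicates <- replicates
  out
}
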