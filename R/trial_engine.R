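# End-to-end trial orchestration: screen -> enrol -> randomise -> visits ->
# adjudicate -> analyse, with an eligibility funnel, per-threshold success
# tables, the primary non-inferiority analysis at test of cure, the ABU
# relapse sub-analysis and the microbiological/clinical cross-table.

#' Adjudicate every scheduled visit of a trial
#'
#' Maps each Part B response to its visit window, applies the rescue rule
#' (rescue therapy on or before the visit forces failure), and adjudicates
#' under each requested threshold. Unscheduled visits are dropped.
#'
#' @param trial a `trial_data` object (see [generate_trial()]) or a list
#'   with `subjects`, `responses` and `params`-compatible fields.
#' @param thresholds character vector of [outcome_threshold()] names.
#' @param treatment_end_day last treatment day used for window
#'   classification; defaults to the generator's.
#' @return data frame: `patient_id`, `arm`, `visit_day`, `window`,
#'   `threshold`, `status`, `hematuria_flag`.
#' @export
adjudicate_trial <- function(trial, thresholds = c("ACSS5", "FDA4", "EMA3"),
                             treatment_end_day = NULL) {
  treatment_end_day <- treatment_end_day %||% trial$params$treatment_end_day %||% 5L
  partb <- trial$responses[trial$responses$part == "B", , drop = FALSE]
  if (nrow(partb) == 0) stop("trial has no follow-up (Part B) responses")
  window <- classify_visit(partb$visit_day, treatment_end_day)
  keep <- window != "unscheduled"
  partb <- partb[keep, , drop = FALSE]
  window <- window[keep]

  sub <- trial$subjects
  idx <- match(partb$patient_id, sub$patient_id)
  if (anyNA(idx)) stop("follow-up responses for unknown patients")
  rescue_day <- sub$rescue_day[idx]
  rescue <- !is.na(rescue_day) & partb$visit_day >= rescue_day

  typ <- cohort_typical_matrix(partb)
  qol <- as.matrix(partb[paste0("q", 1:3)])
  dyn <- partb$dyn
  out <- lapply(thresholds, function(th) {
    success <- adjudicate_matrix(typ, th, rescue, qol = qol, dynamics = dyn)
    data.frame(patient_id = partb$patient_id, arm = sub$arm[idx],
               visit_day = partb$visit_day, window = window, threshold = th,
               status = ifelse(success, "success", "failure"),
               hematuria_flag = typ[, 6L] >= 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Configure an end-to-end simulated trial
#'
#' @param eligibility_rule screening [diagnostic_rule] (also used by the
#'   generator when simulating).
#' @param policy bacteriuria [significance_policy] for the microbiological
#'   populations and outcomes.
#' @param primary_threshold single primary cure threshold, pre-specified in
#'   the protocol; the other configured thresholds are descriptive only, so
#'   no multiplicity adjustment is applied.
#' @param descriptive_thresholds further thresholds reported alongside.
#' @param population analysis population of the primary comparison.
#' @param margin non-inferiority margin (negative risk difference).
#' @param ci_method interval method for [risk_difference_ci()].
#' @param level confidence level.
#' @param generator [trial_params()] for simulation, or `NULL` when reading
#'   `input_files`.
#' @param input_files optional named list with paths `subjects`,
#'   `responses`, `cultures` (CSV layouts as written by
#'   [write_trial_files()]).
#' @param seed integer seed for generation and randomisation.
#' @param verbose log stage-by-stage counts via `message()`.
#' @return object of class `trial_config`.
#' @export
trial_config <- function(eligibility_rule = diagnostic_rule(),
                         policy = significance_policy("s3_species_aware"),
                         primary_threshold = "ACSS5",
                         descriptive_thresholds = c("FDA4", "EMA3"),
                         population = "clinical_itt",
                         margin = -0.10,
                         ci_method = "newcombe",
                         level = 0.95,
                         generator = trial_preset("outcome2023"),
                         input_files = NULL,
                         seed = 1L,
                         verbose = FALSE) {
  if (length(primary_threshold) != 1L) stop("exactly one primary threshold is required")
  if (margin >= 0) stop("non-inferiority margin must be negative")
  if (is.null(generator) && is.null(input_files)) {
    stop("either generator parameters or input files are required")
  }
  if (population == "micro_itt" && !is.null(input_files) && is.null(input_files$cultures)) {
    stop("micro_itt population requires culture data")
  }
  structure(list(
    eligibility_rule = eligibility_rule, policy = policy,
    primary_threshold = primary_threshold,
    descriptive_thresholds = setdiff(descriptive_thresholds, primary_threshold),
    population = population, margin = margin, ci_method = ci_method,
    level = level, generator = generator, input_files = input_files,
    seed = as.integer(seed), verbose = isTRUE(verbose)
  ), class = "trial_config")
}

#' Write / read the trial file set
#'
#' @param trial a `trial_data` object.
#' @param dir output directory (created if absent).
#' @return named list of file paths.
#' @export
write_trial_files <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(subjects = file.path(dir, "subjects.csv"),
                responses = file.path(dir, "responses.csv"),
                cultures = file.path(dir, "cultures.csv"))
  utils::write.csv(trial$subjects, paths$subjects, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8", na = "")
  write_acss_csv(trial$responses, paths$responses)
  write_culture_csv(trial$cultures, paths$cultures)
  paths
}

#' @rdname write_trial_files
#' @param paths named list with `subjects`, `responses` and (optionally)
#'   `cultures` paths.
#' @export
read_trial_files <- function(paths) {
  subjects <- utils::read.csv(paths$subjects, stringsAsFactors = FALSE)
  subjects$baseline_species[is.na(subjects$baseline_species)] <- ""
  trial <- list(subjects = subjects,
                responses = read_acss_csv(paths$responses),
                cultures = if (!is.null(paths$cultures)) read_culture_csv(paths$cultures),
                funnel = NULL, params = NULL)
  class(trial) <- "trial_data"
  trial
}

culture_result_lookup <- function(cultures) {
  if (is.null(cultures)) return(list())
  cultures_to_results(cultures)
}

lookup_culture <- function(lookup, pid, day) {
  lookup[[paste(pid, day, sep = ".")]]
}

#' Run a configured trial end to end
#'
#' Generates (or loads) the trial, verifies the eligibility funnel,
#' adjudicates every scheduled visit under every configured threshold,
#' performs the primary non-inferiority comparison at test of cure on the
#' configured analysis population, tabulates relapse at late follow-up by
#' asymptomatic-bacteriuria status, and cross-tabulates microbiological
#' against clinical outcome in the microbiological ITT population.
#'
#' @param config a [trial_config].
#' @return object of class `trial_report`: `funnel`, `success_tables`,
#'   `ni`, `abu_table`, `crosstab` (at test of cure and late follow-up),
#'   `adjudications`, `trial`.
#' @examples
#' \donttest{
#' cfg <- trial_config(generator = trial_preset("outcome2023"), seed = 7)
#' report <- run_trial(cfg)
#' report$ni
#' }
#' @export
run_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  log_msg <- function(...) if (config$verbose) message(sprintf(...))

  if (!is.null(config$input_files)) {
    trial <- read_trial_files(config$input_files)
    trial$params <- config$generator
  } else {
    gen <- config$generator
    gen$eligibility_rule <- config$eligibility_rule
    trial <- generate_trial(gen, seed = config$seed)
  }
  if (config$population == "micro_itt" && is.null(trial$cultures)) {
    stop("micro_itt population requires culture data")
  }
  n_rand <- nrow(trial$subjects)
  log_msg("randomised %d patients", n_rand)

  # baseline significance under the configured policy
  trial$subjects <- population_annotate(trial$subjects, config$policy)

  thresholds <- c(config$primary_threshold, config$descriptive_thresholds)
  adj <- adjudicate_trial(trial, thresholds = thresholds)
  log_msg("adjudicated %d visit records under %d thresholds", nrow(adj), length(thresholds))

  clin <- population_filter(trial$subjects, "clinical_itt")
  adj_clin <- adj[adj$patient_id %in% clin$patient_id, , drop = FALSE]
  tables <- success_table(adj_clin[c("patient_id", "window", "threshold", "status")])

  # primary analysis: success at test of cure in the configured population
  pop <- population_filter(trial$subjects, config$population)
  analyzed <- nrow(pop)
  prim <- adj[adj$threshold == config$primary_threshold & adj$window == "toc" &
                adj$patient_id %in% pop$patient_id, , drop = FALSE]
  arms <- unique(trial$subjects$arm)
  if (!is.null(trial$params)) arms <- trial$params$arms
  summ <- lapply(arms, function(a) {
    s <- prim[prim$arm == a, , drop = FALSE]
    arm_summary(a, nrow(s), sum(s$status == "success"))
  })
  ni <- noninferiority_conclusion(
    risk_difference_ci(summ[[1]], summ[[2]], level = config$level,
                       method = config$ci_method),
    margin = config$margin)
  log_msg("primary NI analysis (%s, %s): rd %.3f, conclusion %s",
          config$primary_threshold, config$population,
          ni$risk_difference, ni$conclusion)

  funnel <- c(trial$funnel %||% c(screened = NA, symptom_eligible = NA,
                                  eligible = n_rand, randomized = n_rand,
                                  dosed = sum(trial$subjects$dosed)),
              analyzed = analyzed)

  lookup <- culture_result_lookup(trial$cultures)
  abu_tab <- abu_relapse_table(trial, adj, config, lookup)
  xtab <- if (length(lookup)) {
    list(toc = crosstab_micro_clinical(trial, config$policy,
                                       config$primary_threshold, "toc",
                                       adjudications = adj, lookup = lookup),
         late_fu = crosstab_micro_clinical(trial, config$policy,
                                           config$primary_threshold, "late_fu",
                                           adjudications = adj, lookup = lookup))
  }

  structure(list(funnel = funnel, success_tables = tables, ni = ni,
                 abu_table = abu_tab, crosstab = xtab,
                 adjudications = adj, config = config, trial = trial),
            class = "trial_report")
}

population_annotate <- function(subjects, policy) {
  grown <- nzchar(subjects$baseline_species) & subjects$baseline_cfu > 0
  sig <- rep(FALSE, nrow(subjects))
  if (any(grown)) {
    sig[grown] <- isolate_significant(subjects$baseline_species[grown],
                                      subjects$baseline_cfu[grown], policy)
  }
  subjects$baseline_significant <- sig
  subjects
}

# Relapse at late follow-up among test-of-cure successes, stratified by
# asymptomatic bacteriuria at test of cure and by arm, with Wilson CIs.
abu_relapse_table <- function(trial, adj, config, lookup) {
  prim <- config$primary_threshold
  toc <- adj[adj$threshold == prim & adj$window == "toc", , drop = FALSE]
  late <- adj[adj$threshold == prim & adj$window == "late_fu", , drop = FALSE]
  succ <- toc[toc$status == "success", , drop = FALSE]
  if (nrow(succ) == 0 || nrow(late) == 0) return(NULL)
  toc_day <- trial$params$visit_days[["toc"]] %||% unique(toc$visit_day)[1]
  abu <- vapply(seq_len(nrow(succ)), function(i) {
    cult <- lookup_culture(lookup, succ$patient_id[i], toc_day)
    if (is.null(cult)) return(NA)
    abu_flag(TRUE, cult, config$policy)
  }, logical(1))
  relapse <- late$status[match(succ$patient_id, late$patient_id)] == "failure"
  keep <- !is.na(abu) & !is.na(relapse)
  d <- data.frame(arm = succ$arm, abu = abu, relapse = relapse)[keep, , drop = FALSE]
  if (nrow(d) == 0) return(NULL)
  agg <- stats::aggregate(relapse ~ arm + abu, data = d,
                          FUN = function(x) c(n = length(x), rel = sum(x)))
  out <- data.frame(arm = agg$arm, abu = agg$abu,
                    n = as.integer(agg$relapse[, "n"]),
                    relapses = as.integer(agg$relapse[, "rel"]))
  out$proportion <- out$relapses / out$n
  ci <- t(mapply(wilson_ci, out$relapses, out$n))
  out$ci_lower <- ci[, 1]; out$ci_upper <- ci[, 2]
  out
}

#' Cross-tabulate microbiological against clinical outcome
#'
#' For the microbiological ITT population (significant baseline bacteriuria
#' under the policy), classifies each follow-up culture as eradication,
#' persistence, new infection or indeterminate and crosses it with the
#' adjudicated clinical outcome at the same window.
#'
#' @param trial a `trial_data` with cultures.
#' @param policy a [significance_policy].
#' @param threshold cure threshold name for the clinical outcome.
#' @param window `"toc"` or `"late_fu"`.
#' @param adjudications optional precomputed [adjudicate_trial()] table.
#' @param lookup internal culture lookup (recomputed when absent).
#' @return a `table` of clinical status by microbiological outcome; margins
#'   sum to the number of micro-ITT patients adjudicated at the window.
#' @export
crosstab_micro_clinical <- function(trial, policy, threshold = "ACSS5",
                                    window = "toc", adjudications = NULL,
                                    lookup = NULL) {
  if (is.null(trial$cultures)) stop("microbiological cross-table requires culture data")
  if (is.null(lookup)) lookup <- culture_result_lookup(trial$cultures)
  if (is.null(adjudications)) adjudications <- adjudicate_trial(trial, threshold)
  subjects <- population_annotate(trial$subjects, policy)
  micro <- population_filter(subjects, "micro_itt")
  if (nrow(micro) == 0) {
    warning("microbiological ITT population is empty")
    return(table(clinical = factor(character(), c("success", "failure")),
                 micro = factor(character(), c("eradication", "persistence",
                                               "new_infection", "indeterminate"))))
  }
  adj <- adjudications[adjudications$threshold == threshold &
                         adjudications$window == window &
                         adjudications$patient_id %in% micro$patient_id, , drop = FALSE]
  day <- unique(adj$visit_day)[1]
  mo <- vapply(seq_len(nrow(adj)), function(i) {
    pid <- adj$patient_id[i]
    base <- lookup_culture(lookup, pid, 0L)
    if (is.null(base)) {
      sub <- micro[micro$patient_id == pid, ]
      base <- urine_result(pid, 0L, wbc = sub$baseline_wbc %||% 0,
                           species = sub$baseline_species, cfu = sub$baseline_cfu)
    }
    micro_outcome(base, lookup_culture(lookup, pid, adj$visit_day[i]), policy)
  }, character(1))
  table(clinical = factor(adj$status, c("success", "failure")),
        micro = factor(mo, c("eradication", "persistence", "new_infection",
                             "indeterminate")))
}

#' @export
print.trial_report <- function(x, ...) {
  cat("Trial report\n")
  cat("  funnel:", paste(sprintf("%s=%s", names(x$funnel), x$funnel), collapse = ", "), "\n")
  cat("  primary:", x$config$primary_threshold, "at TOC,",
      x$config$population, "population\n")
  print(x$ni)
  invisible(x)
}

#' Serialise a trial report to plain lists
#'
#' Deterministic representation (data frames to lists, tables to matrices)
#' suitable for JSON export; identical config and seed yield identical
#' serialisations.
#'
#' @param report a `trial_report`.
#' @return nested list.
#' @export
report_to_list <- function(report) {
  list(
    funnel = as.list(report$funnel),
    success_tables = unname(split(report$success_tables,
                                  seq_len(nrow(report$success_tables)))),
    ni = list(risk_difference = report$ni$risk_difference,
              ci = as.list(report$ni$ci), method = report$ni$method,
              margin = report$ni$margin, conclusion = report$ni$conclusion),
    abu_table = if (!is.null(report$abu_table)) as.list(report$abu_table),
    crosstab = lapply(report$crosstab, function(t) as.data.frame(unclass(t)))
  )
}
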