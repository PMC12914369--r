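# Bacteriuria-significance policies and microbiological outcome
# classification. Colony counts are CFU per mL of mid-stream urine.

#' One urine specimen: urinalysis plus culture isolates
#'
#' @param patient_id identifier.
#' @param visit_day integer day relative to treatment start.
#' @param wbc leukocyte density, WBC per mm3 (>= 0).
#' @param species character vector of isolate taxon labels (possibly empty
#'   for a sterile culture).
#' @param cfu numeric vector of colony counts, CFU per mL, parallel to
#'   `species`; each > 0.
#' @return an object of class `urine_result`.
#' @examples
#' urine_result("p1", 0, wbc = 50, species = "Escherichia coli", cfu = 1e5)
#' @export
urine_result <- function(patient_id = NA_character_, visit_day = 0L, wbc = 0,
                         species = character(), cfu = numeric()) {
  if (length(species) != length(cfu)) stop("species and cfu must be parallel vectors")
  if (any(is.na(wbc)) || wbc < 0) stop("wbc must be a non-negative count per mm3")
  if (length(cfu) && any(is.na(cfu) | cfu <= 0)) stop("isolate cfu must be positive")
  if (length(species) && any(!nzchar(species))) stop("species labels must be non-empty")
  structure(list(patient_id = as.character(patient_id),
                 visit_day = as.integer(visit_day), wbc = as.numeric(wbc),
                 isolates = data.frame(species = as.character(species),
                                       cfu = as.numeric(cfu),
                                       stringsAsFactors = FALSE)),
            class = "urine_result")
}

#' @export
print.urine_result <- function(x, ...) {
  cat(sprintf("Urine specimen (patient %s, day %d): %g WBC/mm3\n",
              x$patient_id, x$visit_day, x$wbc))
  if (nrow(x$isolates) == 0) cat("  sterile culture\n")
  else for (i in seq_len(nrow(x$isolates)))
    cat(sprintf("  %s: %.3g CFU/mL\n", x$isolates$species[i], x$isolates$cfu[i]))
  invisible(x)
}

# Species-class recognition is by label matching; no strain typing.
species_class <- function(species) {
  s <- tolower(species)
  out <- rep("other", length(s))
  out[grepl("escherichia\\s+coli|^e\\.?\\s*coli", s)] <- "e_coli"
  out[grepl("saprophyticus", s)] <- "s_saprophyticus"
  out[grepl("enterococcus", s)] <- "enterococcus"
  out[grepl("agalactiae|group\\s*b\\s*strep", s)] <- "group_b_strep"
  out
}

#' Bacteriuria significance policies
#'
#' Four policies decide whether an isolate constitutes significant
#' bacteriuria:
#' \describe{
#'   \item{`general_1e5`}{the classical 1e5 CFU/mL cut-off for every
#'     species. Highly specific but insensitive for acute cystitis: applied
#'     as a microbiological inclusion criterion it can exclude roughly half
#'     of genuinely infected symptomatic women.}
#'   \item{`stamm_1e2`}{1e2 CFU/mL for every species, the low count
#'     proposed as the best diagnostic criterion for acute cystitis in
#'     symptomatic women.}
#'   \item{`hooton_low`}{1e1 CFU/mL for *Escherichia coli* and
#'     *Staphylococcus saprophyticus* (the lower end of the reported
#'     1e1-1e2 range, making this the most sensitive policy of the set),
#'     1e2 CFU/mL otherwise.}
#'   \item{`s3_species_aware`}{species-aware rule: *E. coli* is significant
#'     at any count in a symptomatic woman; enterococci and group B
#'     streptococci are never significant (not predictive of urinary tract
#'     infection); other recognised uropathogens use
#'     `uropathogen_threshold`.}
#' }
#'
#' @param name policy name.
#' @param uropathogen_threshold CFU/mL cut-off for non-*E. coli* pathogens
#'   under `s3_species_aware`; configuration, not a published constant.
#' @return an object of class `significance_policy`.
#' @export
significance_policy <- function(name = c("s3_species_aware", "general_1e5",
                                         "stamm_1e2", "hooton_low"),
                                uropathogen_threshold = 1e3) {
  name <- match.arg(name)
  structure(list(name = name, uropathogen_threshold = uropathogen_threshold),
            class = "significance_policy")
}

# Minimum significant CFU per isolate; Inf encodes "never significant".
policy_threshold <- function(species, policy) {
  cls <- species_class(species)
  switch(policy$name,
    general_1e5 = rep(1e5, length(cls)),
    stamm_1e2 = rep(1e2, length(cls)),
    hooton_low = ifelse(cls %in% c("e_coli", "s_saprophyticus"), 1e1, 1e2),
    s3_species_aware = ifelse(cls == "e_coli", 0,
                       ifelse(cls %in% c("enterococcus", "group_b_strep"), Inf,
                              policy$uropathogen_threshold)),
    stop("unknown significance policy: ", policy$name)
  )
}

isolate_significant <- function(species, cfu, policy) {
  thr <- policy_threshold(species, policy)
  # threshold 0 means "any growth"; boundaries are inclusive otherwise
  ifelse(thr == 0, cfu > 0, cfu >= thr)
}

#' Significant bacteriuria under a policy
#'
#' @param result a [urine_result].
#' @param policy a [significance_policy].
#' @return list with `significant` (`TRUE` iff at least one isolate is
#'   significant) and `isolates` (data frame of the significant isolates).
#' @examples
#' r <- urine_result(wbc = 40, species = "Escherichia coli", cfu = 1e2)
#' significant_bacteriuria(r, significance_policy("stamm_1e2"))$significant
#' @export
significant_bacteriuria <- function(result, policy = significance_policy()) {
  stopifnot(inherits(result, "urine_result"), inherits(policy, "significance_policy"))
  iso <- result$isolates
  if (nrow(iso) == 0) return(list(significant = FALSE, isolates = iso))
  sig <- isolate_significant(iso$species, iso$cfu, policy)
  list(significant = any(sig), isolates = iso[sig, , drop = FALSE])
}

#' Microbiological outcome between baseline and a follow-up culture
#'
#' Classifies the follow-up culture of a microbiological-ITT patient
#' (significant baseline bacteriuria required) as:
#' \describe{
#'   \item{eradication}{no baseline-significant species is still significant.}
#'   \item{persistence}{at least one baseline-significant species remains
#'     significant at follow-up.}
#'   \item{new_infection}{baseline species eradicated but a different
#'     species is significant.}
#'   \item{indeterminate}{follow-up culture missing.}
#' }
#' Species are matched at the label level; no strain typing is attempted.
#'
#' @param baseline,followup [urine_result] objects; `followup = NULL` for a
#'   missing culture.
#' @param policy a [significance_policy].
#' @return one of `"eradication"`, `"persistence"`, `"new_infection"`,
#'   `"indeterminate"`.
#' @export
micro_outcome <- function(baseline, followup, policy = significance_policy()) {
  base_sig <- significant_bacteriuria(baseline, policy)
  if (!base_sig$significant) {
    stop("baseline culture has no significant isolate: patient is not in the microbiological ITT population")
  }
  if (is.null(followup)) return("indeterminate")
  fu_sig <- significant_bacteriuria(followup, policy)
  if (!fu_sig$significant) return("eradication")
  base_species <- unique(base_sig$isolates$species)
  if (any(fu_sig$isolates$species %in% base_species)) return("persistence")
  "new_infection"
}

#' Flag asymptomatic bacteriuria at a follow-up visit
#'
#' Marks patients who are clinical successes yet carry significant
#' bacteriuria (ABU) at the visit, for the ABU relapse sub-analysis at late
#' follow-up: ABU may even protect against recurrence, so these patients are
#' followed rather than retreated.
#'
#' @param clinical_success logical adjudicated clinical success.
#' @param followup [urine_result] at the same visit.
#' @param policy a [significance_policy].
#' @return logical ABU flag.
#' @export
abu_flag <- function(clinical_success, followup, policy = significance_policy()) {
  isTRUE(clinical_success) && significant_bacteriuria(followup, policy)$significant
}
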