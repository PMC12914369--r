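# Non-inferiority comparison of success proportions between arms. The
# primary analysis is the clinical outcome at test of cure in the clinical
# ITT population, with a risk-difference margin of -10 percentage points.

#' Per-arm success summary
#'
#' @param arm arm label.
#' @param n number of analysed patients.
#' @param successes number of clinical successes, `0 <= successes <= n`.
#' @return object of class `arm_summary`.
#' @export
arm_summary <- function(arm, n, successes) {
  if (n < 0 || successes < 0 || successes > n) stop("need 0 <= successes <= n")
  structure(list(arm = as.character(arm), n = as.integer(n),
                 successes = as.integer(successes)),
            class = "arm_summary")
}

#' Filter trial records into an analysis population
#'
#' Nested intention-to-treat populations:
#' \describe{
#'   \item{`itt`}{every randomised patient.}
#'   \item{`clinical_itt`}{randomised patients who received at least one
#'     dose and met the symptomatic eligibility criteria at baseline; the
#'     primary analysis population.}
#'   \item{`micro_itt`}{the clinical ITT members with significant baseline
#'     bacteriuria under the chosen policy. Under the classical 1e5 CFU/mL
#'     rule this can discard about half of genuinely symptomatic patients,
#'     which is why the filter makes the exclusion explicit and countable.}
#' }
#'
#' @param records data frame with logical columns `randomized`, `dosed`,
#'   `symptom_eligible` and `baseline_significant` (precomputed under the
#'   chosen policy), or the latter replaced by baseline culture columns via
#'   [significant_bacteriuria()] upstream.
#' @param population `"itt"`, `"clinical_itt"` or `"micro_itt"`.
#' @param policy optional [significance_policy]; when supplied and the
#'   records carry `baseline_species` / `baseline_cfu` columns, the
#'   `baseline_significant` flag is (re)computed under it.
#' @return the subset of `records` in the population.
#' @export
population_filter <- function(records, population = c("clinical_itt", "itt", "micro_itt"),
                              policy = NULL) {
  population <- match.arg(population)
  if (!is.null(policy) && all(c("baseline_species", "baseline_cfu") %in% names(records))) {
    grown <- nzchar(records$baseline_species) & !is.na(records$baseline_cfu) &
      records$baseline_cfu > 0
    records$baseline_significant <- grown &
      isolate_significant(records$baseline_species, pmax(records$baseline_cfu, 1), policy)
  }
  need <- switch(population,
                 itt = "randomized",
                 clinical_itt = c("randomized", "dosed", "symptom_eligible"),
                 micro_itt = c("randomized", "dosed", "symptom_eligible", "baseline_significant"))
  missing <- setdiff(need, names(records))
  if (length(missing)) stop("records lack columns: ", paste(missing, collapse = ", "))
  keep <- switch(population,
    itt = records$randomized,
    clinical_itt = records$randomized & records$dosed & records$symptom_eligible,
    micro_itt = records$randomized & records$dosed & records$symptom_eligible &
      records$baseline_significant
  )
  records[keep, , drop = FALSE]
}

#' Risk difference between two arms with confidence interval
#'
#' Point estimate `p_test - p_ref` with one of three intervals:
#' \describe{
#'   \item{`newcombe`}{hybrid score interval combining the two per-arm
#'     Wilson intervals; robust at boundary proportions. The default.}
#'   \item{`wald`}{normal approximation; kept for textbook comparability.}
#'   \item{`score`}{Miettinen-Nurminen score interval (constrained-MLE
#'     variance with the N/(N-1) inflation).}
#' }
#'
#' @param test,ref [arm_summary] objects for the investigational and
#'   reference arm.
#' @param level confidence level.
#' @param method interval method.
#' @return object of class `ni_result` with `risk_difference`, `ci`,
#'   `method`, `level`, and the per-arm summaries; the non-inferiority
#'   conclusion is added by [noninferiority_conclusion()].
#' @examples
#' risk_difference_ci(arm_summary("test", 100, 75), arm_summary("ref", 100, 80))
#' @export
risk_difference_ci <- function(test, ref, level = 0.95,
                               method = c("newcombe", "wald", "score")) {
  stopifnot(inherits(test, "arm_summary"), inherits(ref, "arm_summary"))
  method <- match.arg(method)
  if (test$n == 0 || ref$n == 0) stop("both arms must have n > 0")
  p1 <- test$successes / test$n
  p2 <- ref$successes / ref$n
  d <- p1 - p2
  ci <- switch(method,
    newcombe = {
      w1 <- wilson_ci(test$successes, test$n, level)
      w2 <- wilson_ci(ref$successes, ref$n, level)
      c(lower = d - sqrt((p1 - w1[["lower"]])^2 + (w2[["upper"]] - p2)^2),
        upper = d + sqrt((w1[["upper"]] - p1)^2 + (p2 - w2[["lower"]])^2))
    },
    wald = {
      z <- stats::qnorm(1 - (1 - level) / 2)
      se <- sqrt(p1 * (1 - p1) / test$n + p2 * (1 - p2) / ref$n)
      c(lower = d - z * se, upper = d + z * se)
    },
    score = mn_interval(test$successes, test$n, ref$successes, ref$n, level)
  )
  structure(list(risk_difference = d, ci = ci, level = level, method = method,
                 test = test, ref = ref,
                 margin = NA_real_, conclusion = NA_character_),
            class = "ni_result")
}

# Miettinen-Nurminen score statistic at hypothesised difference delta,
# using the closed-form constrained MLE of (p1, p2) subject to p1 - p2 = delta.
mn_score <- function(x1, n1, x2, n2, delta) {
  N <- n1 + n2
  p1h <- x1 / n1; p2h <- x2 / n2
  L3 <- N
  L2 <- (n1 + 2 * n2) * delta - N - (x1 + x2)
  L1 <- (n2 * delta - N - 2 * x2) * delta + x1 + x2
  L0 <- x2 * delta * (1 - delta)
  q <- L2^3 / (3 * L3)^3 - L1 * L2 / (6 * L3^2) + L0 / (2 * L3)
  p <- sqrt(max(0, L2^2 / (3 * L3)^2 - L1 / (3 * L3)))
  a <- if (p == 0) 0 else (pi + acos(max(-1, min(1, q / p^3)))) / 3
  p2t <- 2 * p * cos(a) - L2 / (3 * L3)
  p2t <- max(0, min(1, p2t))
  p1t <- max(0, min(1, p2t + delta))
  v <- (p1t * (1 - p1t) / n1 + p2t * (1 - p2t) / n2) * N / (N - 1)
  if (v <= 0) return(sign(p1h - p2h - delta) * Inf)
  (p1h - p2h - delta) / sqrt(v)
}

mn_interval <- function(x1, n1, x2, n2, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  d <- x1 / n1 - x2 / n2
  eps <- 1e-9
  lower <- if (d <= -1 + eps) -1 else
    stats::uniroot(function(del) mn_score(x1, n1, x2, n2, del) - z,
                   lower = -1 + eps, upper = d, tol = 1e-10)$root
  upper <- if (d >= 1 - eps) 1 else
    stats::uniroot(function(del) mn_score(x1, n1, x2, n2, del) + z,
                   lower = d, upper = 1 - eps, tol = 1e-10)$root
  c(lower = lower, upper = upper)
}

#' Declare non-inferiority against a margin
#'
#' The investigational arm is non-inferior when the lower bound of the
#' risk-difference interval lies strictly above the margin (default -10
#' percentage points); otherwise the result is inconclusive. A bound exactly
#' on the margin is inconclusive: the strict inequality is the conservative
#' reading of the margin.
#'
#' @param ni an `ni_result` from [risk_difference_ci()].
#' @param margin non-inferiority margin on the risk-difference scale;
#'   negative by convention (default -0.10).
#' @return the `ni_result` with `margin` and `conclusion`
#'   (`"non_inferior"` or `"inconclusive"`) filled in.
#' @export
noninferiority_conclusion <- function(ni, margin = -0.10) {
  stopifnot(inherits(ni, "ni_result"))
  if (is.na(margin) || margin >= 0) stop("non-inferiority margin must be negative")
  ni$margin <- margin
  ni$conclusion <- if (ni$ci[["lower"]] > margin) "non_inferior" else "inconclusive"
  ni
}

#' @export
print.ni_result <- function(x, digits = 4, ...) {
  cat(sprintf("Risk difference (%s - %s): %.4f\n", x$test$arm, x$ref$arm,
              x$risk_difference))
  cat(sprintf("  %g%% CI (%s): [%.*f, %.*f]\n", 100 * x$level, x$method,
              digits, x$ci[["lower"]], digits, x$ci[["upper"]]))
  if (!is.na(x$margin)) {
    cat(sprintf("  margin %.2f: %s\n", x$margin, x$conclusion))
  }
  invisible(x)
}
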