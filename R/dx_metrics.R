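# Diagnostic-accuracy battery: confusion-matrix metrics with confidence
# intervals, rank AUC, and a sweep over candidate inclusion rules against
# the physician reference diagnosis.

#' Build a 2x2 confusion matrix
#'
#' @param decisions logical (or 0/1) rule decisions, one per subject.
#' @param reference logical reference diagnosis (physician standard), same
#'   length.
#' @return object of class `confusion_matrix` with counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @examples
#' build_confusion(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
#' @export
build_confusion <- function(decisions, reference) {
  if (length(decisions) != length(reference)) stop("decisions and reference differ in length")
  if (length(decisions) == 0) stop("empty input: no subjects")
  d <- as.logical(decisions); r <- as.logical(reference)
  if (anyNA(d) || anyNA(r)) stop("decisions and reference must be complete")
  structure(list(tp = sum(d & r), fp = sum(d & !r),
                 fn = sum(!d & r), tn = sum(!d & !r)),
            class = "confusion_matrix")
}

#' @rdname build_confusion
#' @param tp,fp,fn,tn non-negative cell counts.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0)) stop("cell counts must be non-negative")
  if (sum(counts) == 0) stop("confusion matrix total must be positive")
  structure(lapply(counts, as.integer), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(rule = c("positive", "negative"),
                              reference = c("case", "control")))
  print(m)
  invisible(x)
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Full metric report for a binary rule
#'
#' Computes sensitivity, specificity, predictive values, likelihood ratios,
#' diagnostic odds ratio, Youden index, one-point ROC AUC `(sens + spec)/2`,
#' and the phi coefficient (the correlation between rule decision and
#' reference diagnosis for a binary rule).
#'
#' Ratio metrics (LR+, LR-, DOR) are undefined when a denominator cell is
#' zero. With `correction = "haldane_half"` (the default) 0.5 is added to
#' every cell before computing the ratio metrics whenever any cell is zero;
#' the uncorrected value is reported as `NA` alongside via the `defined`
#' attribute, so both conventions are preserved. Proportion metrics are
#' never corrected.
#'
#' @param cm a `confusion_matrix`.
#' @param correction `"haldane_half"` or `"none"`.
#' @return named list of class `metric_report`.
#' @examples
#' metric_report(confusion_matrix(tp = 85, fp = 28, fn = 15, tn = 72))
#' @export
metric_report <- function(cm, correction = c("haldane_half", "none")) {
  stopifnot(inherits(cm, "confusion_matrix"))
  correction <- match.arg(correction)
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn

  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  ppv <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)

  any_zero <- any(c(tp, fp, fn, tn) == 0)
  h <- if (correction == "haldane_half" && any_zero) 0.5 else 0
  sens_r <- (tp + h) / (tp + fn + 2 * h)
  spec_r <- (tn + h) / (tn + fp + 2 * h)
  lr_pos <- if (correction == "none" && (1 - spec) == 0) NA_real_ else sens_r / (1 - spec_r)
  lr_neg <- if (correction == "none" && spec == 0) NA_real_ else (1 - sens_r) / spec_r
  dor <- if (correction == "none" && (fp == 0 || fn == 0)) NA_real_ else
    ((tp + h) * (tn + h)) / ((fp + h) * (fn + h))

  youden <- sens + spec - 1
  auc <- (sens + spec) / 2
  phi_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  phi <- if (phi_den == 0) NA_real_ else (tp * tn - fp * fn) / phi_den

  structure(list(
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    lr_pos = lr_pos, lr_neg = lr_neg, dor = dor,
    youden = youden, auc = auc, phi = phi,
    corrected = correction == "haldane_half" && any_zero,
    cm = cm
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  keys <- c("sensitivity", "specificity", "ppv", "npv", "lr_pos", "lr_neg",
            "dor", "youden", "auc", "phi")
  vals <- vapply(keys, function(k) x[[k]], numeric(1))
  print(round(vals, digits))
  if (x$corrected) cat("(ratio metrics Haldane-corrected: a zero cell was present)\n")
  invisible(x)
}

#' Rank (Mann-Whitney) AUC of a score-valued rule
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control, ties counted one half; identical to the trapezoidal area under
#' the empirical ROC curve over all thresholds.
#'
#' @param scores numeric score per subject (e.g. an ACSS summary score).
#' @param reference logical case status per subject.
#' @return AUC in `[0, 1]`.
#' @examples
#' score_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
#' @export
score_auc <- function(scores, reference) {
  if (length(scores) != length(reference)) stop("scores and reference differ in length")
  r <- as.logical(reference)
  n1 <- sum(r); n0 <- sum(!r)
  if (n1 == 0 || n0 == 0) stop("AUC needs at least one case and one control")
  ranks <- rank(scores, ties.method = "average")
  (sum(ranks[r]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

wilson_ci <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = centre - half, upper = centre + half)
}

#' Confidence interval for one diagnostic metric
#'
#' Wilson score intervals for the proportion metrics (sensitivity,
#' specificity, PPV, NPV); normal intervals on the log scale for the ratio
#' metrics (LR+, LR-, DOR), with Haldane 0.5 correction applied to zero
#' cells before the log.
#'
#' @param cm a `confusion_matrix`.
#' @param metric one of `"sensitivity"`, `"specificity"`, `"ppv"`, `"npv"`,
#'   `"lr_pos"`, `"lr_neg"`, `"dor"`.
#' @param level confidence level.
#' @return named numeric `c(lower, upper)` containing the point estimate.
#' @export
metric_ci <- function(cm, metric, level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  prop_args <- list(sensitivity = c(tp, tp + fn), specificity = c(tn, tn + fp),
                    ppv = c(tp, tp + fp), npv = c(tn, tn + fn))
  if (metric %in% names(prop_args)) {
    a <- prop_args[[metric]]
    if (a[2] == 0) stop(metric, " is undefined for this confusion matrix")
    return(wilson_ci(a[1], a[2], level))
  }
  if (!metric %in% c("lr_pos", "lr_neg", "dor")) stop("unknown metric: ", metric)
  h <- if (any(c(tp, fp, fn, tn) == 0)) 0.5 else 0
  tp <- tp + h; fp <- fp + h; fn <- fn + h; tn <- tn + h
  z <- stats::qnorm(1 - (1 - level) / 2)
  est_se <- switch(metric,
    lr_pos = {
      est <- (tp / (tp + fn)) / (fp / (fp + tn))
      c(est, sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn)))
    },
    lr_neg = {
      est <- (fn / (tp + fn)) / (tn / (fp + tn))
      c(est, sqrt(1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn)))
    },
    dor = c((tp * tn) / (fp * fn), sqrt(1 / tp + 1 / fp + 1 / fn + 1 / tn))
  )
  c(lower = exp(log(est_se[1]) - z * est_se[2]),
    upper = exp(log(est_se[1]) + z * est_se[2]))
}

#' Sweep candidate inclusion rules over a labelled cohort
#'
#' Applies each [diagnostic_rule] to a cohort carrying questionnaire columns,
#' urinalysis and a reference diagnosis, and reports the full metric battery
#' per rule. The rule with the highest Youden index is flagged as `best`:
#' the highest Youden index and AUC represent the best balance between
#' sensitivity and specificity.
#'
#' @param cohort data frame with columns `t1..t6`, `wbc_mm3` and a logical
#'   `reference` column.
#' @param rules list of [diagnostic_rule] objects.
#' @param level confidence level for the sensitivity/specificity intervals.
#' @return data frame, one row per rule, with metric columns and `best`.
#' @export
rule_sweep <- function(cohort, rules, level = 0.95) {
  if (length(rules) == 0) stop("empty rule list")
  stopifnot("reference" %in% names(cohort))
  rows <- lapply(rules, function(rule) {
    cm <- build_confusion(apply_rule(cohort, rule), cohort$reference)
    rep <- metric_report(cm)
    sens_ci <- metric_ci(cm, "sensitivity", level)
    spec_ci <- metric_ci(cm, "specificity", level)
    data.frame(rule = rule$name,
               sensitivity = rep$sensitivity,
               sens_lower = sens_ci["lower"], sens_upper = sens_ci["upper"],
               specificity = rep$specificity,
               spec_lower = spec_ci["lower"], spec_upper = spec_ci["upper"],
               ppv = rep$ppv, npv = rep$npv,
               lr_pos = rep$lr_pos, lr_neg = rep$lr_neg, dor = rep$dor,
               youden = rep$youden, auc = rep$auc, phi = rep$phi,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$best <- out$youden == max(out$youden)
  out
}

#' Write a rule-sweep report table
#'
#' Delimited export of the diagnostic-accuracy battery, one row per rule.
#'
#' @param report data frame from [rule_sweep()].
#' @param path file path.
#' @export
write_metric_table <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
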