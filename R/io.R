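# Flat-file interchange. One CSV dialect per record type, UTF-8, header row
# required; the same dialects are emitted by the synthetic generator and
# consumed by the scoring/adjudication pipeline.

ACSS_CSV_COLS <- c("patient_id", "part", "visit_day",
                   paste0("t", 1:6), paste0("d", 1:4),
                   paste0("q", 1:3), paste0("a", 1:5), "dyn")

CULTURE_CSV_COLS <- c("patient_id", "visit_day", "wbc_mm3", "species", "cfu_per_ml")

#' Read / write ACSS questionnaire records
#'
#' One row per questionnaire administration, columns `patient_id, part,
#' visit_day, t1..t6, d1..d4, q1..q3, a1..a5, dyn`. Typical items t1..t6 are
#' ordered frequency, urgency, dysuria, suprapubic pain, incomplete emptying,
#' visible blood. `dyn` is empty for Part A rows.
#'
#' @param path file path.
#' @param x data frame in the questionnaire column layout.
#' @return `read_acss_csv` returns a data frame with the canonical columns;
#'   rows are not validated on read (use [validate_response()] per row).
#' @export
read_acss_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(ACSS_CSV_COLS, names(df))
  if (length(missing)) {
    stop("questionnaire file lacks required columns: ", paste(missing, collapse = ", "))
  }
  df[ACSS_CSV_COLS]
}

#' @rdname read_acss_csv
#' @export
write_acss_csv <- function(x, path) {
  missing <- setdiff(ACSS_CSV_COLS, names(x))
  if (length(missing)) {
    stop("questionnaire data lacks required columns: ", paste(missing, collapse = ", "))
  }
  utils::write.csv(x[ACSS_CSV_COLS], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Convert between response objects and the questionnaire table layout
#'
#' @param responses list of [acss_response] objects.
#' @return `responses_to_df` returns a data frame in the `t1..dyn` layout;
#'   `df_to_responses` the inverse (stopping on the first invalid row).
#' @export
responses_to_df <- function(responses) {
  stopifnot(all(vapply(responses, inherits, logical(1), "acss_response")))
  rows <- lapply(responses, function(r) {
    as.data.frame(c(
      list(patient_id = r$patient_id, part = r$part, visit_day = r$visit_day),
      stats::setNames(as.list(r$typical), paste0("t", 1:6)),
      stats::setNames(as.list(r$differential), paste0("d", 1:4)),
      stats::setNames(as.list(r$qol), paste0("q", 1:3)),
      stats::setNames(as.list(as.integer(r$additional)), paste0("a", 1:5)),
      list(dyn = r$dynamics)
    ))
  })
  do.call(rbind, rows)
}

#' @rdname responses_to_df
#' @param df data frame in the questionnaire layout.
#' @export
df_to_responses <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    out <- validate_response(df[i, , drop = FALSE])
    if (length(out$violations)) {
      stop(sprintf("row %d: %s", i, paste(out$violations, collapse = "; ")))
    }
    out$response
  })
}

#' Read / write urine-culture records
#'
#' One isolate per row, columns `patient_id, visit_day, wbc_mm3, species,
#' cfu_per_ml`; a sterile culture is a single row with empty species and CFU
#' 0. WBC density is per mm3 of mid-stream urine.
#'
#' @param path file path.
#' @param x data frame in the culture layout.
#' @export
read_culture_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = c(species = "character"))
  missing <- setdiff(CULTURE_CSV_COLS, names(df))
  if (length(missing)) {
    stop("culture file lacks required columns: ", paste(missing, collapse = ", "))
  }
  df$species[is.na(df$species)] <- ""
  df[CULTURE_CSV_COLS]
}

#' @rdname read_culture_csv
#' @export
write_culture_csv <- function(x, path) {
  missing <- setdiff(CULTURE_CSV_COLS, names(x))
  if (length(missing)) {
    stop("culture data lacks required columns: ", paste(missing, collapse = ", "))
  }
  utils::write.csv(x[CULTURE_CSV_COLS], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Assemble urine results from a culture table
#'
#' Groups culture rows by patient and visit into [urine_result] objects.
#'
#' @param df data frame in the culture layout.
#' @return list of [urine_result] objects.
#' @export
cultures_to_results <- function(df) {
  key <- interaction(df$patient_id, df$visit_day, drop = TRUE)
  lapply(split(df, key), function(g) {
    grown <- nzchar(g$species) & g$cfu_per_ml > 0
    urine_result(patient_id = g$patient_id[1], visit_day = g$visit_day[1],
                 wbc = g$wbc_mm3[1],
                 species = g$species[grown], cfu = g$cfu_per_ml[grown])
  })
}
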