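# Hand-built 10-patient trial with known clinical and microbiological
# outcomes at TOC (day 11, treatment end day 5). Cultures at 1e6 CFU/mL so
# significance is policy-independent for growing species.
make_manual_trial <- function() {
  ids <- sprintf("m%02d", 1:10)
  subjects <- data.frame(
    patient_id = ids, arm = rep(c("test", "reference"), 5),
    randomized = TRUE, dosed = TRUE, symptom_eligible = TRUE,
    baseline_species = "Escherichia coli", baseline_cfu = 1e6,
    baseline_wbc = 50, rescue = FALSE, rescue_day = NA_integer_,
    stringsAsFactors = FALSE)
  # clinical: patients 1-6 success (symptom-free), 7-10 failure (dysuria 3)
  typ <- rbind(matrix(0L, 6, 6), matrix(c(0L, 0L, 3L, 0L, 0L, 0L), 4, 6, byrow = TRUE))
  responses <- data.frame(patient_id = ids, part = "B", visit_day = 11L,
                          stringsAsFactors = FALSE)
  responses[paste0("t", 1:6)] <- as.data.frame(typ)
  responses[paste0("d", 1:4)] <- 0L
  responses[paste0("q", 1:3)] <- 0L
  responses[paste0("a", 1:5)] <- 0L
  responses$dyn <- 1L
  # micro at TOC: 1-3 sterile (eradication), 4-5 E. coli (persistence),
  # 6 Proteus (new infection), 7-8 E. coli (persistence), 9 sterile
  # (eradication), 10 missing culture (indeterminate)
  cultures <- rbind(
    data.frame(patient_id = ids, visit_day = 0L, wbc_mm3 = 50,
               species = "Escherichia coli", cfu_per_ml = 1e6),
    data.frame(patient_id = ids[c(1:3, 9)], visit_day = 11L, wbc_mm3 = 4,
               species = "", cfu_per_ml = 0),
    data.frame(patient_id = ids[c(4, 5, 7, 8)], visit_day = 11L, wbc_mm3 = 40,
               species = "Escherichia coli", cfu_per_ml = 1e6),
    data.frame(patient_id = ids[6], visit_day = 11L, wbc_mm3 = 30,
               species = "Proteus mirabilis", cfu_per_ml = 1e6))
  structure(list(subjects = subjects, responses = responses, cultures = cultures,
                 funnel = NULL, params = NULL), class = "trial_data")
}

test_that("micro-clinical cross-table reproduces hand-enumerated counts", {
  trial <- make_manual_trial()
  tab <- crosstab_micro_clinical(trial, significance_policy("general_1e5"),
                                 "ACSS5", "toc")
  expect_equal(sum(tab), 10) # margins equal the micro ITT size
  expect_equal(tab["success", "eradication"], c(eradication = 3) [[1]])
  expect_equal(unname(tab["success", "persistence"]), 2)
  expect_equal(unname(tab["success", "new_infection"]), 1)
  expect_equal(unname(tab["success", "indeterminate"]), 0)
  expect_equal(unname(tab["failure", "persistence"]), 2)
  expect_equal(unname(tab["failure", "eradication"]), 1)
  expect_equal(unname(tab["failure", "indeterminate"]), 1)
})

test_that("single-outcome cohorts collapse the cross-table to one cell", {
  trial <- make_manual_trial()
  keep <- sprintf("m%02d", 1:3) # all success + eradication
  trial$subjects <- trial$subjects[trial$subjects$patient_id %in% keep, ]
  trial$responses <- trial$responses[trial$responses$patient_id %in% keep, ]
  trial$cultures <- trial$cultures[trial$cultures$patient_id %in% keep, ]
  tab <- crosstab_micro_clinical(trial, significance_policy("general_1e5"),
                                 "ACSS5", "toc")
  expect_equal(unname(tab["success", "eradication"]), 3)
  expect_equal(sum(tab), 3)
})

test_that("permuted-block randomisation balances arms", {
  for (s in 1:5) {
    set.seed(s)
    arm <- randomize_blocks(67 * 2, c("a", "b"), block_size = 4)
    expect_lte(abs(sum(arm == "a") - sum(arm == "b")), 4)
  }
  set.seed(1)
  odd <- randomize_blocks(33, c("a", "b"), block_size = 4)
  expect_lte(abs(sum(odd == "a") - sum(odd == "b")), 4)
  expect_error(randomize_blocks(10, c("a", "b"), block_size = 3), "even")
})

test_that("the eligibility funnel is monotone on every run", {
  for (s in c(2, 11, 23)) {
    rep <- run_trial(trial_config(generator = trial_params(n_per_arm = 25), seed = s))
    f <- rep$funnel
    expect_true(all(diff(unname(f[c("screened", "symptom_eligible", "eligible",
                                    "randomized", "dosed", "analyzed")])) <= 0))
  }
})

test_that("trial reports are deterministic given config and seed", {
  cfg <- trial_config(generator = trial_params(n_per_arm = 20), seed = 31)
  r1 <- run_trial(cfg)
  r2 <- run_trial(cfg)
  expect_identical(report_to_list(r1), report_to_list(r2))
  r3 <- run_trial(trial_config(generator = trial_params(n_per_arm = 20), seed = 32))
  expect_false(identical(report_to_list(r1), report_to_list(r3)))
})

test_that("universal rescue forces zero success and zero risk difference", {
  gen <- trial_params(n_per_arm = 20, rescue_prob = c(1, 1), rescue_day = 0L,
                      relapse_prob = NULL)
  rep <- run_trial(trial_config(generator = gen, seed = 4))
  expect_true(all(rep$success_tables$n_success == 0))
  expect_equal(rep$ni$risk_difference, 0)
})

test_that("trial config rejects contradictory settings", {
  expect_error(trial_config(primary_threshold = c("ACSS5", "FDA4")), "one primary")
  expect_error(trial_config(margin = 0.1), "negative")
  expect_error(trial_config(generator = NULL, input_files = NULL), "required")
  expect_error(trial_config(population = "micro_itt", generator = NULL,
                            input_files = list(subjects = "s.csv", responses = "r.csv")),
               "culture")
})

test_that("a trial written to files and re-analysed gives the same primary result", {
  gen <- trial_params(n_per_arm = 20)
  trial <- generate_trial(gen, seed = 8)
  dir <- withr::local_tempdir()
  paths <- write_trial_files(trial, dir)
  direct <- run_trial(trial_config(generator = gen, seed = 8))
  from_files <- run_trial(trial_config(generator = gen, input_files = paths, seed = 8))
  expect_equal(from_files$ni$risk_difference, direct$ni$risk_difference)
  expect_equal(unname(from_files$ni$ci), unname(direct$ni$ci))
  expect_equal(from_files$success_tables$n_success, direct$success_tables$n_success)
})
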