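test_that("presets emit the published cohort sizes", {
  co <- generate_diagnostic_cohort(cohort_preset("study2019"), seed = 1)
  expect_equal(nrow(co$subjects), 517)
  expect_equal(sum(co$subjects$reference), 285)
  expect_equal(sum(!co$subjects$reference), 232)
  tr <- generate_trial(trial_preset("outcome2023"), seed = 1)
  expect_equal(nrow(tr$subjects), 134)
  # all-control cohort
  empty_cases <- generate_diagnostic_cohort(cohort_params(n_cases = 0, n_controls = 25), seed = 2)
  expect_equal(sum(empty_cases$subjects$reference), 0)
  expect_equal(nrow(empty_cases$subjects), 25)
})

test_that("generation is deterministic given the seed, down to the written files", {
  p <- cohort_params(n_cases = 40, n_controls = 30)
  a <- generate_diagnostic_cohort(p, seed = 9)
  b <- generate_diagnostic_cohort(p, seed = 9)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$cultures, b$cultures)
  c <- generate_diagnostic_cohort(p, seed = 10)
  expect_false(identical(a$subjects, c$subjects))

  t1 <- generate_trial(trial_params(n_per_arm = 20), seed = 5)
  t2 <- generate_trial(trial_params(n_per_arm = 20), seed = 5)
  f1 <- withr::local_tempdir(); f2 <- withr::local_tempdir()
  p1 <- write_trial_files(t1, f1); p2 <- write_trial_files(t2, f2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
})

test_that("empirical severity frequencies match the generating distributions", {
  n <- 10000
  co <- generate_diagnostic_cohort(cohort_params(n_cases = n, n_controls = 0), seed = 77)
  dist <- co$params$case_typical
  for (j in 1:6) {
    obs <- tabulate(co$subjects[[paste0("t", j)]] + 1L, nbins = 4)
    keep <- dist[j, ] > 0
    gof <- stats::chisq.test(obs[keep], p = dist[j, keep])
    expect_gt(gof$p.value, 0.01)
  }
  # WBC marginals: pyuria prevalence differs strongly by case status
  both <- generate_diagnostic_cohort(cohort_params(n_cases = 2000, n_controls = 2000), seed = 78)
  py <- both$subjects$wbc_mm3 >= 10
  expect_gt(mean(py[both$subjects$reference]), 0.8)
  expect_lt(mean(py[!both$subjects$reference]), 0.35)
})

test_that("degenerate trial configurations force their outcomes", {
  # full resolution, no rescue, symptom-free resolved state: all success
  perfect <- trial_params(
    n_per_arm = 15,
    visit_success_prob = matrix(1, 2, 4),
    rescue_prob = c(0, 0), relapse_prob = NULL, abu_prob_given_success = 0,
    resolved_typical = severity_dist_matrix(rep(list(c(1, 0, 0, 0)), 6),
                                            paste0("t", 1:6)))
  tr <- generate_trial(perfect, seed = 3)
  for (th in c("ACSS5", "FDA4", "EMA3")) {
    adj <- adjudicate_trial(tr, th)
    expect_true(all(adj$status == "success"), label = th)
  }
  # universal rescue from day 0: failure everywhere
  rescued <- trial_params(n_per_arm = 15, rescue_prob = c(1, 1), rescue_day = 0L,
                          relapse_prob = NULL)
  tr2 <- generate_trial(rescued, seed = 3)
  adj2 <- adjudicate_trial(tr2, "ACSS5")
  expect_true(all(adj2$status == "failure"))
})

test_that("trial parameters are validated", {
  expect_error(trial_params(visit_success_prob = matrix(1.5, 2, 4)), "\\[0, 1\\]")
  expect_error(trial_params(rescue_prob = c(-0.1, 0)), "\\[0, 1\\]")
  expect_error(trial_params(arms = "only-one"), "two arms")
  expect_error(cohort_params(n_cases = -1))
  bad_dist <- matrix(0.3, 6, 4)
  expect_error(cohort_params(case_typical = bad_dist), "sum to 1")
})

test_that("latent mixing induces positive item correlation", {
  plain <- generate_diagnostic_cohort(
    cohort_params(n_cases = 3000, n_controls = 0), seed = 55)
  mixed <- generate_diagnostic_cohort(
    cohort_params(n_cases = 3000, n_controls = 0, latent_mixing = 0.7), seed = 55)
  cor_of <- function(co) cor(co$subjects$t1, co$subjects$t2)
  expect_gt(cor_of(mixed), cor_of(plain) + 0.2)
})

test_that("the recovery harness estimates the latent success probabilities", {
  params <- trial_params(
    n_per_arm = 30,
    visit_success_prob = matrix(c(0.6, 0.6, 0.6, 0.6, 0.8, 0.8, 0.8, 0.8),
                                2, 4, byrow = TRUE),
    rescue_prob = c(0, 0), relapse_prob = NULL, abu_prob_given_success = 0,
    resolved_typical = severity_dist_matrix(rep(list(c(1, 0, 0, 0)), 6),
                                            paste0("t", 1:6)),
    unresolved_typical = severity_dist_matrix(c(list(c(0, 0, 0, 1)),
                                                rep(list(c(1, 0, 0, 0)), 5)),
                                              paste0("t", 1:6)))
  rec <- recovery_harness(params, replicates = 60, seed = 400)
  expect_equal(nrow(rec), 8)
  expect_true(all(abs(rec$mean_success - rec$true_prob) <= 4 * rec$mc_se))
  # distinct seeds: statistically compatible but not identical estimates
  rec2 <- recovery_harness(params, replicates = 60, seed = 9000)
  expect_false(identical(rec$mean_success, rec2$mean_success))
  expect_true(all(abs(rec$mean_success - rec2$mean_success) <=
                    4 * sqrt(rec$mc_se^2 + rec2$mc_se^2)))
  one <- recovery_harness(params, replicates = 1, seed = 12)
  expect_equal(unique(one$replicates), 1)
})
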