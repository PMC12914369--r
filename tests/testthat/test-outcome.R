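test_that("visit days map to the follow-up schedule", {
  expect_equal(classify_visit(3, 5), "early")
  expect_equal(classify_visit(7, 5), "end_of_treatment")
  expect_equal(classify_visit(11, 5), "toc") # 6 days after end of treatment
  expect_equal(classify_visit(28, 5), "late_fu")
  expect_equal(classify_visit(1, 5), "unscheduled")
  expect_equal(classify_visit(15, 5), "unscheduled")
  # overlapping windows resolve to the later stage
  expect_equal(classify_visit(7, 2), "toc")       # toc beats end_of_treatment
  expect_equal(classify_visit(c(2, 9, 33), 5), c("early", "end_of_treatment", "late_fu"))
  expect_error(classify_visit(-1, 5))
})

test_that("adjudication applies the cure threshold and the rescue rule", {
  expect_equal(adjudicate(respB(c(1, 1, 1, 1, 1, 0)), "ACSS5")$status, "success")
  expect_equal(adjudicate(respB(c(0, 0, 2, 0, 0, 0)), "ACSS5")$status, "failure")
  expect_equal(adjudicate(respB(rep(0, 6)), "ACSS5", rescue_taken = TRUE)$status, "failure")
  # visible blood blocks cure and raises the hematuria flag independently
  a <- adjudicate(respB(c(0, 0, 0, 0, 0, 1)), "ACSS5")
  expect_equal(a$status, "failure")
  expect_true(a$hematuria_flag)
  b <- adjudicate(respB(c(0, 0, 2, 0, 0, 1)), "ACSS5", rescue_taken = TRUE)
  expect_true(b$hematuria_flag)
  expect_error(adjudicate(resp(rep(0, 6)), "ACSS5"), "Part B")
  expect_error(adjudicate(respB(rep(0, 6), dynamics = NULL), "DYNAMICS_ONLY"), "Dynamics")
  expect_equal(adjudicate(respB(rep(0, 6), dynamics = 0), "DYNAMICS_ONLY")$status, "success")
  expect_equal(adjudicate(respB(rep(0, 6), dynamics = 1), "DYNAMICS_ONLY")$status, "failure")
  # QoL criterion tightens the five-symptom threshold
  ok <- acss_response(c(1, 1, 1, 0, 0, 0), qol = c(2, 0, 0), part = "B",
                      visit_day = 11, dynamics = 1)
  expect_equal(adjudicate(ok, "ACSS5")$status, "success")
  expect_equal(adjudicate(ok, "ACSS5_QOL")$status, "failure")
})

test_that("cure and the failure criteria partition all 1024 five-symptom vectors", {
  grid <- all_severity_vectors(5)
  for (i in seq_len(nrow(grid))) {
    v <- c(grid[i, ], 0) # no visible blood
    status <- adjudicate(respB(v), "ACSS5")$status
    fails <- sum(grid[i, ]) >= 6 || max(grid[i, ]) >= 2
    expect_equal(status == "failure", fails)
  }
})

test_that("the summary-score clause is implied by the per-item cap", {
  for (nm in c("EMA3", "FDA4", "ACSS5")) {
    thr <- outcome_threshold(nm)
    k <- length(variant_indices(thr$variant))
    grid <- all_severity_vectors(k)
    for (i in seq_len(nrow(grid))) {
      v <- rep(0L, 6); v[variant_indices(thr$variant)] <- grid[i, ]
      with_sum <- adjudicate(respB(v), thr)$status
      # a cap-only adjudication: max item <= 1 and no blood
      cap_only <- max(grid[i, ]) <= 1
      expect_equal(with_sum == "success", cap_only)
    }
  }
})

test_that("raising a severity never converts failure into success, and successes nest", {
  set.seed(13)
  for (i in 1:150) {
    v <- sample(0:3, 6, replace = TRUE)
    s1 <- adjudicate(respB(v), "ACSS5")$status
    idxs <- which(v < 3)
    if (!length(idxs)) next
    j <- idxs[sample.int(length(idxs), 1)]
    v2 <- v; v2[j] <- v2[j] + 1L
    s2 <- adjudicate(respB(v2), "ACSS5")$status
    expect_false(s1 == "failure" && s2 == "success")
  }
  # ACSS5 success implies FDA4 success implies EMA3 success (nested item sets)
  grid <- all_severity_vectors(6)
  for (i in seq_len(nrow(grid))) {
    r <- respB(grid[i, ])
    s <- vapply(c("ACSS5", "FDA4", "EMA3"), function(t) {
      adjudicate(r, t)$status == "success"
    }, logical(1))
    expect_true(!s[["ACSS5"]] || s[["FDA4"]])
    expect_true(!s[["FDA4"]] || s[["EMA3"]])
  }
})

test_that("success tables aggregate per threshold and window", {
  adj <- data.frame(
    patient_id = c("a", "b", "c", "d"), window = "toc", threshold = "ACSS5",
    status = c("success", "success", "success", "failure"),
    stringsAsFactors = FALSE)
  tab <- success_table(adj)
  expect_equal(tab$proportion, 0.75)
  expect_equal(tab$n_total, 4)
  expect_equal(nrow(success_table(adj[0, ])), 0)
  expect_error(success_table(rbind(adj, adj[1, ])), "duplicate")
  # a strictly stricter threshold can only lower the success count
  set.seed(21)
  typ <- matrix(sample(0:3, 50 * 6, TRUE, prob = c(.5, .3, .15, .05)), 50)
  qol <- matrix(sample(0:3, 50 * 3, TRUE), 50)
  rows <- do.call(rbind, lapply(c("ACSS5", "ACSS5_QOL"), function(th) {
    ok <- vapply(seq_len(50), function(i) {
      r <- acss_response(typ[i, ], qol = qol[i, ], part = "B", visit_day = 11,
                         dynamics = 1)
      adjudicate(r, th)$status
    }, character(1))
    data.frame(patient_id = sprintf("p%02d", 1:50), window = "toc",
               threshold = th, status = ok, stringsAsFactors = FALSE)
  }))
  tab2 <- success_table(rows)
  expect_lte(tab2$n_success[tab2$threshold == "ACSS5_QOL"],
             tab2$n_success[tab2$threshold == "ACSS5"])
})

test_that("cure score floors equal the failure cuts", {
  expect_equal(cure_score_floor("ACSS5"), 6)
  expect_equal(cure_score_floor("FDA4"), 5)
  expect_equal(cure_score_floor("EMA3"), 4)
})
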