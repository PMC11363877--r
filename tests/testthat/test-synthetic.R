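test_that("generation is seed-deterministic, byte-identical on disk", {
  tr <- tiny_truth()
  g1 <- generate_general_survey(tr, n = 200, seed = 4)
  g2 <- generate_general_survey(tr, n = 200, seed = 4)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  r1 <- generate_rds_survey(tr, n_target = 80, seed = 4)
  r2 <- generate_rds_survey(tr, n_target = 80, seed = 4)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(tr, d1, n_general = 100, seed = 9, n_target = 40)
  write_simulation(tr, d2, n_general = 100, seed = 9, n_target = 40)
  for (f in c("general_survey.csv", "rds_survey.csv", "frame.yaml", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # and the written study round-trips through the readers
  fr <- load_frame(file.path(d1, "frame.yaml"))
  expect_equal(fr$e0, tr$frame$e0)
  g <- read_general_survey(file.path(d1, "general_survey.csv"), fr)
  expect_s3_class(g, "general_survey")
  r <- read_rds_survey(file.path(d1, "rds_survey.csv"), fr)
  expect_s3_class(r, "rds_table")
})

test_that("generated tables always satisfy their type invariants", {
  for (seed in 1:6) {
    tr <- tiny_truth(tau_true = c(0.5, 0.8, 1)[(seed %% 3) + 1])
    r <- generate_rds_survey(tr, n_target = 70, seed = seed)
    expect_true(all(aware_matrix(r) <= known_matrix(r)))
    is_seed <- is.na(r$recruiter_id)
    expect_true(all(r$wave[is_seed] == 0))
    ridx <- match(r$recruiter_id[!is_seed], r$id)
    expect_false(anyNA(ridx))
    expect_true(all(r$wave[ridx] == r$wave[!is_seed] - 1))
    # re-validation is idempotent (construction enforced the invariants)
    expect_silent(rds_table(as.data.frame(r), tr$frame))
  }
})

test_that("degenerate truths produce the promised degenerate surveys", {
  # tau = 1: aware counts equal known counts everywhere
  tr1 <- tiny_truth(tau_true = 1)
  r <- generate_rds_survey(tr1, n_target = 50, seed = 3)
  expect_identical(aware_matrix(r), known_matrix(r))

  # n_target = n_seeds: all rows are seeds at wave 0
  r2 <- generate_rds_survey(tiny_truth(), n_target = 5, n_seeds = 5, seed = 3)
  expect_equal(nrow(r2), 5L)
  expect_true(all(r2$wave == 0) && all(is.na(r2$recruiter_id)))

  # N_H = 0: nobody to report, all unmasked sensitive answers are zero
  tr0 <- tiny_truth(N_H = 0, nonresponse_rate = 0)
  g <- generate_general_survey(tr0, n = 150, seed = 2)
  expect_true(all(attr(g, "hidden_true") == 0))
  # ... and recruitment of a hidden population of zero is impossible
  expect_error(generate_rds_survey(tr0, n_target = 10, seed = 1), "exhausts")

  expect_error(generate_rds_survey(tiny_truth(), n_target = 2, n_seeds = 5),
               "n_target >= n_seeds")
  expect_error(generate_rds_survey(tiny_truth(N_H = 20), n_target = 50),
               "exhausts")
})

test_that("truth_report is a pure linear account of the truth", {
  tr <- tiny_truth(N_H = 1242)
  tp <- truth_report(tr)
  expect_equal(tp$prevalence_pct, 100 * 1242 / tr$frame$adult_pop)
  expect_equal(truth_report(tiny_truth(N_H = 2484))$prevalence_pct,
               2 * tp$prevalence_pct)
  tp1 <- truth_report(tiny_truth(delta_true = 1, tau_true = 1))
  expect_equal(tp1$e1_expected, tp1$N_H)
  expect_equal(tp$e1_expected, tr$N_H * tr$delta_true * tr$tau_true)
  # the published-world prevalence: N_H = 1242 on the built-in frame
  tpT <- truth_report(synthetic_truth(N_H = 1242))
  expect_equal(signif(tpT$prevalence_pct, 2), 0.044)
})

test_that("general survey honors nonresponse, masking and cluster structure", {
  tr <- tiny_truth(nonresponse_rate = 0.2)
  g <- generate_general_survey(tr, n = 2000, seed = 21)
  # blank sheets carry no counts and no answer
  blank <- !g$answered
  expect_gt(sum(blank), 0)
  expect_true(all(is.na(known_matrix(g[blank, , drop = FALSE]))))
  expect_true(all(is.na(g$rrt_answer[blank])))
  expect_lt(abs(mean(blank) - 0.2), 4 * sqrt(0.2 * 0.8 / 2000))
  # nested labels: each department maps to exactly one unit and industry
  expect_true(all(rowSums(table(g$department, g$unit) > 0) == 1))
  expect_true(all(rowSums(table(g$unit, g$industry) > 0) == 1))
  expect_true(all(g$rrt_group %in% c(1, 2)))
})
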