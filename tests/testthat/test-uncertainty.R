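mean_rowsum <- function(x) mean(rowSums(known_matrix(x)))

test_that("degenerate and deterministic bootstrap contracts hold", {
  fr <- tiny_frame()
  # constant dataset: every resample is identical, CI width 0
  g <- manual_general(rep(5, 30))
  b <- bootstrap_general(g, mean_rowsum, bootstrap_spec(B = 200, seed = 1))
  expect_equal(b$ci_low, b$ci_high)
  expect_equal(b$point, 5)

  km <- matrix(2L, 10, nrow(fr$known))
  r <- manual_rds(km, frame = fr)
  bc <- rds_chain_bootstrap(r, mean_rowsum, bootstrap_spec(B = 200, seed = 1))
  expect_equal(bc$ci_low, bc$ci_high)

  # fixed seed -> identical CI on re-run; different seed -> different replicates
  g2 <- manual_general(rpois(60, 6))
  b1 <- bootstrap_general(g2, mean_rowsum, bootstrap_spec(B = 300, seed = 42))
  b2 <- bootstrap_general(g2, mean_rowsum, bootstrap_spec(B = 300, seed = 42))
  expect_identical(b1$replicates, b2$replicates)
  b3 <- bootstrap_general(g2, mean_rowsum, bootstrap_spec(B = 300, seed = 43))
  expect_false(identical(b1$replicates, b3$replicates))

  # percentile CI brackets its own resample median
  med <- stats::median(b1$replicates)
  expect_lte(b1$ci_low, med); expect_gte(b1$ci_high, med)
})

test_that("invalid recruitment graphs are rejected before resampling", {
  fr <- tiny_frame()
  km <- matrix(1L, 3, nrow(fr$known))
  # dangling recruiter
  expect_error(manual_rds(km, frame = fr, recruiter = c(NA, "R1", "ghost"),
                          wave = c(0L, 1L, 2L)), "dangling|recruiter")
  # cycle (mutual recruitment) cannot satisfy the wave ordering
  expect_error(manual_rds(km, frame = fr, recruiter = c("R2", "R1", "R1"),
                          wave = c(1L, 1L, 2L)), "seed|earlier")
  # seed at nonzero wave
  expect_error(manual_rds(km, frame = fr, recruiter = c(NA, "R1", "R1"),
                          wave = c(1L, 2L, 2L)), "wave")
})

test_that("cluster bootstrap resamples whole clusters", {
  tr <- tiny_truth()
  g <- generate_general_survey(tr, n = 300, seed = 6)
  m0_stat <- function(x) as.numeric(suppressMessages(mean_known_count(x)))
  b <- bootstrap_general(g, m0_stat,
                         bootstrap_spec(B = 100, seed = 2,
                                        cluster_level = "department"))
  expect_true(is.finite(b$ci_low) && b$ci_low <= b$point && b$point <= b$ci_high)
  expect_error(
    bootstrap_general(g[, setdiff(names(g), "department")], m0_stat,
                      bootstrap_spec(B = 10, seed = 2,
                                     cluster_level = "department")),
    "cluster")
})

test_that("bootstrap CI for a mean attains nominal coverage (scaled-down sim)", {
  # Scaled down from 500 outer reps x B = 2000 to 300 x 1000 to fit the test
  # budget; tolerance widened from +/-3 to +/-4 points (3 binomial SEs at 300).
  mu <- 5; n <- 500
  cover <- 0L
  for (rep in seq_len(300)) {
    set.seed(1000 + rep)
    df <- data.frame(y = stats::rnorm(n, mu, 1))
    b <- bootstrap_general(df, function(t) mean(t$y),
                           bootstrap_spec(B = 1000, seed = 2000 + rep))
    cover <- cover + (b$ci_low <= mu && mu <= b$ci_high)
  }
  expect_gte(cover / 300, 0.91)
  expect_lte(cover / 300, 0.99)
})

test_that("endpoints converge in B on a fixed dataset", {
  set.seed(77)
  df <- data.frame(y = stats::rgamma(200, 2, 0.5))
  st <- function(t) mean(t$y)
  b5 <- bootstrap_general(df, st, bootstrap_spec(B = 5000, seed = 5))
  b10 <- bootstrap_general(df, st, bootstrap_spec(B = 10000, seed = 5))
  expect_lt(abs(b5$ci_low - b10$ci_low) / abs(b10$ci_low), 0.01)
  expect_lt(abs(b5$ci_high - b10$ci_high) / abs(b10$ci_high), 0.01)
})

test_that("joint pipeline CI: delta = tau = 1 world collapses onto e1", {
  # A world with no barrier effect or transmission error: the adjusted CI
  # should approximate the e1 CI up to the (propagated) resampling noise of
  # the estimated adjustment factors.
  tr <- tiny_truth(delta_true = 1, tau_true = 1, nonresponse_rate = 0)
  g <- generate_general_survey(tr, n = 1500, seed = 14)
  r <- generate_rds_survey(tr, n_target = 300, seed = 15)
  ci <- joint_pipeline_ci(g, r, tr$frame, rrt_design(),
                          bootstrap_spec(B = 400, seed = 16))
  expect_lt(abs(log(ci$delta$point)), 0.15)
  expect_lt(abs(log(ci$tau$point)), 0.1)
  expect_lt(abs(ci$adjusted$point / ci$e1$point - 1), 0.3)
  # reproducible report
  ci2 <- joint_pipeline_ci(g, r, tr$frame, rrt_design(),
                           bootstrap_spec(B = 400, seed = 16))
  expect_identical(ci$replicates, ci2$replicates)
  # every intermediate got a CI
  expect_setequal(setdiff(names(ci), "replicates"),
                  c("m0", "c", "m1", "e1", "c_H", "aware", "delta", "tau",
                    "adjusted", "prevalence"))
})

test_that("a statistic failing on too many resamples aborts with a diagnostic", {
  df <- data.frame(y = c(1, 2, 3, 4))
  flaky <- function(t) if (stats::runif(1) < 0.2) stop("boom") else mean(t$y)
  expect_error(bootstrap_general(df, flaky, bootstrap_spec(B = 200, seed = 9)),
               "failed on")
})
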