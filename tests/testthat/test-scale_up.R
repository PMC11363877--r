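test_that("mean_known_count averages answered row-sums and logs exclusions", {
  g <- manual_general(c(8, 8, 9))
  expect_equal(as.numeric(mean_known_count(g)), 25 / 3)

  g2 <- manual_general(c(8, 8, 9, 99), answered = c(TRUE, TRUE, TRUE, FALSE))
  expect_message(m <- mean_known_count(g2), "excluded 1")
  expect_equal(as.numeric(m), 25 / 3)
  expect_equal(attr(m, "n_excluded"), 1L)

  g3 <- manual_general(c(1, 2), answered = c(FALSE, FALSE))
  expect_error(mean_known_count(g3), "no answered rows")
})

test_that("network size and basic estimate reproduce the published arithmetic", {
  fr <- taiyuan_frame()
  # published: 58.5 = 3.9 * 4,531,429 / 302,251
  expect_equal(round(network_size_from_known(3.9, fr), 1), 58.5)
  # published chain used unrounded m0; printed m0 = 8.3 recomputes to 124.4
  expect_equal(round(network_size_from_known(8.3, fr), 1), 124.4)
  expect_equal(network_size_from_known(0, fr), 0)

  # published: 585.1 from unrounded inputs; printed inputs give 585.2 at 1 dp
  expect_equal(round(basic_nsum_estimate(1.6e-2, 123.9, fr$t), 1), 585.2)
  expect_equal(basic_nsum_estimate(0, 123.9, fr$t), 0)
  expect_equal(basic_nsum_estimate(123.9, 123.9, fr$t), fr$t)
  expect_error(basic_nsum_estimate(1, 0, fr$t), "positive")
})

test_that("composition identity and scale equivariance hold", {
  fr <- tiny_frame()
  m0 <- 7.3; m1 <- 0.21
  c_G <- network_size_from_known(m0, fr)
  expect_equal(basic_nsum_estimate(m1, c_G, fr$t), m1 * fr$e0 / m0)

  g <- manual_general(c(3, 5, 8, 2))
  m <- as.numeric(mean_known_count(g))
  g2 <- manual_general(2 * c(3, 5, 8, 2))
  expect_equal(as.numeric(mean_known_count(g2)), 2 * m)
  expect_equal(network_size_from_known(2 * m, fr),
               2 * network_size_from_known(m, fr))
})

test_that("mean known count matches the binomial-expectation oracle", {
  tr <- tiny_truth(delta_true = 1, tau_true = 1, nonresponse_rate = 0)
  fr <- tr$frame
  g <- generate_general_survey(tr, n = 5000, seed = 99)
  rs <- rowSums(known_matrix(g))
  target <- tr$c_true * fr$e0 / fr$t   # E[rowsum] = E[d] * e0 / t
  se <- stats::sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs) - target), 3 * se)
})

test_that("name-proportion diagnostic behaves on exact, noisy and adversarial data", {
  fr <- tiny_frame()
  n_names <- nrow(fr$known)
  # reported counts exactly proportional to the actual sizes -> r = 1
  km <- matrix(rep(fr$known$size, each = 4), nrow = 4)
  df <- data.frame(id = paste0("G", 1:4), stringsAsFactors = FALSE)
  df[paste0("name_", fr$known$label)] <- as.data.frame(km)
  df$rrt_group <- 1L; df$rrt_answer <- 0; df$answered <- TRUE
  d <- name_proportion_diagnostic(general_survey(df, fr), fr)
  expect_equal(d$r, 1)

  # counts reversed against size order -> negative correlation
  df[paste0("name_", fr$known$label)] <- as.data.frame(
    matrix(rep(rev(fr$known$size), each = 4), nrow = 4))
  expect_lt(name_proportion_diagnostic(general_survey(df, fr), fr)$r, 0)

  # constant actual shares -> undefined correlation error
  frc <- study_frame(100000, 65000,
                     data.frame(label = paste0("C", 1:4), size = rep(150L, 4)))
  dfc <- data.frame(id = "G1", stringsAsFactors = FALSE)
  dfc[paste0("name_", frc$known$label)] <- as.list(c(1L, 2L, 3L, 4L))
  dfc$rrt_group <- 1L; dfc$rrt_answer <- 0; dfc$answered <- TRUE
  expect_error(name_proportion_diagnostic(general_survey(dfc, frc), frc),
               "constant|undefined")

  # generator's own binomial tie model: strong positive correlation. A
  # 60-seed Monte-Carlo oracle puts r at 0.91 +/- 0.03 for n = 1000 (min
  # 0.835) and above 0.96 for n = 5000, so the thresholds below hold with
  # margin rather than sitting on the distribution's edge.
  g <- generate_general_survey(tiny_truth(), n = 1000, seed = 12)
  expect_gt(name_proportion_diagnostic(g, fr)$r, 0.8)
  g5 <- generate_general_survey(tiny_truth(), n = 5000, seed = 12)
  expect_gt(name_proportion_diagnostic(g5, fr)$r, 0.9)
})
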