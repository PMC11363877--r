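test_that("adjustment arithmetic reproduces the published chain values", {
  fr <- taiyuan_frame()
  # printed means chain: 4.4 -> 66.0 and 3.9 -> 58.5 (paper printed 66.3 from
  # the unrounded mean)
  expect_equal(round(4.4 * fr$t / fr$e0, 1), 66.0)
  km <- matrix(0L, 2, nrow(fr$known)); km[, 1] <- c(4L, 5L)  # mean 4.5 rows
  expect_equal(hidden_network_size(manual_rds(km, frame = fr), fr),
               4.5 * fr$t / fr$e0)

  expect_equal(round(popularity_ratio(66.3, 123.9), 3), 0.535)
  expect_equal(popularity_ratio(77, 77), 1)
  expect_equal(popularity_ratio(0, 50), 0)
  expect_equal(round(transmission_rate(58.5, 66.3), 3), 0.882)
  expect_equal(transmission_rate(66.3, 66.3), 1)
  expect_equal(transmission_rate(0, 66.3), 0)

  expect_equal(round(adjusted_estimate(585.1, adjustment_factors(0.536, 0.879)), 1),
               1241.9)
  expect_equal(adjusted_estimate(100, adjustment_factors(0.5, 0.5)), 400)
  expect_equal(adjusted_estimate(585.1, adjustment_factors(1, 1)), 585.1)
  expect_equal(signif(prevalence(1241.9, fr), 2), 0.044)
  expect_equal(prevalence(0, fr), 0)
  expect_equal(prevalence(fr$adult_pop, fr), 100)
})

test_that("aware/hidden network sizes respect their invariants on tables", {
  fr <- tiny_frame()
  km <- matrix(3L, 4, nrow(fr$known))
  # aware == known -> tau = 1 exactly; all-zero aware -> 0
  r <- manual_rds(km, km, frame = fr)
  expect_equal(aware_network_size(r, fr), hidden_network_size(r, fr))
  r0 <- manual_rds(km, km * 0L, frame = fr)
  expect_equal(aware_network_size(r0, fr), 0)
  expect_error(hidden_network_size(r[0, ], fr), "empty")

  # aware > known is rejected at construction
  expect_error(manual_rds(km, km + 1L, frame = fr), "aware")
})

test_that("tau <= 1 on any valid generated RDS table; delta > 1 warns", {
  for (seed in 1:5) {
    tr <- tiny_truth(tau_true = runif(1, 0.3, 1))
    r <- generate_rds_survey(tr, n_target = 60, seed = seed)
    c_H <- hidden_network_size(r, tr$frame)
    if (c_H > 0) {
      expect_lte(transmission_rate(aware_network_size(r, tr$frame), c_H), 1)
    }
    expect_true(all(aware_matrix(r) <= known_matrix(r)))
  }
  expect_warning(popularity_ratio(130, 100), "> 1")
})

test_that("adjusted estimate is strictly decreasing in delta and tau", {
  e1 <- 585.1
  grid <- seq(0.2, 1, by = 0.1)
  for (tau in c(0.5, 0.9, 1)) {
    vals <- vapply(grid, function(d)
      adjusted_estimate(e1, adjustment_factors(d, tau)), numeric(1))
    expect_true(all(diff(vals) < 0))
  }
  for (delta in c(0.4, 0.8, 1)) {
    vals <- vapply(grid, function(tau)
      adjusted_estimate(e1, adjustment_factors(delta, tau)), numeric(1))
    expect_true(all(diff(vals) < 0))
  }
  # adjusted >= e1 whenever both factors are <= 1
  for (d in c(0.3, 1)) for (tau in c(0.4, 1)) {
    expect_gte(adjusted_estimate(e1, adjustment_factors(d, tau)), e1)
  }
})

test_that("RDS means recover the generator's truth within 3 SE", {
  tr <- tiny_truth(delta_true = 0.6, tau_true = 0.8)
  fr <- tr$frame
  r <- generate_rds_survey(tr, n_target = 300, seed = 31)
  rs <- rowSums(known_matrix(r))
  se <- stats::sd(rs) / sqrt(length(rs)) * fr$t / fr$e0
  expect_lt(abs(hidden_network_size(r, fr) - tr$c_true * tr$delta_true), 3 * se)

  aw <- rowSums(aware_matrix(r))
  se_a <- stats::sd(aw) / sqrt(length(aw)) * fr$t / fr$e0
  expect_lt(abs(aware_network_size(r, fr) -
                  tr$c_true * tr$delta_true * tr$tau_true), 3 * se_a)

  # weighted (RDS-II style) variant runs; in this sparse-count world many
  # rows have a zero degree proxy and are dropped with a warning
  expect_warning(w <- hidden_network_size(r, fr, weighted = TRUE),
                 "zero-degree")
  expect_true(is.finite(w) && w > 0)
})

test_that("estimate_adjustment_factors wires c_H and aware through", {
  tr <- tiny_truth()
  r <- generate_rds_survey(tr, n_target = 200, seed = 8)
  c_G <- tr$c_true
  fa <- estimate_adjustment_factors(r, tr$frame, c_G)
  expect_equal(fa$delta, attr(fa, "c_H") / c_G)
  expect_equal(fa$tau, attr(fa, "aware") / attr(fa, "c_H"))
  expect_error(adjustment_factors(0, 0.5), "delta")
  expect_error(adjustment_factors(0.5, 1.2), "tau")
})
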