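test_that("strategy table matches the published test characteristics", {
  st <- screening_strategies()
  expect_length(st, 6)
  expect_equal(unname(st$s1$sensitivity_by_nyha),
               c(0.250, 0.853, 0.923, 1.000))
  expect_equal(unname(st$s4$sensitivity_by_nyha),
               c(0.500, 0.862, 0.897, 1.000))
  expect_equal(vapply(st, `[[`, 0, "specificity"),
               c(s0 = 1.000, s1 = 0.610, s2 = 0.617, s3 = 0.652,
                 s4 = 0.676, s5 = 1.000))
  expect_equal(vapply(st, `[[`, 0, "gp_screen_cost"),
               c(s0 = 0, s1 = 6.39, s2 = 15.17, s3 = 36.67, s4 = 61.77,
                 s5 = 0))
  expect_true(st$s5$direct_echo)
  expect_equal(sum(st$s0$sensitivity_by_nyha), 0)
})

test_that("screening moves undetected mass per sensitivity and prices events", {
  p <- default_parameters("men")
  d <- state_distribution(DIAB_NO_HF = 0.7, NYHA2_U = 0.2, NYHA2_D = 0.1)

  out <- apply_screening(d, screening_strategies(1), p)
  # brute-force arithmetic on the published inputs
  expect_equal(out$new_detections_by_nyha[["NYHA2"]], 0.2 * 0.853)
  expect_equal(out$echo_referrals, 0.2 * 0.853 + 0.7 * (1 - 0.610))
  expect_equal(out$screened_fraction, 0.9)
  expect_equal(out$event_cost,
               0.9 * 6.39 + (0.1706 + 0.273) * 169.38 + 0.1706 * 94.75)
  expect_equal(out$post_distribution[["NYHA2_U"]], 0.2 * (1 - 0.853))
  expect_equal(out$post_distribution[["NYHA2_D"]], 0.1 + 0.2 * 0.853)
  expect_equal(sum(out$post_distribution), 1, tolerance = 1e-12)
})

test_that("no screening is a free no-op; direct echo refers everyone", {
  p <- default_parameters("men")
  d <- state_distribution(DIAB_NO_HF = 0.8, NYHA2_U = 0.2)

  out0 <- apply_screening(d, screening_strategies(0), p)
  expect_identical(out0$post_distribution, d)
  expect_equal(out0$event_cost, 0)

  out5 <- apply_screening(d, screening_strategies(5), p)
  expect_equal(out5$post_distribution[["NYHA2_D"]], 0.2)
  expect_equal(out5$post_distribution[["NYHA2_U"]], 0)
  expect_equal(out5$echo_referrals, 1.0)   # everyone screened gets an echo
  expect_equal(out5$cost_screening, 0)     # no GP cost under direct echo
  expect_equal(out5$cost_diagnosis, 1.0 * 169.38 + 0.2 * 94.75)
})

test_that("diagnosis cost is the stress-test price times new detections", {
  p <- default_parameters("men")
  expect_equal(diagnosis_cost(0, p), 0)
  expect_equal(diagnosis_cost(1, p), 94.75)
  expect_equal(diagnosis_cost(0.1706, p), 0.1706 * 94.75, tolerance = 1e-9)
})

test_that("a perfect screen is idempotent after its first application", {
  p <- default_parameters("men")
  perfect <- hfscreen:::new_strategy(9L, "perfect", rep(1, 4), 0.9, 5)
  d <- state_distribution(DIAB_NO_HF = 0.6, NYHA2_U = 0.3, NYHA3_U = 0.1)
  once <- apply_screening(d, perfect, p)
  twice <- apply_screening(once$post_distribution, perfect, p)
  expect_equal(twice$post_distribution, once$post_distribution)
  expect_equal(sum(twice$new_detections_by_nyha), 0)
  # second pass: only GP cost and false-positive echoes remain
  expect_equal(twice$event_cost,
               5 * 0.6 + (1 - 0.9) * 0.6 * p$echo_cost)
})

test_that("event cost is monotone in sensitivity and specificity", {
  p <- default_parameters("men")
  d <- state_distribution(DIAB_NO_HF = 0.5, NYHA2_U = 0.3, NYHA3_U = 0.2)
  base <- hfscreen:::new_strategy(9L, "x", c(0.2, 0.5, 0.5, 1), 0.7, 10)
  cost0 <- apply_screening(d, base, p)$event_cost
  up_sens <- hfscreen:::new_strategy(9L, "x", c(0.2, 0.9, 0.5, 1), 0.7, 10)
  expect_gte(apply_screening(d, up_sens, p)$event_cost, cost0)
  up_spec <- hfscreen:::new_strategy(9L, "x", c(0.2, 0.5, 0.5, 1), 0.9, 10)
  expect_lte(apply_screening(d, up_spec, p)$event_cost, cost0)
})

test_that("detections are ordered: echo screen >= partial screens >= none", {
  p <- default_parameters("men")
  st <- screening_strategies()
  set.seed(7)
  for (i in 1:10) {
    w <- stats::runif(4)
    d <- state_distribution(DIAB_NO_HF = 0.5,
                            NYHA1_U = 0.5 * w[1] / sum(w),
                            NYHA2_U = 0.5 * w[2] / sum(w),
                            NYHA3_U = 0.5 * w[3] / sum(w),
                            NYHA4_U = 0.5 * w[4] / sum(w))
    det <- vapply(st, function(s)
      sum(apply_screening(d, s, p)$new_detections_by_nyha), 0)
    expect_equal(det[["s0"]], min(det))
    expect_equal(det[["s5"]], max(det))
    expect_true(all(det[c("s1", "s2", "s3", "s4")] >= det[["s0"]]))
    expect_true(all(det[c("s1", "s2", "s3", "s4")] <= det[["s5"]]))
  }
})
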