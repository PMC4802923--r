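test_that("annual-to-cycle conversion follows the constant-hazard form", {
  expect_equal(annual_to_cycle_prob(0, 0.25), 0)
  expect_equal(annual_to_cycle_prob(1, 0.25), 1)
  expect_equal(annual_to_cycle_prob(0.042, 0.25), 1 - 0.958^0.25)
  # composing four quarterly steps recovers the annual probability
  for (p in c(0.01, 0.042, 0.3, 0.9)) {
    q <- annual_to_cycle_prob(p, 0.25)
    expect_equal(1 - (1 - q)^4, p, tolerance = 1e-12)
  }
  expect_error(annual_to_cycle_prob(1.2, 0.25), "0, 1")
  expect_error(annual_to_cycle_prob(0.5, 0), "positive")
})

test_that("treatment mixing multiplier has the right limits and value", {
  p <- default_parameters("men")
  f <- p$hfpef_fraction; h <- p$hfref_treatment_hr

  # base case: multiplier (1-f)h + f
  expect_equal(treatment_hazard_multiplier(p, relative = FALSE),
               (1 - f) * h + f)
  # relative multiplier is 1 at rho = 0: published detected mortalities
  # already include the current treatment mix
  expect_equal(treatment_hazard_multiplier(p, relative = TRUE), 1)

  # rho = 1: full-effect limit, multiplier h uniformly
  p1 <- p; p1$hfpef_relative_effectiveness <- 1
  expect_equal(treatment_hazard_multiplier(p1, relative = FALSE), h)

  # h = 1: null treatment, base probability unchanged for any rho
  p2 <- p; p2$hfref_treatment_hr <- 1
  for (rho in c(0, 0.5, 1)) {
    p2$hfpef_relative_effectiveness <- rho
    expect_equal(treated_mortality(0.103, p2), 0.103)
  }

  # closed-form hazard-scale oracle
  m <- (1 - f) * h + f
  expect_equal(treated_mortality(0.103, p),
               1 - exp(log(1 - 0.103) * m))
  expect_equal(treated_mortality(0, p), 0)
  expect_equal(treated_mortality(1, p), 1)
})

test_that("NYHA cycle matrix is the cubed monthly matrix, age-adjusted", {
  p <- default_parameters("men")

  # identity is a fixed point at any age
  I4 <- diag(4); dimnames(I4) <- dimnames(p$nyha_monthly_transition)
  expect_equal(nyha_cycle_matrix(I4, 80, p), I4)

  # no age scale configured: plain third power
  M <- p$nyha_monthly_transition
  expect_equal(nyha_cycle_matrix(M, 90, p), M %*% M %*% M)

  # with an age scale: worsening scaled up, improvement down, rows re-sum
  # to 1; brute-force per-row oracle
  p$mortality_age_scale <- data.frame(age = c(60, 75),
                                      detected = c(1, 1.5),
                                      undetected = c(1, 1.5))
  out <- nyha_cycle_matrix(M, 80, p, "undetected")
  P3 <- M %*% M %*% M
  for (i in 1:4) {
    for (j in 1:4) {
      if (j > i) expect_equal(out[i, j], P3[i, j] * 1.5)
      if (j < i) expect_equal(out[i, j], P3[i, j] / 1.5)
    }
    expect_equal(sum(out[i, ]), 1, tolerance = 1e-12)
  }
  expect_error(nyha_cycle_matrix(matrix(0.5, 4, 4), 70, p),
               "row-stochastic")
})

test_that("transition matrix assembly: null dynamics, absorbing rows, cells", {
  # all mortality and incidence off, identity NYHA matrix -> identity
  p0 <- toy_params()
  P <- build_transition_matrix(p0, 60)
  expect_equal(unclass(P), diag(11), ignore_attr = TRUE)

  p <- default_parameters("men")
  P <- build_transition_matrix(p, 60)
  expect_equal(rowSums(P), setNames(rep(1, 11), health_states()),
               tolerance = 1e-12)
  expect_true(all(P >= 0 & P <= 1))

  # death rows are unit self-loops
  expect_equal(P["DEATH_HF", "DEATH_HF"], 1)
  expect_equal(P["DEATH_OTHER", "DEATH_OTHER"], 1)
  expect_equal(sum(P["DEATH_HF", ]), 1)

  # detected NYHA III death cell equals the cycle-converted published
  # mortality (base case: treatment factor 1)
  expect_equal(P["NYHA3_D", "DEATH_HF"], annual_to_cycle_prob(0.103, 0.25))

  # detection never happens inside the matrix, and undetected states are
  # reachable only from no-HF (into NYHA II) or other undetected states
  det_rows <- c("NYHA1_D", "NYHA2_D", "NYHA3_D", "NYHA4_D")
  und_cols <- c("NYHA1_U", "NYHA2_U", "NYHA3_U", "NYHA4_U")
  expect_equal(sum(P[det_rows, und_cols]), 0)
  expect_equal(sum(P["DIAB_NO_HF", setdiff(und_cols, "NYHA2_U")]), 0)
})

test_that("cohort iteration equals matrix powers for a fixed matrix", {
  p <- default_parameters("men")
  p$background_mortality_annual <- 0.02  # scalar: age-invariant matrix
  P <- build_transition_matrix(p, 60)
  tr <- run_cohort(screening_strategies(0), p, horizon = 10)
  v <- baseline_distribution(p)
  for (n in c(1, 5, 20, 40)) {
    Pn <- diag(11)
    for (k in seq_len(n)) Pn <- Pn %*% P
    expect_equal(unname(tr$occupancy[n + 1, ]),
                 as.vector(v %*% Pn), tolerance = 1e-10)
  }
})

test_that("two-state toy matches the geometric life-expectancy oracle", {
  for (q in c(0.5, 0.1, 0.01)) {
    p <- toy_params(background_annual = 1 - (1 - q)^4)  # cycle prob = q
    p$baseline_hf_distribution[] <- 0  # everyone starts alive, no HF
    tr <- run_cohort(screening_strategies(0), p, horizon = 700,
                     max_age = Inf)
    cycles_alive <- sum(rowSums(tr$occupancy[, 1:9]))
    expect_equal(cycles_alive, 1 / q, tolerance = 1e-6)
  }
})

test_that("cohort mass is conserved and death mass non-decreasing", {
  for (g in c("men", "women")) {
    p <- default_parameters(g)
    for (sid in c(0, 1, 5)) {
      tr <- run_cohort(screening_strategies(sid), p)
      expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
      dead <- rowSums(tr$occupancy[, c("DEATH_HF", "DEATH_OTHER")])
      expect_true(all(diff(dead) > -1e-12))
      alive <- rowSums(tr$occupancy[, 1:9])
      expect_lt(alive[nrow(tr$occupancy)], 1e-6)
    }
  }
})

test_that("an absorbed cohort accrues nothing", {
  p <- default_parameters("men")
  init <- state_distribution(DEATH_OTHER = 1)
  tr <- run_cohort(screening_strategies(1), p, init = init)
  res <- accrue(tr, p)
  expect_equal(res$life_years, 0)
  expect_equal(res$qalys, 0)
  expect_equal(res$total_cost, 0)
})

test_that("raising mortality shortens life; raising sensitivity detects more", {
  p <- default_parameters("men")
  base <- accrue(run_cohort(screening_strategies(0), p), p)

  worse <- p
  worse$hf_mortality_annual <- pmin(p$hf_mortality_annual * 1.5, 1)
  res_w <- accrue(run_cohort(screening_strategies(0), worse), worse)
  expect_lt(res_w$life_years, base$life_years)

  worse2 <- p
  worse2$background_mortality_annual$qx <-
    pmin(p$background_mortality_annual$qx * 1.5, 0.999)
  res_w2 <- accrue(run_cohort(screening_strategies(0), worse2), worse2)
  expect_lt(res_w2$life_years, base$life_years)

  det_occ <- function(strategy) {
    tr <- run_cohort(strategy, p)
    sum(tr$occupancy[, c("NYHA1_D", "NYHA2_D", "NYHA3_D", "NYHA4_D")])
  }
  st <- screening_strategies()
  expect_gt(det_occ(st$s1), det_occ(st$s0))
  expect_gt(det_occ(st$s5), det_occ(st$s1))
})

test_that("perfect detection dominates the trace cycle by cycle", {
  p <- default_parameters("men")
  tr0 <- run_cohort(screening_strategies(0), p)
  tr5 <- run_cohort(screening_strategies(5), p)
  n <- min(nrow(tr0$occupancy), nrow(tr5$occupancy))
  det_cols <- c("NYHA1_D", "NYHA2_D", "NYHA3_D", "NYHA4_D")
  d0 <- rowSums(tr0$occupancy[seq_len(n), det_cols])
  d5 <- rowSums(tr5$occupancy[seq_len(n), det_cols])
  expect_true(all(d5[-1] > d0[-1]))
})

test_that("with detection-symmetric inputs screening only adds cost", {
  p <- default_parameters("men")
  p$hf_mortality_annual[, "detected"] <- p$hf_mortality_annual[, "undetected"]
  p$annual_hf_cost[, "detected"] <- p$annual_hf_cost[, "undetected"]
  p$utilities[c("NYHA1_D", "NYHA2_D", "NYHA3_D", "NYHA4_D")] <-
    p$utilities[c("NYHA1_U", "NYHA2_U", "NYHA3_U", "NYHA4_U")]
  p$hfref_treatment_hr <- 1
  res <- lapply(screening_strategies(), function(s)
    accrue(run_cohort(s, p), p))
  qal <- vapply(res, `[[`, 0, "qalys")
  expect_equal(unname(qal), rep(qal[[1]], 6), tolerance = 1e-9)
  cst <- vapply(res, `[[`, 0, "total_cost")
  expect_true(all(cst[-1] >= cst[[1]]))
})

test_that("trace exports one row per cycle with occupancy and event costs", {
  p <- default_parameters("men")
  tr <- run_cohort(screening_strategies(1), p, horizon = 5)
  df <- as.data.frame(tr)
  expect_equal(nrow(df), nrow(tr$occupancy))
  expect_true(all(c("cycle", "age", health_states(),
                    "event_cost_screening", "event_cost_diagnosis")
                  %in% names(df)))
  # annual follow-up screens fall on every 4th cycle
  expect_true(all(df$event_cost_screening[df$cycle %% 4 != 0] == 0))
  expect_gt(df$event_cost_screening[df$cycle == 4], 0)
})
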