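test_that("sampling with only fixed specs returns the base unchanged", {
  p <- default_parameters("men")
  specs <- list(fixed_spec(target = c("params", "echo_cost")),
                fixed_spec(target = c("params", "utilities", "NYHA2_D")))
  q <- sample_parameters(p, specs, rng_seed = 1)
  expect_equal(unclass(q), unclass(p))
})

test_that("sampled gamma costs reproduce mean and variance", {
  sp <- gamma_spec_from_mean(169.38, target = c("params", "echo_cost"))
  p <- default_parameters("men")
  set.seed(5)
  draws <- vapply(1:1e5, function(i)
    hfscreen:::draw_spec(sp), 0)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 169.38), 3 * se)
  expect_lt(abs(var(draws) - 169.38) / 169.38, 0.05)
  # and a single targeted draw lands in the parameter set
  q <- sample_parameters(p, list(sp), rng_seed = 2)
  expect_false(q$echo_cost == p$echo_cost)
  expect_gt(q$echo_cost, 0)
})

test_that("Dirichlet prevalence draws stay on the rescaled simplex", {
  p <- default_parameters("men")
  specs <- psa_specs(p)
  diri <- Filter(function(s) s$family == "dirichlet", specs)
  expect_length(diri, 1)
  total <- sum(p$baseline_hf_distribution)
  set.seed(9)
  for (i in 1:200) {
    d <- hfscreen:::draw_spec(diri[[1]])
    expect_equal(sum(d), total, tolerance = 1e-9)
    expect_true(all(d >= 0))
  }
  # zero-concentration cells stay zero
  q <- sample_parameters(p, diri, rng_seed = 3)
  expect_equal(q$baseline_hf_distribution["NYHA4", "detected"], 0)
  expect_equal(q$baseline_hf_distribution["NYHA1", "undetected"], 0)
  expect_equal(sum(q$baseline_hf_distribution), total, tolerance = 1e-9)
})

test_that("spec targeting a non-existent field is a configuration error", {
  p <- default_parameters("men")
  sp <- gamma_spec_from_mean(10, target = c("params", "no_such_field", "x"))
  expect_error(sample_parameters(p, list(sp)), "configuration error")
})

test_that("PSA is seed-deterministic and n=1 all-fixed equals base case", {
  p <- default_parameters("men")
  st <- screening_strategies()

  fixed_only <- list(fixed_spec(target = c("params", "echo_cost")))
  cloud <- run_psa(st, p, specs = fixed_only, n = 1, seed = 7)
  base <- hfscreen:::evaluate_strategies(st, p)
  expect_equal(cloud$samples$qalys,
               unname(vapply(base, `[[`, 0, "qalys")))
  expect_equal(cloud$samples$cost,
               unname(vapply(base, `[[`, 0, "total_cost")))

  c1 <- run_psa(st, p, n = 8, seed = 123)
  c2 <- run_psa(st, p, n = 8, seed = 123)
  expect_identical(c1$samples, c2$samples)
  c3 <- run_psa(st, p, n = 8, seed = 124)
  expect_false(identical(c3$samples$qalys, c1$samples$qalys))
})

test_that("CEAC probabilities are normalized and match a brute-force count", {
  p <- default_parameters("men")
  st <- screening_strategies()
  cloud <- run_psa(st, p, n = 40, seed = 31)
  grid <- seq(0, 50000, by = 5000)
  cc <- ceac(cloud, grid)
  expect_equal(unname(rowSums(cc$prob_optimal)), rep(1, length(grid)),
               tolerance = 1e-9)

  # counting oracle: draw-wise argmax of NMB
  s <- cloud$samples
  for (w in c(0, 20000, 50000)) {
    counts <- setNames(numeric(6), paste0("s", 0:5))
    for (d in seq_len(cloud$n_samples)) {
      si <- s[s$draw == d, ]
      nmb <- w * si$qalys - si$cost
      win <- which(nmb == max(nmb))
      counts[paste0("s", si$strategy[win])] <-
        counts[paste0("s", si$strategy[win])] + 1 / length(win)
    }
    expect_equal(cc$prob_optimal[match(w, grid), ],
                 counts / cloud$n_samples, tolerance = 1e-12)
  }
})

test_that("a degenerate cloud gives 0/1 step acceptability curves", {
  p <- default_parameters("men")
  st <- screening_strategies()
  fixed_only <- list(fixed_spec(target = c("params", "echo_cost")))
  cloud <- run_psa(st, p, specs = fixed_only, n = 3, seed = 1)
  cc <- ceac(cloud, seq(0, 60000, by = 1000))
  expect_true(all(cc$prob_optimal %in% c(0, 1)))
  # cost-minimization limit at WTP 0: no screening wins
  expect_equal(unname(cc$prob_optimal[1, "s0"]), 1)
})

test_that("scenario grid embeds the base case and is null when HR is 1", {
  p <- default_parameters("men")
  st <- screening_strategies()
  sg <- scenario_grid(st, p, rho_values = c(0, 0.5, 1))

  base <- hfscreen:::evaluate_strategies(st, p)
  d10 <- base[[2]]$total_cost - base[[1]]$total_cost
  q10 <- base[[2]]$qalys - base[[1]]$qalys
  r0 <- sg[sg$rho == 0 & sg$comparison == "1 vs 0", ]
  expect_equal(r0$delta_cost, d10, tolerance = 1e-9)
  expect_equal(r0$delta_qalys, q10, tolerance = 1e-9)
  expect_equal(r0$icer, d10 / q10, tolerance = 1e-9)

  # null-treatment limit: all rows identical
  p1 <- p; p1$hfref_treatment_hr <- 1
  sg1 <- scenario_grid(st, p1, rho_values = c(0, 0.5, 1))
  for (cmp in unique(sg1$comparison)) {
    ic <- sg1$icer[sg1$comparison == cmp]
    expect_equal(ic, rep(ic[1], length(ic)), tolerance = 1e-9)
  }
})
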