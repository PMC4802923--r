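test_that("ICER is incremental cost over incremental effect", {
  expect_equal(icer(810, 0.132), 810 / 0.132)
  expect_equal(icer(0, 0.1), 0)
  expect_equal(icer(62, 0.002), 31000)
  expect_error(icer(100, 0), "undefined")
})

test_that("published per-strategy totals yield the published dominance", {
  res <- incremental_analysis(reference_totals_men())
  tab <- res$table
  expect_equal(sort(tab$strategy[tab$dominance == "strongly_dominated"]),
               c(2, 3, 4))
  expect_equal(res$frontier$strategy, c(0, 1, 5))
  expect_equal(res$frontier$icer, c(NA, 810 / 0.132, 62 / 0.002))
  expect_true(all(diff(res$frontier$icer[-1]) > 0))
})

test_that("single strategy: frontier of one, no ICER", {
  res <- incremental_analysis(data.frame(strategy = 1, effect = 2,
                                         cost = 100))
  expect_equal(nrow(res$frontier), 1)
  expect_true(is.na(res$frontier$icer))
  expect_equal(res$table$dominance, "nondominated")
})

test_that("middle strategy with too-steep ICER is extendedly dominated", {
  # middle point lies above the segment joining its neighbours
  res <- incremental_analysis(data.frame(
    strategy = c(1, 2, 3),
    effect = c(0, 1, 2),
    cost = c(0, 900, 1000)))
  expect_equal(res$table$dominance[res$table$strategy == 2],
               "extendedly_dominated")
  expect_equal(res$frontier$strategy, c(1, 3))
})

# independent brute-force oracle: the frontier is the lower convex hull of
# the (effect, cost) cloud from the cheapest point to the most effective
hull_frontier <- function(df) {
  df <- df[order(df$effect, df$cost), ]
  df <- df[!duplicated(df$effect), ]  # only the cheapest at each effect
  hull <- list()
  cross <- function(o, a, b)
    (a$effect - o$effect) * (b$cost - o$cost) -
    (a$cost - o$cost) * (b$effect - o$effect)
  for (i in seq_len(nrow(df))) {
    p <- df[i, ]
    while (length(hull) >= 2 &&
           cross(hull[[length(hull) - 1]], hull[[length(hull)]], p) <= 0)
      hull[[length(hull)]] <- NULL
    hull[[length(hull) + 1]] <- p
  }
  h <- do.call(rbind, hull)
  h$strategy[which.min(h$cost):nrow(h)]
}

test_that("frontier equals the convex-hull oracle on random instances", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    df <- data.frame(strategy = seq_len(n),
                     effect = round(stats::runif(n, 1, 10), 3),
                     cost = round(stats::runif(n, 100, 10000), 1))
    res <- incremental_analysis(df)
    expect_setequal(res$frontier$strategy, hull_frontier(df))
    # every NMB optimum over a WTP scan lies on the frontier
    opt <- unique(optimal_strategy(res, seq(0, 5e4, length.out = 501)))
    expect_true(all(opt %in% res$frontier$strategy))
    # every strategy classified exactly once
    expect_true(all(res$table$dominance %in%
      c("nondominated", "strongly_dominated", "extendedly_dominated")))
    expect_equal(nrow(res$table), n)
    # frontier ICERs strictly increasing
    ic <- res$frontier$icer[-1]
    if (length(ic) > 1) expect_true(all(diff(ic) > 0))
  }
})

test_that("scaling all costs scales ICERs and preserves dominance", {
  df <- reference_totals_men()
  res1 <- incremental_analysis(df)
  df2 <- df; df2$cost <- df2$cost * 3.5
  res2 <- incremental_analysis(df2)
  expect_equal(res2$table$dominance, res1$table$dominance)
  expect_equal(res2$frontier$icer, res1$frontier$icer * 3.5)
})

test_that("net monetary benefit reproduces the published optimum at 20k", {
  df <- reference_totals_men()
  nmb <- net_monetary_benefit(df$effect, 20000, cost = df$cost)
  expect_equal(nmb[df$strategy == 1], 20000 * 12.477 - 7605)
  expect_equal(nmb[df$strategy == 1], 241935)
  expect_equal(df$strategy[which.max(nmb)], 1)
  expect_equal(optimal_strategy(df, 20000), 1)
  # wtp 0: minus cost, so the cheapest wins
  expect_equal(net_monetary_benefit(df$effect, 0, cost = df$cost),
               -df$cost)
  expect_equal(optimal_strategy(df, 0), 0)
})

test_that("optimal strategy switches twice as willingness to pay rises", {
  df <- reference_totals_men()
  path <- optimal_strategy(df, seq(0, 60000, by = 100))
  expect_equal(unique(path), c(0, 1, 5))
  expect_equal(sum(diff(path) != 0), 2)
})

test_that("exact ties are kept and flagged", {
  df <- data.frame(strategy = 1:3, effect = c(1, 2, 2),
                   cost = c(10, 50, 50))
  res <- incremental_analysis(df)
  expect_setequal(res$ties, c("2", "3"))
  expect_equal(nrow(res$table), 3)
})
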