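#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost Incremental cost (EUR).
#' @param delta_effect Incremental effect (QALYs); must be non-zero.
#' @return Cost per QALY.
#' @export
#' @examples
#' icer(810, 0.132)
icer <- function(delta_cost, delta_effect) {
  if (any(delta_effect == 0))
    stop("undefined ICER: delta_effect is zero (handle via dominance, ",
         "not division)", call. = FALSE)
  delta_cost / delta_effect
}

#' Net monetary benefit
#'
#' `wtp * effect - cost`; the strategy maximizing it at a given
#' willingness to pay is optimal.
#'
#' @param result An `econ_result`, or a numeric effect (QALYs) if `cost`
#'   is supplied.
#' @param wtp Willingness to pay (EUR per QALY, >= 0).
#' @param cost Cost (EUR), only when `result` is numeric.
#' @return Net monetary benefit in EUR.
#' @export
#' @examples
#' net_monetary_benefit(12.477, 20000, cost = 7605)
net_monetary_benefit <- function(result, wtp, cost = NULL) {
  stopifnot(all(wtp >= 0))
  if (inherits(result, "econ_result"))
    return(wtp * result$qalys - result$total_cost)
  stopifnot(is.numeric(result), !is.null(cost))
  wtp * result - cost
}

#' Incremental cost-effectiveness analysis
#'
#' Ranks strategies by effect, classifies strong and extended dominance,
#' and computes the cost-effectiveness frontier with its incremental
#' cost-effectiveness ratios.
#'
#' Strategies are sorted by effect ascending (ties broken by lower cost).
#' A strategy is strongly dominated if another offers at least the effect
#' at lower cost, or more effect at no greater cost. Extended dominance is
#' removed iteratively: whenever the ICER of reaching a strategy exceeds
#' the ICER of the next step along the candidate frontier, that strategy is
#' excluded, until frontier ICERs are strictly increasing.
#'
#' @param results A list of `econ_result` objects, or a `data.frame` with
#'   columns `strategy`, `effect` (or `qalys`), `cost` (or `total_cost`).
#' @return A `cea_result`: list with `table` (per-strategy effect, cost,
#'   dominance classification), `frontier` (`data.frame` of frontier
#'   members with `icer` versus the previous member; `NA` for the
#'   reference), and `ties` (ids of exact-tie pairs, if any).
#' @export
#' @examples
#' tab <- data.frame(strategy = 0:5,
#'                   effect = c(12.345, 12.477, 12.477, 12.477, 12.477, 12.479),
#'                   cost = c(6795, 7605, 7611, 7625, 7642, 7667))
#' incremental_analysis(tab)
incremental_analysis <- function(results) {
  df <- cea_input_frame(results)
  if (nrow(df) < 1L) stop("need at least one strategy", call. = FALSE)
  if (any(!is.finite(df$effect)) || any(!is.finite(df$cost)))
    stop("effects and costs must be finite", call. = FALSE)

  df <- df[order(df$effect, df$cost), , drop = FALSE]
  n <- nrow(df)
  df$dominance <- "nondominated"

  # exact ties in both dimensions: kept, flagged
  ties <- character(0)
  if (n > 1L) {
    dup <- duplicated(df[, c("effect", "cost")]) |
      duplicated(df[, c("effect", "cost")], fromLast = TRUE)
    if (any(dup))
      ties <- as.character(df$strategy[dup])
  }

  for (i in seq_len(n)) {
    e <- df$effect[i]; c0 <- df$cost[i]
    strong <- (df$effect >= e & df$cost < c0) |
              (df$effect > e & df$cost <= c0)
    if (any(strong)) df$dominance[i] <- "strongly_dominated"
  }

  cand <- which(df$dominance == "nondominated")
  # drop exact-tie duplicates from frontier candidacy (identical points)
  if (length(cand) > 1L) {
    dupc <- duplicated(df[cand, c("effect", "cost")])
    cand <- cand[!dupc]
  }
  repeat {
    if (length(cand) <= 2L) break
    ic <- diff(df$cost[cand]) / diff(df$effect[cand])
    viol <- which(diff(ic) <= 0)
    if (!length(viol)) break
    drop_i <- cand[viol[1L] + 1L]
    df$dominance[drop_i] <- "extendedly_dominated"
    cand <- setdiff(cand, drop_i)
  }

  frontier <- df[cand, c("strategy", "effect", "cost"), drop = FALSE]
  frontier$icer <- c(NA_real_,
                     if (nrow(frontier) > 1L)
                       diff(frontier$cost) / diff(frontier$effect))
  rownames(df) <- rownames(frontier) <- NULL

  structure(list(table = df, frontier = frontier, ties = ties),
            class = "cea_result")
}

cea_input_frame <- function(results) {
  if (is.data.frame(results)) {
    eff <- results$effect %||% results$qalys
    cst <- results$cost %||% results$total_cost
    if (is.null(eff) || is.null(cst))
      stop("data frame needs effect/qalys and cost/total_cost columns",
           call. = FALSE)
    return(data.frame(strategy = results$strategy %||% seq_len(nrow(results)),
                      effect = eff, cost = cst))
  }
  if (inherits(results, "econ_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(strategy = r$strategy_id, effect = r$qalys,
               cost = r$total_cost)))
}

#' Optimal strategy at a willingness to pay
#'
#' @param cea A `cea_result`, or anything [incremental_analysis()] accepts.
#' @param wtp Vector of willingness-to-pay values (EUR per QALY).
#' @return Strategy id with the highest net monetary benefit at each
#'   `wtp` (the cheaper strategy on exact ties).
#' @export
optimal_strategy <- function(cea, wtp) {
  tab <- if (inherits(cea, "cea_result")) cea$table else
    cea_input_frame(cea)
  vapply(wtp, function(w) {
    nmb <- w * tab$effect - tab$cost
    tab$strategy[which.max(nmb)]
  }, tab$strategy[1L])
}

#' @export
print.cea_result <- function(x, digits = 3, ...) {
  cat("Incremental cost-effectiveness analysis\n")
  tab <- x$table
  tab$effect <- round(tab$effect, digits)
  tab$cost <- round(tab$cost)
  f <- x$frontier
  tab$icer <- NA_character_
  for (i in seq_len(nrow(f))) {
    j <- which(tab$strategy == f$strategy[i])
    tab$icer[j] <- if (is.na(f$icer[i])) "(reference)"
                   else format(round(f$icer[i]), big.mark = ",")
  }
  tab$icer[tab$dominance != "nondominated"] <- "dominated"
  print(tab, row.names = FALSE)
  if (length(x$ties))
    cat("exact ties:", paste(x$ties, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cea_result <- function(object, ...) {
  n_dom <- sum(object$table$dominance != "nondominated")
  cat(nrow(object$table), "strategies;", n_dom, "dominated;",
      nrow(object$frontier), "on the frontier\n")
  invisible(object)
}

#' Plot the cost-effectiveness plane and frontier
#'
#' @param x A `cea_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cea_result <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$effect, tab$cost, pch = 19,
                 col = ifelse(tab$dominance == "nondominated",
                              "steelblue", "grey60"),
                 xlab = "QALYs", ylab = "Cost (EUR)", ...)
  graphics::lines(x$frontier$effect, x$frontier$cost, col = "steelblue")
  graphics::text(tab$effect, tab$cost, labels = tab$strategy, pos = 3,
                 cex = 0.8)
  invisible(x)
}
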