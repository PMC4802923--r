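#' Discount factor
#'
#' `(1 + rate)^(-time)`, with time measured at cycle start.
#'
#' @param rate Annual discount rate (>= 0).
#' @param time Time in years (>= 0).
#' @return Dimensionless factor in (0, 1].
#' @export
#' @examples
#' discount_factor(0.04, 1)
discount_factor <- function(rate, time) {
  stopifnot(rate >= 0, all(time >= 0))
  (1 + rate)^(-time)
}

#' Heart-failure state cost per cycle
#'
#' Only the increase in costs attributable to heart failure is modelled:
#' the diabetes-without-heart-failure state and the death states cost
#' nothing, NYHA states cost their annual heart-failure cost times the
#' cycle length. The annual costs come from the published table by default;
#' see [derive_hf_costs()] for the derived path that builds them from a
#' base hospitalization cost, per-NYHA hospitalization hazard ratios and
#' detected-only GP/medication components.
#'
#' @param state A health-state label, or vector of labels.
#' @param params An `hf_params` object.
#' @return Cost in EUR per cycle for each state.
#' @export
#' @examples
#' state_cost_per_cycle("NYHA4_U", default_parameters("men"))
state_cost_per_cycle <- function(state, params) {
  cost_vec <- state_cost_vector(params)
  i <- match(state, STATE_LABELS)
  if (anyNA(i)) stop("unknown health state(s): ",
                     paste(state[is.na(i)], collapse = ", "), call. = FALSE)
  unname(cost_vec[i])
}

state_cost_vector <- function(params) {
  cst <- stats::setNames(numeric(11L), STATE_LABELS)
  cst[I_D] <- params$annual_hf_cost[, "detected"] * params$cycle_length
  cst[I_U] <- params$annual_hf_cost[, "undetected"] * params$cycle_length
  cst
}

#' Derive annual heart-failure costs from hospitalization hazard ratios
#'
#' The alternative to the published cost table: annual costs for all
#' heart-failure patients (hospitalization and nursing care) are a base
#' cost weighted over NYHA classes by hospitalization hazard ratios and
#' adjusted between detection statuses by the ratio of their mortality
#' risks; detected patients additionally accrue an extra GP consultation
#' and medication costs (prescription proportions times annual drug
#' costs).
#'
#' @param params An `hf_params` object supplying
#'   `hosp_hazard_ratio_by_nyha`, `hf_mortality_annual`,
#'   `medication_prescription` and `drug_annual_cost`.
#' @param base_cost Annual hospitalization/nursing cost (EUR) of a NYHA I
#'   undetected patient.
#' @param gp_annual_cost Annual extra GP consultation cost (EUR) for
#'   detected patients.
#' @return 4 x 2 matrix shaped like `params$annual_hf_cost`.
#' @export
derive_hf_costs <- function(params, base_cost, gp_annual_cost = 0) {
  hr <- params$hosp_hazard_ratio_by_nyha
  if (is.null(hr) || anyNA(hr))
    stop("configuration error: hosp_hazard_ratio_by_nyha required for the ",
         "derived cost path", call. = FALSE)
  dc <- params$drug_annual_cost
  if (is.null(dc) || anyNA(dc))
    stop("configuration error: drug_annual_cost required for the derived ",
         "cost path", call. = FALSE)
  mort_ratio <- params$hf_mortality_annual[, "detected"] /
    params$hf_mortality_annual[, "undetected"]
  undet <- base_cost * hr / hr[1L]
  det <- undet * mort_ratio
  med <- sum(params$medication_prescription[, "detected"] *
               dc[rownames(params$medication_prescription)])
  nyha_matrix(detected = det + gp_annual_cost + med, undetected = undet)
}

#' Accrue discounted outcomes over a cohort trace
#'
#' Per cycle, adds occupancy-weighted utility times cycle length
#' (discounted at the effects rate) to QALYs, and occupancy-weighted state
#' costs plus screening/diagnosis event costs (discounted at the costs
#' rate) to total cost. Life-years come from the surviving occupancy.
#' Discounting is applied at cycle start by default; `half_cycle = TRUE`
#' averages adjacent cycle occupancies before accrual.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param params The `hf_params` object the trace was produced with.
#' @param half_cycle Apply a half-cycle correction (default `FALSE`).
#' @return An `econ_result`: list with `strategy_id`, `life_years`
#'   (undiscounted), `life_years_disc`, `qalys` (discounted at the effects
#'   rate), `qalys_undisc`, `total_cost` (discounted at the costs rate) and
#'   `breakdown` (screening, diagnosis, hf_state, medication).
#' @export
#' @examples
#' p <- default_parameters("men")
#' accrue(run_cohort(screening_strategies(0), p), p)
accrue <- function(trace, params, half_cycle = FALSE) {
  occ <- trace$occupancy
  if (ncol(occ) != 11L)
    stop("dimension error: trace occupancy must have 11 state columns",
         call. = FALSE)
  cl <- trace$cycle_length
  n <- nrow(occ)
  if (half_cycle && n > 1L) {
    occ <- (occ[-n, , drop = FALSE] + occ[-1L, , drop = FALSE]) / 2
    occ <- rbind(occ, trace$occupancy[n, ] / 2)
  }
  t_vec <- (seq_len(n) - 1L) * cl
  de <- discount_factor(params$discount_rate_effects, t_vec)
  dc <- discount_factor(params$discount_rate_costs, t_vec)

  alive <- rowSums(occ[, I_ALIVE, drop = FALSE])
  uw <- as.numeric(occ %*% params$utilities)
  cw <- as.numeric(occ %*% state_cost_vector(params))

  cost_screen <- sum(trace$event_cost_screening * dc)
  cost_dx <- sum(trace$event_cost_diagnosis * dc)
  cost_state <- sum(cw * dc)

  structure(list(
    strategy_id = trace$strategy_id,
    strategy_name = trace$strategy_name,
    life_years = sum(alive) * cl,
    life_years_disc = sum(alive * de) * cl,
    qalys = sum(uw * de) * cl,
    qalys_undisc = sum(uw) * cl,
    total_cost = cost_screen + cost_dx + cost_state,
    breakdown = c(screening = cost_screen, diagnosis = cost_dx,
                  hf_state = cost_state, medication = 0)),
    class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat("Strategy ", x$strategy_id, " (", x$strategy_name, ")\n", sep = "")
  cat(sprintf("  life expectancy  %8.3f y (discounted %.3f)\n",
              x$life_years, x$life_years_disc))
  cat(sprintf("  QALYs            %8.3f (undiscounted %.3f)\n",
              x$qalys, x$qalys_undisc))
  cat(sprintf("  total cost       %8.0f EUR  (screening %.0f, diagnosis %.0f, HF state %.0f)\n",
              x$total_cost, x$breakdown[["screening"]],
              x$breakdown[["diagnosis"]], x$breakdown[["hf_state"]]))
  invisible(x)
}

#' @export
as.data.frame.econ_result <- function(x, ...) {
  data.frame(strategy = x$strategy_id, name = x$strategy_name,
             life_years = x$life_years,
             life_years_disc = x$life_years_disc,
             qalys = x$qalys, qalys_undisc = x$qalys_undisc,
             total_cost = x$total_cost,
             cost_screening = x$breakdown[["screening"]],
             cost_diagnosis = x$breakdown[["diagnosis"]],
             cost_hf_state = x$breakdown[["hf_state"]])
}
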