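# Shared fixtures built in code.

# A stripped-down parameter set for analytic oracles: scalar background
# mortality, no incidence, no NYHA movement, zero costs, utility 1
# everywhere alive. Individual pieces are switched back on per test.
toy_params <- function(background_annual = 0,
                       hf_mortality = 0,
                       incidence_per_100k = 0,
                       utilities1 = TRUE) {
  p <- default_parameters("men")
  p$background_mortality_annual <- background_annual
  p$hf_mortality_annual[] <- hf_mortality
  p$hf_incidence_per_100k <- incidence_per_100k
  p$nyha_monthly_transition <- diag(4)
  dimnames(p$nyha_monthly_transition) <-
    dimnames(default_parameters("men")$nyha_monthly_transition)
  p$annual_hf_cost[] <- 0
  p$echo_cost <- 0
  p$ecg_stress_cost <- 0
  p$gp_followup_cost <- 0
  if (utilities1) {
    p$utilities[] <- 1
    p$utilities[c("DEATH_HF", "DEATH_OTHER")] <- 0
  }
  p$discount_rate_costs <- 0
  p$discount_rate_effects <- 0
  validate_parameters(p)
}

# published per-strategy totals for men
reference_totals_men <- function() reference_outcomes("men")

# build a cohort_trace by hand (for accrual oracles)
manual_trace <- function(occ, cycle_length = 0.25,
                         ev_screen = numeric(nrow(occ)),
                         ev_dx = numeric(nrow(occ))) {
  structure(list(occupancy = occ,
                 ages = 60 + (seq_len(nrow(occ)) - 1L) * cycle_length,
                 event_cost_screening = ev_screen,
                 event_cost_diagnosis = ev_dx,
                 cycle_length = cycle_length,
                 strategy_id = 0L, strategy_name = "manual"),
            class = "cohort_trace")
}
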