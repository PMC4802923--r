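#' Convert an annual probability to a per-cycle probability
#'
#' Constant-hazard conversion: `1 - (1 - p)^t` for a cycle of `t` years.
#'
#' @param p_annual Annual probability in \[0, 1\].
#' @param cycle_years Cycle length in years (> 0).
#' @return Per-cycle probability.
#' @export
#' @examples
#' annual_to_cycle_prob(0.042, 0.25)
annual_to_cycle_prob <- function(p_annual, cycle_years) {
  if (any(p_annual < 0) || any(p_annual > 1))
    stop("p_annual must lie in [0, 1]", call. = FALSE)
  if (cycle_years <= 0)
    stop("cycle_years must be positive", call. = FALSE)
  1 - (1 - p_annual)^cycle_years
}

#' Mortality under treatment, mixing HFpEF and HFrEF effects
#'
#' Detected patients are treated according to guidelines. Treatment reduces
#' the mortality hazard by the factor `h = hfref_treatment_hr` in the HFrEF
#' fraction `1 - f` of cases; in the HFpEF fraction `f` the hazard factor
#' is `1 - rho * (1 - h)`, where `rho = hfpef_relative_effectiveness`
#' interpolates between no HFpEF effect (`rho = 0`, the base case) and full
#' HFrEF-equivalent effect (`rho = 1`). The combined hazard multiplier is
#'
#'   `m(rho) = (1 - f) * h + f * (1 - rho * (1 - h))`
#'
#' applied on the hazard scale: the annual probability is converted to a
#' hazard, multiplied, and converted back.
#'
#' @param base_annual Annual probability of death from heart failure for an
#'   untreated patient.
#' @param params An `hf_params` object.
#' @return Annual probability under treatment.
#' @seealso [treatment_hazard_multiplier()] for the multiplier itself; the
#'   cohort engine applies the multiplier relative to its base-case value,
#'   because the published detected-state mortalities already include the
#'   current (`rho = 0`) treatment mix.
#' @export
#' @examples
#' treated_mortality(0.103, default_parameters("men"))
treated_mortality <- function(base_annual, params) {
  if (any(base_annual < 0) || any(base_annual > 1))
    stop("base_annual must lie in [0, 1]", call. = FALSE)
  m <- treatment_hazard_multiplier(params, relative = FALSE)
  haz <- -log(1 - pmin(base_annual, 1 - 1e-15))
  out <- 1 - exp(-haz * m)
  out[base_annual == 1] <- 1
  out
}

#' Treatment hazard multiplier
#'
#' @param params An `hf_params` object.
#' @param relative If `TRUE` (what the cohort engine uses) the multiplier
#'   is normalized by its value at `rho = 0`, so that the base case leaves
#'   the published detected-state mortalities untouched and `rho > 0`
#'   expresses the additional benefit of extending treatment effectiveness
#'   to the HFpEF share.
#' @return Dimensionless hazard multiplier.
#' @export
treatment_hazard_multiplier <- function(params, relative = TRUE) {
  f <- params$hfpef_fraction
  h <- params$hfref_treatment_hr
  rho <- params$hfpef_relative_effectiveness
  m <- function(r) (1 - f) * h + f * (1 - r * (1 - h))
  if (relative) m(rho) / m(0) else m(rho)
}

#' Three-month NYHA transition matrix, age-adjusted
#'
#' The third matrix power of the 1-month NYHA-to-NYHA matrix (whose source
#' population is 65-year-old treated heart-failure patients). For ages
#' other than 65, each worsening (above-diagonal) probability is multiplied
#' by the ratio of the age-scale multiplier at the current age to its value
#' at 65 for the given detection status, improvement (below-diagonal)
#' probabilities are scaled down by the same ratio, and the diagonal
#' absorbs the remainder. If scaling pushes a row's off-diagonal mass above
#' 1, the row is clipped and renormalized with a warning.
#'
#' @param monthly 4 x 4 row-stochastic 1-month matrix.
#' @param age Age in years at cycle start.
#' @param params An `hf_params` object (supplies `mortality_age_scale`).
#' @param detection `"detected"` or `"undetected"`.
#' @return 4 x 4 row-stochastic 3-month matrix.
#' @export
nyha_cycle_matrix <- function(monthly, age, params,
                              detection = c("undetected", "detected")) {
  detection <- match.arg(detection)
  stopifnot(is.matrix(monthly), all(dim(monthly) == c(4L, 4L)))
  if (any(abs(rowSums(monthly) - 1) > 1e-9))
    stop("monthly matrix must be row-stochastic", call. = FALSE)
  P <- monthly %*% monthly %*% monthly
  ratio <- age_scale_ratio(params, age, detection)
  if (ratio == 1) return(P)

  up <- upper.tri(P)
  lo <- lower.tri(P)
  Q <- P
  Q[up] <- P[up] * ratio
  Q[lo] <- P[lo] / ratio
  diag(Q) <- 0
  off <- rowSums(Q)
  over <- off > 1
  if (any(over)) {
    warning("age scaling pushed off-diagonal mass above 1 in row(s) ",
            paste(which(over), collapse = ", "), "; row(s) renormalized")
    Q[over, ] <- Q[over, , drop = FALSE] / off[over]
    off[over] <- 1
  }
  diag(Q) <- 1 - off
  Q
}

# multiplier at `age` relative to the reference age 65; identity when no
# age scale is configured
age_scale_ratio <- function(params, age, detection) {
  ms <- params$mortality_age_scale
  if (is.null(ms)) return(1)
  lookup <- function(a) {
    i <- findInterval(a, ms$age)
    if (i < 1L) i <- 1L
    ms[[detection]][i]
  }
  lookup(age) / lookup(65)
}

# background (other-cause) annual mortality at a given age
background_mortality_at <- function(params, age) {
  bm <- params$background_mortality_annual
  if (is.data.frame(bm)) {
    i <- findInterval(age, bm$age)
    if (i < 1L) i <- 1L
    if (i > nrow(bm)) i <- nrow(bm)
    bm$qx[i]
  } else bm
}

#' Build the per-cycle transition matrix
#'
#' Assembles the 11 x 11 one-cycle transition matrix at a given age.
#' Within a cycle, events compose in the order death, incidence, NYHA
#' movement: heart-failure death (cycle-converted annual mortality by NYHA
#' class and detection status, detected states additionally scaled by the
#' relative treatment multiplier when `hfpef_relative_effectiveness > 0`),
#' then other-cause death among heart-failure survivors, then — conditional
#' on surviving both — new-onset heart failure (no-HF state only, entering
#' NYHA II undetected) or NYHA movement within the current detection
#' stratum. Death states are absorbing; detection status never changes
#' inside the matrix (screening events handle detection).
#'
#' @param params An `hf_params` object.
#' @param age Age in years at cycle start.
#' @return 11 x 11 row-stochastic matrix with `age` attribute.
#' @export
#' @examples
#' P <- build_transition_matrix(default_parameters("men"), 60)
#' rowSums(P)
build_transition_matrix <- function(params, age) {
  cl <- params$cycle_length
  p_bg <- annual_to_cycle_prob(background_mortality_at(params, age), cl)
  p_inc <- annual_to_cycle_prob(
    params$hf_incidence_per_100k / 1e5 * params$diabetes_incidence_multiplier,
    cl)

  tx <- treatment_hazard_multiplier(params, relative = TRUE)
  haz_scale <- function(p_annual, mult) 1 - (1 - p_annual)^(cl * mult)
  scale_det <- age_scale_ratio(params, age, "detected") * tx
  scale_und <- age_scale_ratio(params, age, "undetected")
  p_hf_det <- haz_scale(params$hf_mortality_annual[, "detected"], scale_det)
  p_hf_und <- haz_scale(params$hf_mortality_annual[, "undetected"], scale_und)

  M <- params$nyha_monthly_transition
  P3_det <- nyha_cycle_matrix(M, age, params, "detected")
  P3_und <- nyha_cycle_matrix(M, age, params, "undetected")

  P <- matrix(0, 11L, 11L, dimnames = list(STATE_LABELS, STATE_LABELS))

  # diabetes without HF: other-cause death, else incident HF (NYHA II
  # undetected), else stay
  P[I_NOHF, I_DOTH] <- p_bg
  P[I_NOHF, I_U[2L]] <- (1 - p_bg) * p_inc
  P[I_NOHF, I_NOHF] <- (1 - p_bg) * (1 - p_inc)

  for (k in 1:4) {
    # undetected NYHA k
    i <- I_U[k]
    P[i, I_DHF] <- p_hf_und[k]
    P[i, I_DOTH] <- (1 - p_hf_und[k]) * p_bg
    P[i, I_U] <- (1 - p_hf_und[k]) * (1 - p_bg) * P3_und[k, ]
    # detected NYHA k
    i <- I_D[k]
    P[i, I_DHF] <- p_hf_det[k]
    P[i, I_DOTH] <- (1 - p_hf_det[k]) * p_bg
    P[i, I_D] <- (1 - p_hf_det[k]) * (1 - p_bg) * P3_det[k, ]
  }
  P[I_DHF, I_DHF] <- 1
  P[I_DOTH, I_DOTH] <- 1

  if (any(P < -1e-12) || any(P > 1 + 1e-12))
    stop("assembly error: probability outside [0, 1] in row(s) ",
         paste(STATE_LABELS[unique(which(P < -1e-12 | P > 1 + 1e-12,
                                         arr.ind = TRUE)[, 1L])],
               collapse = ", "), call. = FALSE)
  structure(P, age = age)
}

# Transition matrices for a vector of cycle-start ages. When the parameter
# set has no age-dependent inputs (scalar background mortality and no age
# scale) a single matrix is built and reused.
transition_matrices <- function(params, ages) {
  age_varying <- is.data.frame(params$background_mortality_annual) ||
    !is.null(params$mortality_age_scale)
  if (!age_varying) {
    P <- build_transition_matrix(params, ages[1L])
    return(rep(list(P), length(ages)))
  }
  # matrices change only when the integer age changes (life tables and age
  # scales are indexed by whole years)
  key <- floor(ages + 1e-9)
  uniq <- unique(key)
  built <- lapply(uniq, function(a) build_transition_matrix(params, a))
  built[match(key, uniq)]
}

#' Baseline state distribution
#'
#' The cohort starts with the baseline heart-failure prevalence spread over
#' the NYHA states and the remainder in diabetes without heart failure. By
#' default all prevalent heart failure starts undetected (detected and
#' undetected prevalence columns are pooled into the undetected states);
#' set `params$baseline_detected = TRUE` to start the published detected
#' column in detected states instead.
#'
#' @param params An `hf_params` object.
#' @return Named state distribution of length 11.
#' @export
baseline_distribution <- function(params) {
  b <- params$baseline_hf_distribution
  d <- stats::setNames(numeric(11L), STATE_LABELS)
  if (isTRUE(params$baseline_detected)) {
    d[I_D] <- b[, "detected"]
    d[I_U] <- b[, "undetected"]
  } else {
    d[I_U] <- b[, "detected"] + b[, "undetected"]
  }
  d[I_NOHF] <- 1 - sum(d)
  if (d[I_NOHF] < -1e-9)
    stop("baseline_hf_distribution sums to more than 1", call. = FALSE)
  d[I_NOHF] <- max(d[I_NOHF], 0)
  d
}

#' Run the cohort simulation
#'
#' Iterates the cohort from the starting distribution over 3-month cycles
#' until (lifetime horizon) the surviving mass drops below `1e-8` or the
#' cohort reaches `max_age`. The initial screening event of the strategy is
#' applied at cycle 0; strategies 1-5 additionally apply an annual
#' EMR/symptoms follow-up screen every fourth cycle. Occupancy is recorded
#' at each cycle start, after any screening event of that cycle.
#'
#' @param strategy An `hf_strategy` (see [screening_strategies()]).
#' @param params An `hf_params` object.
#' @param horizon `"lifetime"` or a horizon in years.
#' @param max_age Age at which the simulation stops regardless of surviving
#'   mass (default 110).
#' @param matrices Optional pre-built list of per-cycle transition matrices
#'   (from the internal cache used by the probabilistic sensitivity
#'   analysis); normally left `NULL`.
#' @param init Optional starting distribution overriding
#'   [baseline_distribution()].
#' @return A `cohort_trace`: list with `occupancy` (cycles x 11 matrix),
#'   `ages`, `event_cost_screening`, `event_cost_diagnosis` (EUR per
#'   cohort member per cycle), `cycle_length`, `strategy_id`.
#' @export
#' @examples
#' tr <- run_cohort(screening_strategies(0), default_parameters("men"))
#' utils::head(as.data.frame(tr))
run_cohort <- function(strategy, params, horizon = "lifetime",
                       max_age = 110, matrices = NULL, init = NULL) {
  stopifnot(inherits(strategy, "hf_strategy"))
  cl <- params$cycle_length
  n_max <- if (identical(horizon, "lifetime")) {
    if (is.finite(max_age)) ceiling((max_age - params$start_age) / cl) + 1L
    else 400000L
  } else {
    stopifnot(is.numeric(horizon), horizon > 0)
    ceiling(horizon / cl) + 1L
  }
  ages <- params$start_age + (seq_len(n_max) - 1L) * cl
  if (is.null(matrices)) matrices <- transition_matrices(params, ages)

  occ <- matrix(0, n_max, 11L, dimnames = list(NULL, STATE_LABELS))
  ev_scr <- numeric(n_max)
  ev_dx <- numeric(n_max)

  v <- if (is.null(init)) baseline_distribution(params) else init
  n_used <- 0L
  for (t in seq_len(n_max)) {
    cyc <- t - 1L
    if (cyc == 0L) {
      out <- apply_screening(v, strategy, params, is_initial = TRUE)
      v <- out$post_distribution
      ev_scr[t] <- out$cost_screening
      ev_dx[t] <- out$cost_diagnosis
    } else if (strategy$id != 0L && cyc %% 4L == 0L) {
      out <- apply_screening(v, strategy, params, is_initial = FALSE)
      v <- out$post_distribution
      ev_scr[t] <- out$cost_screening
      ev_dx[t] <- out$cost_diagnosis
    }
    occ[t, ] <- v
    n_used <- t
    alive <- sum(v[I_ALIVE])
    if (identical(horizon, "lifetime") && alive < 1e-8) break
    if (t < n_max) v <- as.numeric(v %*% matrices[[t]])
    names(v) <- STATE_LABELS
  }

  structure(list(
    occupancy = occ[seq_len(n_used), , drop = FALSE],
    ages = ages[seq_len(n_used)],
    event_cost_screening = ev_scr[seq_len(n_used)],
    event_cost_diagnosis = ev_dx[seq_len(n_used)],
    cycle_length = cl,
    strategy_id = strategy$id,
    strategy_name = strategy$name),
    class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x$occupancy)
  alive <- rowSums(x$occupancy[, I_ALIVE, drop = FALSE])
  cat("Cohort trace, strategy ", x$strategy_id, " (", x$strategy_name,
      ")\n", sep = "")
  cat("  ", n, " cycles of ", x$cycle_length, " years; ages ",
      x$ages[1L], "-", x$ages[n], "\n", sep = "")
  cat("  surviving mass at last cycle: ", signif(alive[n], 4), "\n",
      sep = "")
  cat("  undiscounted life-years: ",
      round(sum(alive) * x$cycle_length, 3), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(cycle = seq_len(nrow(x$occupancy)) - 1L,
             age = x$ages,
             x$occupancy,
             event_cost_screening = x$event_cost_screening,
             event_cost_diagnosis = x$event_cost_diagnosis,
             check.names = FALSE)
}
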