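# Seeded generators for the model inputs that are not published: the
# 1-month NYHA transition matrix, age-indexed life tables, and
# patient-level utility/cost samples emulating the screening cohort's
# summary statistics. The generator defaults double as the shipped model
# defaults; the NYHA progression and life-table slope values were fixed
# once by calibrating no-screening and EMR/symptoms life expectancy
# against the published totals (see calibrate_nyha_matrix).

#' Configuration of the synthetic-input generators
#'
#' @param seed Integer seed for stochastic generators.
#' @param n_patients Cohort size (default 581).
#' @param hf_prevalence Screen-detected heart-failure prevalence (0.277).
#' @param hfpef_share Share of heart failure that is HFpEF (0.826).
#' @param nyha_mix Proportions of heart-failure cases over NYHA I-IV
#'   (default: the baseline prevalence proportions).
#' @param progression_intensity Per-month probability scale of worsening by
#'   one NYHA class.
#' @param improvement_intensity Per-month probability scale of improving by
#'   one NYHA class.
#' @param step_decay Geometric decay of multi-class jumps relative to
#'   one-class moves.
#' @param jitter_sd Relative log-normal jitter applied to off-diagonal
#'   entries of generated NYHA matrices (0 = none, fully deterministic).
#' @param gompertz_params Named vector `c(rate, shape)` of the life-table
#'   hazard model: the annual other-cause death hazard at age `a` is the
#'   anchored age-60 hazard times `exp(rate * (a - 60)^shape)`.
#' @param utility_sd Patient-level standard deviation of EQ5D utility
#'   draws.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_patients = 581L,
                             hf_prevalence = 0.277,
                             hfpef_share = 0.826,
                             nyha_mix = NULL,
                             progression_intensity = 0.207,
                             improvement_intensity = 0.323,
                             step_decay = 0.25,
                             jitter_sd = 0,
                             gompertz_params = c(rate = 0.118, shape = 1),
                             utility_sd = 0.15) {
  if (is.null(nyha_mix)) {
    prev <- c(0.007, 0.290, 0.078, 0.000)
    nyha_mix <- prev / sum(prev)
  }
  stopifnot(n_patients >= 1L, hf_prevalence >= 0, hf_prevalence <= 1,
            hfpef_share >= 0, hfpef_share <= 1,
            abs(sum(nyha_mix) - 1) < 1e-9, all(nyha_mix >= 0),
            progression_intensity >= 0, improvement_intensity >= 0,
            step_decay >= 0, step_decay <= 1, jitter_sd >= 0,
            utility_sd > 0)
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 hf_prevalence = hf_prevalence, hfpef_share = hfpef_share,
                 nyha_mix = stats::setNames(nyha_mix, NYHA_LABELS),
                 progression_intensity = progression_intensity,
                 improvement_intensity = improvement_intensity,
                 step_decay = step_decay, jitter_sd = jitter_sd,
                 gompertz_params = gompertz_params,
                 utility_sd = utility_sd),
            class = "synthetic_config")
}

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a 1-month NYHA transition matrix
#'
#' Row-stochastic 4 x 4 matrix with worsening mass above the diagonal
#' (one-class moves at the progression intensity, multi-class jumps
#' geometrically damped), improvement mass below it (including NYHA IV
#' back to NYHA I), and the diagonal as remainder. With `jitter_sd > 0`
#' off-diagonal entries are perturbed by seeded log-normal noise.
#'
#' @param config A [synthetic_config()].
#' @return 4 x 4 matrix with NYHA dimnames.
#' @export
#' @examples
#' rowSums(generate_nyha_matrix(synthetic_config()))
generate_nyha_matrix <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  M <- matrix(0, 4L, 4L, dimnames = list(NYHA_LABELS, NYHA_LABELS))
  for (i in 1:4) for (j in 1:4) {
    if (j > i) M[i, j] <- config$progression_intensity *
        config$step_decay^(j - i - 1L)
    if (j < i) M[i, j] <- config$improvement_intensity *
        config$step_decay^(i - j - 1L)
  }
  if (config$jitter_sd > 0) {
    noise <- with_seed(config$seed,
                       matrix(stats::rlnorm(16L, 0, config$jitter_sd), 4L))
    M <- M * noise
  }
  off <- rowSums(M)
  if (any(off > 1))
    stop("generation error: intensities give off-diagonal row mass > 1",
         call. = FALSE)
  diag(M) <- 1 - off
  M
}

#' The shipped default 1-month NYHA transition matrix
#'
#' The generator output under the default [synthetic_config()], whose
#' progression and improvement intensities were calibrated once against
#' the published no-screening and EMR/symptoms expectancies (see
#' [calibrate_nyha_matrix()]). Versioned with the package: regenerate with
#' a custom config to explore alternatives.
#'
#' @return 4 x 4 row-stochastic matrix.
#' @export
default_nyha_matrix <- function() generate_nyha_matrix(synthetic_config())

#' Generate an age-indexed life table
#'
#' Gompertz-shaped annual probabilities of death from causes other than
#' heart failure for ages 60-110, strictly increasing in age and anchored
#' so the age-60 value equals the published point mortality (0.010 for
#' men, 0.007 for women).
#'
#' @param config A [synthetic_config()] (supplies the Gompertz rate and
#'   shape).
#' @param gender `"men"` or `"women"`.
#' @return `data.frame(age, qx)` for ages 60-110.
#' @export
#' @examples
#' lt <- generate_life_table(synthetic_config(), "men")
#' lt$qx[lt$age == 60]
generate_life_table <- function(config = synthetic_config(),
                                gender = c("men", "women")) {
  gender <- match.arg(gender)
  q60 <- if (gender == "men") 0.010 else 0.007
  ages <- 60:110
  h60 <- -log(1 - q60)
  rate <- config$gompertz_params[["rate"]]
  shape <- if ("shape" %in% names(config$gompertz_params))
    config$gompertz_params[["shape"]] else 1
  h <- h60 * exp(rate * (ages - 60)^shape)
  data.frame(age = ages, qx = pmin(1 - exp(-h), 0.999))
}

#' Generate a synthetic patient-level table
#'
#' Emits one row per patient (id, gender, age, heart-failure status,
#' HFpEF/HFrEF type, NYHA class, detected flag, EQ5D utility draw, annual
#' heart-failure cost draw) such that group means of utility and cost
#' converge to the built-in parameter values as the cohort grows.
#' Utilities are drawn from Beta distributions moment-matched to the
#' group means (patient-level standard deviation `config$utility_sd`),
#' costs from Gamma distributions with variance equal to the mean. This is
#' an emulation of published summary statistics, not a reconstruction of
#' any real cohort.
#'
#' @param config A [synthetic_config()].
#' @return A `data.frame` with `config$n_patients` rows.
#' @export
generate_patient_table <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_patients
  b <- default_parameters("men")$baseline_hf_distribution
  det_share <- ifelse(rowSums(b) > 0, b[, "detected"] / rowSums(b), 0)
  u_all <- default_utilities()

  with_seed(config$seed, {
    gender <- sample(c("men", "women"), n, replace = TRUE)
    age <- pmin(60 + stats::rgamma(n, shape = 2, scale = 4), 90)
    hf <- stats::rbinom(n, 1L, config$hf_prevalence) == 1L
    nyha <- rep(NA_integer_, n)
    nyha[hf] <- sample(1:4, sum(hf), replace = TRUE,
                       prob = config$nyha_mix)
    hfpef <- rep(NA, n)
    hfpef[hf] <- stats::rbinom(sum(hf), 1L, config$hfpef_share) == 1L
    detected <- rep(FALSE, n)
    detected[hf] <- stats::runif(sum(hf)) < det_share[nyha[hf]]

    state <- rep("DIAB_NO_HF", n)
    sel <- which(hf)
    state[sel] <- STATE_LABELS[ifelse(detected[sel], I_D[nyha[sel]],
                                      I_U[nyha[sel]])]
    u_mean <- u_all[state]
    nu <- u_mean * (1 - u_mean) / config$utility_sd^2 - 1
    utility <- stats::rbeta(n, u_mean * nu, (1 - u_mean) * nu)

    cost_m <- default_parameters("men")$annual_hf_cost
    cost_w <- default_parameters("women")$annual_hf_cost
    c_mean <- numeric(n)
    idx_hf <- which(hf)
    for (i in idx_hf) {
      tabc <- if (gender[i] == "men") cost_m else cost_w
      c_mean[i] <- tabc[nyha[i], if (detected[i]) "detected" else "undetected"]
    }
    annual_cost <- numeric(n)
    annual_cost[idx_hf] <- stats::rgamma(length(idx_hf),
                                         shape = c_mean[idx_hf], scale = 1)

    data.frame(id = seq_len(n), gender = gender, age = age,
               hf = hf, hf_type = ifelse(hf, ifelse(hfpef, "HFpEF", "HFrEF"),
                                         NA_character_),
               nyha = nyha, detected = detected,
               utility = utility, annual_cost = annual_cost)
  })
}

#' Calibrate the NYHA transition matrix against outcome targets
#'
#' The published model totals depend on a 1-month NYHA transition matrix
#' that was never printed. This helper searches over the generator's
#' progression and improvement intensities (derivative-free Nelder-Mead on
#' the log scale, capped at `search_budget` model evaluations) to minimize
#' the squared deviation of the model's no-screening and EMR/symptoms
#' (undiscounted) life expectancy and QALY expectancy from the supplied
#' targets. Four scalar targets cannot identify a full matrix: the result
#' is a best-fitting member of the generator family, with no claim of
#' uniqueness.
#'
#' @param targets Numeric length 4: life-years and QALYs under no
#'   screening, then under EMR/symptoms.
#' @param base An `hf_params` object supplying every other input.
#' @param search_budget Maximum number of loss evaluations after the
#'   initial one (0 = no search, return the starting matrix with its
#'   loss).
#' @param init Optional starting [synthetic_config()].
#' @return A `nyha_calibration`: list with `matrix`, `config`, `loss`,
#'   `achieved` (model outcomes at the optimum), `targets`,
#'   `evaluations`.
#' @export
calibrate_nyha_matrix <- function(targets, base, search_budget = 300L,
                                  init = NULL) {
  stopifnot(length(targets) == 4L, search_budget >= 0L)
  targets <- as.numeric(targets)
  if (is.null(init)) init <- synthetic_config()

  strat <- screening_strategies()
  outcomes <- function(cfg) {
    p <- base
    p$nyha_monthly_transition <- generate_nyha_matrix(cfg)
    r0 <- accrue(run_cohort(strat$s0, p), p)
    r1 <- accrue(run_cohort(strat$s1, p), p)
    c(ly0 = r0$life_years, qaly0 = r0$qalys_undisc,
      ly1 = r1$life_years, qaly1 = r1$qalys_undisc)
  }
  cfg_at <- function(theta) {
    cfg <- init
    cfg$progression_intensity <- exp(theta[1L])
    cfg$improvement_intensity <- exp(theta[2L])
    cfg
  }

  evals <- 0L
  best <- list(loss = Inf, theta = NULL, achieved = NULL)
  loss_fn <- function(theta) {
    ach <- outcomes(cfg_at(theta))
    loss <- sum((ach - targets)^2)
    evals <<- evals + 1L
    if (loss < best$loss)
      best <<- list(loss = loss, theta = theta, achieved = ach)
    loss
  }

  theta0 <- log(c(max(init$progression_intensity, 1e-6),
                  max(init$improvement_intensity, 1e-6)))
  loss_fn(theta0)
  if (search_budget > 0L) {
    budget_hit <- function(e) NULL
    tryCatch(
      stats::optim(theta0, function(th) {
        if (evals >= search_budget + 1L) stop("budget exhausted")
        loss_fn(th)
      }, method = "Nelder-Mead",
      control = list(maxit = 10L * search_budget,
                     reltol = 1e-14)),
      error = budget_hit)
  }

  cfg <- cfg_at(best$theta)
  structure(list(matrix = generate_nyha_matrix(cfg), config = cfg,
                 loss = best$loss, achieved = best$achieved,
                 targets = stats::setNames(targets,
                                           names(best$achieved)),
                 evaluations = evals),
            class = "nyha_calibration")
}

#' @export
print.nyha_calibration <- function(x, ...) {
  cat("NYHA matrix calibration: loss ", format(x$loss, digits = 4),
      " after ", x$evaluations, " evaluations\n", sep = "")
  cmp <- rbind(target = x$targets, achieved = x$achieved)
  print(round(cmp, 4))
  cat("intensities: progression ",
      signif(x$config$progression_intensity, 4), ", improvement ",
      signif(x$config$improvement_intensity, 4), " per month\n", sep = "")
  invisible(x)
}
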