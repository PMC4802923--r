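#' Screening strategies
#'
#' The six strategies compared by the model. Strategy 0 is no screening
#' (usual care). Strategies 1-4 are once-in-a-life screens of increasing
#' intensity built on electronic-medical-record (EMR) and symptom checks —
#' adding physical examination, NT-proBNP, and ECG — whose NYHA-specific
#' sensitivities and specificities embody the rule that patients with an
#' estimated heart-failure risk of at least 20% are referred for
#' echocardiography. Strategy 5 refers everyone directly for
#' echocardiography (a perfect reference standard). All initial strategies
#' 1-5 are followed by an annual EMR/symptoms re-screen.
#'
#' @param id Optional single strategy id (0-5) to return.
#' @return A list of `hf_strategy` objects (or a single one if `id` is
#'   given). Each has fields `id`, `name`, `sensitivity_by_nyha`
#'   (named over NYHA classes), `specificity`, `gp_screen_cost` (EUR per
#'   screened person) and `direct_echo`.
#' @export
#' @examples
#' screening_strategies(1)$sensitivity_by_nyha
screening_strategies <- function(id = NULL) {
  sens <- rbind(
    c(0.000, 0.000, 0.000, 0.000),
    c(0.250, 0.853, 0.923, 1.000),
    c(0.250, 0.853, 0.949, 1.000),
    c(0.250, 0.879, 0.897, 1.000),
    c(0.500, 0.862, 0.897, 1.000),
    c(1.000, 1.000, 1.000, 1.000))
  colnames(sens) <- NYHA_LABELS
  spec <- c(1.000, 0.610, 0.617, 0.652, 0.676, 1.000)
  gp   <- c(0.00, 6.39, 15.17, 36.67, 61.77, 0.00)
  nm   <- c("No screening",
            "EMR/symptoms",
            "EMR/symptoms/PhysicalExam",
            "EMR/symptoms/PhysicalExam/NTproBNP",
            "EMR/symptoms/PhysicalExam/NTproBNP/ECG",
            "Echocardiography")
  out <- lapply(0:5, function(k)
    new_strategy(k, nm[k + 1L], sens[k + 1L, ], spec[k + 1L], gp[k + 1L],
                 direct_echo = k == 5L))
  names(out) <- paste0("s", 0:5)
  if (!is.null(id)) {
    stopifnot(length(id) == 1L, id %in% 0:5)
    return(out[[id + 1L]])
  }
  out
}

new_strategy <- function(id, name, sensitivity_by_nyha, specificity,
                         gp_screen_cost, direct_echo = FALSE) {
  stopifnot(all(sensitivity_by_nyha >= 0), all(sensitivity_by_nyha <= 1),
            specificity >= 0, specificity <= 1, gp_screen_cost >= 0)
  structure(list(id = as.integer(id), name = name,
                 sensitivity_by_nyha =
                   stats::setNames(as.numeric(sensitivity_by_nyha),
                                   NYHA_LABELS),
                 specificity = specificity,
                 gp_screen_cost = gp_screen_cost,
                 direct_echo = isTRUE(direct_echo)),
            class = "hf_strategy")
}

#' @export
print.hf_strategy <- function(x, ...) {
  cat("Strategy ", x$id, ": ", x$name, "\n", sep = "")
  cat("  sensitivity (NYHA I-IV):",
      paste(format(x$sensitivity_by_nyha, nsmall = 3), collapse = " "), "\n")
  cat("  specificity:", format(x$specificity, nsmall = 3),
      "  GP cost: EUR", x$gp_screen_cost,
      if (x$direct_echo) " (direct echocardiography)" else "", "\n")
  invisible(x)
}

#' Apply a screening event to a state distribution
#'
#' Moves, per NYHA class, a fraction equal to the strategy's sensitivity of
#' the undetected mass to the corresponding detected state. Echocardiography
#' is the perfect arbiter: every referral is correctly classified, so no
#' false heart-failure diagnoses occur. Only patients without diagnosed
#' heart failure and undetected NYHA states are screened; detected patients
#' are under cardiology care and dead patients are not screened.
#'
#' Event costs per cohort member comprise the GP screening cost for every
#' screened person, the echocardiography cost for every referral (new
#' detections plus the false-positive fraction `1 - specificity` of the
#' heart-failure-free mass; under direct echocardiography everyone screened
#' is referred), and an ECG stress test for every new diagnosis.
#'
#' @param dist State distribution (named length-11 vector, see
#'   [state_distribution()]).
#' @param strategy An `hf_strategy`.
#' @param params An `hf_params` object.
#' @param is_initial If `FALSE` this is an annual follow-up screen: the
#'   EMR/symptoms test profile (strategy 1 sensitivities and specificity)
#'   is used regardless of `strategy`, at the GP cost
#'   `params$gp_followup_cost`.
#' @return A `screening_outcome`: list with `post_distribution`,
#'   `screened_fraction`, `echo_referrals`, `new_detections_by_nyha`,
#'   `event_cost` and its components `cost_screening` (GP) and
#'   `cost_diagnosis` (echo + ECG).
#' @export
#' @examples
#' d <- state_distribution(DIAB_NO_HF = 0.7, NYHA2_U = 0.2, NYHA2_D = 0.1)
#' out <- apply_screening(d, screening_strategies(1), default_parameters("men"))
#' out$new_detections_by_nyha
apply_screening <- function(dist, strategy, params, is_initial = TRUE) {
  stopifnot(length(dist) == 11L)
  if (strategy$id == 0L && is_initial) {
    return(structure(list(
      post_distribution = dist, screened_fraction = 0,
      echo_referrals = 0,
      new_detections_by_nyha = stats::setNames(numeric(4L), NYHA_LABELS),
      cost_screening = 0, cost_diagnosis = 0, event_cost = 0),
      class = "screening_outcome"))
  }
  if (is_initial) {
    sens <- strategy$sensitivity_by_nyha
    spcf <- strategy$specificity
    gp   <- strategy$gp_screen_cost
    direct <- strategy$direct_echo
  } else {
    s1 <- screening_strategies(1L)
    sens <- s1$sensitivity_by_nyha
    spcf <- s1$specificity
    gp   <- params$gp_followup_cost
    direct <- FALSE
  }

  undet <- dist[I_U]
  new_det <- stats::setNames(as.numeric(sens) * as.numeric(undet),
                             NYHA_LABELS)
  post <- dist
  post[I_U] <- post[I_U] - new_det
  post[I_D] <- post[I_D] + new_det

  screened <- dist[I_NOHF] + sum(undet)
  referrals <- if (direct) screened
               else sum(new_det) + (1 - spcf) * dist[I_NOHF]

  cost_screening <- gp * screened
  cost_diagnosis <- params$echo_cost * referrals +
    diagnosis_cost(sum(new_det), params)

  structure(list(
    post_distribution = post,
    screened_fraction = unname(screened),
    echo_referrals = unname(referrals),
    new_detections_by_nyha = new_det,
    cost_screening = unname(cost_screening),
    cost_diagnosis = unname(cost_diagnosis),
    event_cost = unname(cost_screening + cost_diagnosis)),
    class = "screening_outcome")
}

#' Cost of confirming a new heart-failure diagnosis
#'
#' Each new diagnosis triggers a cardiac ECG stress test (the
#' echocardiography itself is booked with the referral).
#'
#' @param new_detections Proportion of the cohort newly diagnosed.
#' @param params An `hf_params` object.
#' @return Cost in EUR per cohort member.
#' @export
diagnosis_cost <- function(new_detections, params) {
  stopifnot(new_detections >= 0, new_detections <= 1)
  unname(new_detections * params$ecg_stress_cost)
}
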