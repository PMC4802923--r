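#' Built-in model parameter sets
#'
#' Returns the full set of model inputs for a cohort of Dutch patients with
#' type 2 diabetes aged 60 or over, stratified by gender. Point estimates
#' (screening test characteristics, incidence, mortality, health-state
#' utilities and annual heart-failure costs) are the published values the
#' default analysis emulates; inputs that were never published — the
#' one-month NYHA-to-NYHA transition matrix, the age-indexed life table,
#' hospitalization hazard ratios and drug unit costs — are supplied by the
#' seeded synthetic generators (see [generate_nyha_matrix()],
#' [generate_life_table()]), with the NYHA matrix calibrated so that
#' no-screening life expectancy matches the published totals.
#'
#' @param gender `"men"` or `"women"`.
#' @return An object of class `hf_params`: a validated named list. See
#'   Details for the fields.
#'
#' @details Fields of an `hf_params` object:
#' \describe{
#'   \item{gender, start_age, cycle_length}{cohort descriptor; ages in
#'     years, cycle length in years (default 0.25, i.e. 3 months).}
#'   \item{hf_incidence_per_100k}{heart-failure incidence per 100,000
#'     person-years (658 men, 666 women).}
#'   \item{diabetes_incidence_multiplier}{dimensionless scaling of the
#'     population incidence for the diabetic cohort (default 1).}
#'   \item{background_mortality_annual}{annual probability of death from
#'     causes other than heart failure; either a scalar or a
#'     `data.frame(age, qx)` life table.}
#'   \item{hf_mortality_annual}{4 x 2 matrix (NYHA class x
#'     detected/undetected) of annual heart-failure death probabilities.}
#'   \item{mortality_age_scale}{optional `data.frame(age, detected,
#'     undetected)` of multipliers applied (relative to their value at age
#'     65) to heart-failure mortality and to NYHA worsening probabilities;
#'     `NULL` means no age scaling.}
#'   \item{baseline_hf_distribution}{4 x 2 matrix of baseline prevalence
#'     proportions by NYHA class and detection status (remainder of the
#'     cohort starts without heart failure).}
#'   \item{baseline_detected}{logical; if `FALSE` (default) all prevalent
#'     heart failure starts undetected (the screened cohort excluded
#'     patients with a confirmed diagnosis) and the initial screening event
#'     performs the first detection; if `TRUE` the printed detected column
#'     is used verbatim as the starting distribution.}
#'   \item{nyha_monthly_transition}{4 x 4 row-stochastic matrix of 1-month
#'     NYHA-to-NYHA transition probabilities.}
#'   \item{hosp_hazard_ratio_by_nyha}{hazard ratios for hospitalization per
#'     NYHA class (used only by the derived cost path, see
#'     [derive_hf_costs()]).}
#'   \item{annual_hf_cost}{4 x 2 matrix of annual heart-failure related
#'     costs (EUR) by NYHA class and detection status.}
#'   \item{medication_prescription}{2 x 2 matrix (drug class x detection
#'     status) of prescription proportions.}
#'   \item{drug_annual_cost}{annual drug costs (EUR) per drug class (used
#'     only by the derived cost path).}
#'   \item{echo_cost, ecg_stress_cost}{event costs (EUR) of an
#'     echocardiography and a cardiac ECG stress test.}
#'   \item{gp_followup_cost}{GP cost (EUR) of one annual follow-up screen
#'     (defaults to the EMR/symptoms strategy cost).}
#'   \item{utilities}{named utility per health state (EQ5D scale, death
#'     states 0); shared across genders.}
#'   \item{discount_rate_costs, discount_rate_effects}{annual discount
#'     rates (0.04 and 0.015).}
#'   \item{hfpef_fraction}{proportion of heart failure that is HFpEF
#'     (0.826).}
#'   \item{hfref_treatment_hr}{hazard ratio on mortality of guideline
#'     treatment in detected HFrEF (default 0.90).}
#'   \item{hfpef_relative_effectiveness}{scalar in \[0, 1\]: effectiveness
#'     of HFpEF treatment relative to HFrEF treatment (0 in the base
#'     case).}
#'   \item{cohort_size, screen_prevalence}{size of the screening cohort the
#'     inputs derive from (581) and its heart-failure prevalence (0.277);
#'     used to reconstruct effective sample sizes for probabilistic
#'     sensitivity distributions.}
#'   \item{utility_se}{standard error used for Beta distributions around
#'     utility means in the probabilistic sensitivity analysis.}
#' }
#' @export
#' @examples
#' p <- default_parameters("men")
#' p$echo_cost
#' p$utilities[["DIAB_NO_HF"]]
default_parameters <- function(gender = c("men", "women")) {
  gender <- match.arg(gender)
  men <- gender == "men"

  hf_mort <- if (men) {
    nyha_matrix(detected   = c(0.042, 0.066, 0.103, 0.159),
                undetected = c(0.043, 0.067, 0.105, 0.163))
  } else {
    nyha_matrix(detected   = c(0.035, 0.056, 0.087, 0.137),
                undetected = c(0.036, 0.057, 0.089, 0.139))
  }
  hf_cost <- if (men) {
    nyha_matrix(detected   = c(1777, 2099, 3235, 8752),
                undetected = c(1786, 2114, 3275, 8912))
  } else {
    nyha_matrix(detected   = c(1172, 1370, 2070, 5470),
                undetected = c(1100, 1302, 2018, 5490))
  }
  medication <- if (men) {
    matrix(c(0.53, 0.53, 0.57, 0.50), 2, 2, byrow = TRUE,
           dimnames = list(c("ace_inhibitor", "beta_blocker"),
                           c("detected", "undetected")))
  } else {
    matrix(c(0.27, 0.18, 0.50, 0.50), 2, 2, byrow = TRUE,
           dimnames = list(c("ace_inhibitor", "beta_blocker"),
                           c("detected", "undetected")))
  }

  p <- structure(list(
    gender = gender,
    start_age = 60,
    cycle_length = 0.25,
    hf_incidence_per_100k = if (men) 658 else 666,
    diabetes_incidence_multiplier = 1,
    background_mortality_annual =
      generate_life_table(synthetic_config(), gender),
    hf_mortality_annual = hf_mort,
    mortality_age_scale = NULL,
    baseline_hf_distribution =
      nyha_matrix(detected   = c(0.007, 0.148, 0.047, 0.000),
                  undetected = c(0.000, 0.142, 0.031, 0.000)),
    baseline_detected = FALSE,
    nyha_monthly_transition = default_nyha_matrix(),
    hosp_hazard_ratio_by_nyha =
      stats::setNames(c(1.0, 1.3, 2.1, 4.5), NYHA_LABELS),
    annual_hf_cost = hf_cost,
    medication_prescription = medication,
    drug_annual_cost = c(ace_inhibitor = 85, beta_blocker = 70),
    echo_cost = 169.38,
    ecg_stress_cost = 94.75,
    gp_followup_cost = 6.39,
    utilities = default_utilities(),
    discount_rate_costs = 0.04,
    discount_rate_effects = 0.015,
    hfpef_fraction = 0.826,
    hfref_treatment_hr = 0.90,
    hfpef_relative_effectiveness = 0,
    cohort_size = 581,
    screen_prevalence = 0.277,
    utility_se = 0.02
  ), class = "hf_params")
  validate_parameters(p)
}

nyha_matrix <- function(detected, undetected) {
  matrix(c(detected, undetected), 4, 2,
         dimnames = list(NYHA_LABELS, c("detected", "undetected")))
}

default_utilities <- function() {
  u <- stats::setNames(numeric(11L), STATE_LABELS)
  u["DIAB_NO_HF"] <- 0.868
  u[c("NYHA1_D", "NYHA2_D", "NYHA3_D", "NYHA4_D")] <-
    c(0.855, 0.790, 0.734, 0.665)
  u[c("NYHA1_U", "NYHA2_U", "NYHA3_U", "NYHA4_U")] <-
    c(0.817, 0.739, 0.685, 0.683)
  u
}

#' Validate a parameter set
#'
#' Checks every structural invariant of an `hf_params` object:
#' probabilities and proportions in \[0, 1\], non-negative costs, utilities
#' at most 1, row-stochastic NYHA transition matrix, baseline prevalence
#' summing to at most 1, and heart-failure mortality non-decreasing in NYHA
#' class within each detection status. Errors name the offending field.
#'
#' @param params An `hf_params` object (or plain list with the same
#'   fields).
#' @return The validated object, invisibly classed `hf_params`.
#' @export
validate_parameters <- function(params) {
  fail <- function(field, msg)
    stop("invalid parameter '", field, "': ", msg, call. = FALSE)
  need <- setdiff(names(default_parameter_skeleton()), names(params))
  if (length(need))
    stop("missing parameter field(s): ", paste(need, collapse = ", "),
         call. = FALSE)

  chk_prob <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      fail(field, "probabilities must lie in [0, 1]")
  }
  chk_pos <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0))
      fail(field, "must be non-negative and finite")
  }

  if (!params$gender %in% c("men", "women")) fail("gender", "must be 'men' or 'women'")
  if (params$cycle_length <= 0) fail("cycle_length", "must be positive")
  chk_pos(params$hf_incidence_per_100k, "hf_incidence_per_100k")
  if (params$diabetes_incidence_multiplier < 0)
    fail("diabetes_incidence_multiplier", "must be non-negative")

  bm <- params$background_mortality_annual
  if (is.data.frame(bm)) {
    if (!all(c("age", "qx") %in% names(bm)))
      fail("background_mortality_annual", "life table needs columns age, qx")
    chk_prob(bm$qx, "background_mortality_annual")
  } else chk_prob(bm, "background_mortality_annual")

  chk_prob(params$hf_mortality_annual, "hf_mortality_annual")
  for (s in c("detected", "undetected")) {
    if (is.unsorted(params$hf_mortality_annual[, s]))
      fail("hf_mortality_annual",
           paste0("must be non-decreasing in NYHA class (", s, ")"))
  }

  M <- params$nyha_monthly_transition
  if (!is.matrix(M) || any(dim(M) != c(4L, 4L)))
    fail("nyha_monthly_transition", "must be a 4x4 matrix")
  chk_prob(M, "nyha_monthly_transition")
  if (any(abs(rowSums(M) - 1) > 1e-9))
    fail("nyha_monthly_transition",
         paste0("rows must sum to 1 (got ",
                paste(signif(rowSums(M), 6), collapse = ", "), ")"))

  chk_prob(params$baseline_hf_distribution, "baseline_hf_distribution")
  if (sum(params$baseline_hf_distribution) > 1 + 1e-9)
    fail("baseline_hf_distribution", "must sum to at most 1")

  chk_pos(params$annual_hf_cost, "annual_hf_cost")
  chk_prob(params$medication_prescription, "medication_prescription")
  chk_pos(params$drug_annual_cost, "drug_annual_cost")
  chk_pos(params$hosp_hazard_ratio_by_nyha, "hosp_hazard_ratio_by_nyha")
  chk_pos(params$echo_cost, "echo_cost")
  chk_pos(params$ecg_stress_cost, "ecg_stress_cost")
  chk_pos(params$gp_followup_cost, "gp_followup_cost")

  u <- params$utilities
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    fail("utilities", "must lie in [0, 1]")
  if (any(u[STATE_LABELS[I_DEAD]] != 0))
    fail("utilities", "death states must have utility 0")

  chk_pos(params$discount_rate_costs, "discount_rate_costs")
  chk_pos(params$discount_rate_effects, "discount_rate_effects")
  chk_prob(params$hfpef_fraction, "hfpef_fraction")
  chk_pos(params$hfref_treatment_hr, "hfref_treatment_hr")
  chk_prob(params$hfpef_relative_effectiveness, "hfpef_relative_effectiveness")

  if (!is.null(params$mortality_age_scale)) {
    ms <- params$mortality_age_scale
    if (!is.data.frame(ms) ||
        !all(c("age", "detected", "undetected") %in% names(ms)))
      fail("mortality_age_scale",
           "needs columns age, detected, undetected")
    chk_pos(ms$detected, "mortality_age_scale")
    chk_pos(ms$undetected, "mortality_age_scale")
  }
  invisible(structure(params, class = "hf_params"))
}

default_parameter_skeleton <- function() {
  # field names required of every parameter set (values irrelevant)
  list(gender = NULL, start_age = NULL, cycle_length = NULL,
       hf_incidence_per_100k = NULL, diabetes_incidence_multiplier = NULL,
       background_mortality_annual = NULL, hf_mortality_annual = NULL,
       mortality_age_scale = NULL, baseline_hf_distribution = NULL,
       baseline_detected = NULL, nyha_monthly_transition = NULL,
       hosp_hazard_ratio_by_nyha = NULL, annual_hf_cost = NULL,
       medication_prescription = NULL, drug_annual_cost = NULL,
       echo_cost = NULL, ecg_stress_cost = NULL, gp_followup_cost = NULL,
       utilities = NULL, discount_rate_costs = NULL,
       discount_rate_effects = NULL, hfpef_fraction = NULL,
       hfref_treatment_hr = NULL, hfpef_relative_effectiveness = NULL,
       cohort_size = NULL, screen_prevalence = NULL, utility_se = NULL)
}

#' Load a parameter set from a configuration source
#'
#' Accepts either the name of a built-in parameter set (`"men"` or
#' `"women"`), the path of a YAML configuration file, or a plain list of
#' overrides. Configuration keys mirror the `hf_params` fields; fields not
#' present fall back to the built-in defaults for the configured gender.
#' The returned object is fully validated; violations raise errors naming
#' the field.
#'
#' @param source Fixture name, file path, or named list.
#' @return A validated `hf_params` object.
#' @seealso [write_config()] for the inverse operation.
#' @export
#' @examples
#' p <- load_parameters("men")
#' q <- load_parameters(list(gender = "men", discount_rate_costs = 0))
#' q$discount_rate_costs
load_parameters <- function(source = "men") {
  if (is.character(source) && length(source) == 1L) {
    if (source %in% c("men", "women"))
      return(default_parameters(source))
    if (!file.exists(source))
      stop("configuration error: file not found: ", source, call. = FALSE)
    source <- yaml::read_yaml(source)
  }
  if (inherits(source, "hf_params")) return(validate_parameters(source))
  if (!is.list(source))
    stop("configuration error: source must be a fixture name, file path, ",
         "or list", call. = FALSE)
  gender <- source$gender %||% "men"
  if (!is.character(gender) || !gender %in% c("men", "women"))
    stop("configuration error: gender must be 'men' or 'women'",
         call. = FALSE)
  p <- unclass(default_parameters(gender))
  unknown <- setdiff(names(source), names(p))
  if (length(unknown))
    stop("configuration error: unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (nm in names(source))   # list-assign so NULL values keep the field
    p[nm] <- list(restore_field(nm, source[[nm]], p[[nm]]))
  validate_parameters(p)
}

# Convert a YAML-deserialized value back to the in-memory representation
# of the corresponding default field (matrices and data frames arrive as
# nested lists).
restore_field <- function(name, value, template) {
  if (is.matrix(template) && is.list(value)) {
    m <- do.call(rbind, lapply(value, unlist))
    dimnames(m) <- dimnames(template)
    storage.mode(m) <- "double"
    return(m)
  }
  if (is.data.frame(template) && is.list(value) && !is.data.frame(value))
    return(as.data.frame(lapply(value, unlist)))
  if (is.numeric(template) && !is.null(names(template)) && is.list(value))
    return(stats::setNames(unlist(value), names(value)))
  value
}

#' Write a parameter set to a YAML configuration file
#'
#' The written file round-trips through [load_parameters()]: every field is
#' restored exactly (matrices as row lists, life tables as column lists).
#'
#' @param params An `hf_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "hf_params"))
  x <- lapply(unclass(params), function(v) {
    if (is.matrix(v)) {
      rows <- lapply(seq_len(nrow(v)), function(i) as.list(v[i, ]))
      names(rows) <- rownames(v)
      rows
    } else if (is.data.frame(v)) {
      as.list(v)
    } else if (is.numeric(v) && !is.null(names(v))) {
      as.list(v)
    } else v
  })
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Export a parameter set as a flat table
#'
#' One row per scalar parameter cell: name, value, and the probabilistic
#' sensitivity distribution family attached to it (if any).
#'
#' @param params An `hf_params` object.
#' @param specs Optional list of distribution specifications, e.g. from
#'   [psa_specs()]; when supplied, family and distribution parameters are
#'   filled in for targeted cells.
#' @return A `data.frame` with columns `parameter`, `value`, `family`,
#'   `dist_parameters`.
#' @export
parameter_table <- function(params, specs = NULL) {
  rows <- list()
  add <- function(name, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = name, value = as.numeric(value),
      family = "fixed", dist_parameters = "", stringsAsFactors = FALSE)
  flat <- unclass(params)
  for (nm in names(flat)) {
    v <- flat[[nm]]
    if (is.matrix(v)) {
      for (i in rownames(v)) for (j in colnames(v))
        add(paste(nm, i, j, sep = "."), v[i, j])
    } else if (is.numeric(v) && !is.null(names(v))) {
      for (i in names(v)) add(paste(nm, i, sep = "."), v[[i]])
    } else if (is.numeric(v) && length(v) == 1L) {
      add(nm, v)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(specs)) {
    for (sp in specs) {
      nm <- paste(utils::tail(sp$target, -1L), collapse = ".")
      hit <- match(nm, out$parameter)
      if (!is.na(hit)) {
        out$family[hit] <- sp$family
        out$dist_parameters[hit] <-
          paste(signif(unlist(sp$parameters), 6), collapse = ", ")
      }
    }
  }
  out
}

#' @export
print.hf_params <- function(x, ...) {
  cat("Heart-failure screening model parameters (", x$gender, ")\n", sep = "")
  cat("  start age ", x$start_age, ", cycle length ", x$cycle_length,
      " years\n", sep = "")
  cat("  HF incidence ", x$hf_incidence_per_100k, " per 100,000 py",
      " (multiplier ", x$diabetes_incidence_multiplier, ")\n", sep = "")
  cat("  discounting: costs ", 100 * x$discount_rate_costs,
      "%/y, effects ", 100 * x$discount_rate_effects, "%/y\n", sep = "")
  cat("  HFpEF fraction ", x$hfpef_fraction,
      ", HFrEF treatment HR ", x$hfref_treatment_hr,
      ", HFpEF relative effectiveness ",
      x$hfpef_relative_effectiveness, "\n", sep = "")
  cat("  annual HF mortality (detected):",
      paste(x$hf_mortality_annual[, "detected"], collapse = " "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
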