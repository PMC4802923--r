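# Probabilistic sensitivity analysis: distribution specs attached to
# parameter-set (and strategy) fields, Monte-Carlo propagation through the
# cohort model, acceptability curves, and the HFpEF-effectiveness scenario
# grid.

# -- nested path access -------------------------------------------------

get_path <- function(obj, path) {
  for (k in seq_along(path)) {
    p <- path[k]
    if (is.matrix(obj)) {
      stopifnot(k + 1L == length(path) || k == length(path))
      if (k == length(path)) return(obj)
      return(obj[path[k], path[k + 1L]])
    }
    obj <- obj[[p]]
    if (is.null(obj)) stop("configuration error: target path not found: ",
                           paste(path, collapse = "$"), call. = FALSE)
  }
  obj
}

set_path <- function(obj, path, value) {
  p <- path[1L]
  if (is.matrix(obj)) {
    if (length(path) != 2L)
      stop("matrix targets need row and column names", call. = FALSE)
    obj[path[1L], path[2L]] <- value
    return(obj)
  }
  if (length(path) == 1L) {
    if (is.matrix(obj[[p]]) && length(value) == length(obj[[p]])) {
      # whole-block assignment (Dirichlet)
      m <- obj[[p]]
      m[] <- value
      obj[[p]] <- m
    } else obj[[p]] <- value
    return(obj)
  }
  if (is.null(obj[[p]]))
    stop("configuration error: target path not found: ",
         paste(path, collapse = "$"), call. = FALSE)
  obj[[p]] <- set_path(obj[[p]], path[-1L], value)
  obj
}

# -- default specification set ------------------------------------------

#' Default distribution specifications for the PSA
#'
#' Builds the full set of sampling distributions: Beta for screening
#' sensitivities and specificities (effective true-positive /
#' false-negative counts reconstructed from the screening cohort size and
#' prevalence, split over NYHA classes by the baseline prevalence
#' proportions; exact 0 and 1 cells stay fixed), Beta (method of moments,
#' standard error `params$utility_se`) for utilities, Gamma with variance
#' equal to the mean for every cost, and a Dirichlet over the baseline
#' prevalence block. Incidence and mortality inputs stay fixed.
#'
#' @param params An `hf_params` object.
#' @param strategies Strategy list from [screening_strategies()].
#' @return A list of `dist_spec` objects with targets into
#'   `list(params = , strategies = )`.
#' @export
psa_specs <- function(params, strategies = screening_strategies()) {
  specs <- list()
  add <- function(sp) specs[[length(specs) + 1L]] <<- sp

  b <- params$baseline_hf_distribution
  nyha_prop <- rowSums(b) / sum(rowSums(b))
  n_cases <- params$cohort_size * params$screen_prevalence
  n_noncases <- params$cohort_size * (1 - params$screen_prevalence)

  for (snm in names(strategies)) {
    st <- strategies[[snm]]
    if (st$id %in% c(0L, 5L)) next  # all-0 / all-1 profiles: fixed
    for (k in seq_along(NYHA_LABELS)) {
      sens <- st$sensitivity_by_nyha[k]
      n_k <- n_cases * nyha_prop[k]
      if (sens > 0 && sens < 1 && n_k > 0)
        add(beta_spec_from_counts(
          sens * n_k, (1 - sens) * n_k,
          target = c("strategies", snm, "sensitivity_by_nyha",
                     NYHA_LABELS[k])))
    }
    if (st$specificity > 0 && st$specificity < 1)
      add(beta_spec_from_counts(
        st$specificity * n_noncases, (1 - st$specificity) * n_noncases,
        target = c("strategies", snm, "specificity")))
    if (st$gp_screen_cost > 0)
      add(gamma_spec_from_mean(st$gp_screen_cost,
                               target = c("strategies", snm,
                                          "gp_screen_cost")))
  }

  for (nm in names(params$utilities)) {
    u <- params$utilities[[nm]]
    if (u > 0 && u < 1)
      add(beta_spec_from_mean_se(u, params$utility_se,
                                 target = c("params", "utilities", nm)))
  }

  add(gamma_spec_from_mean(params$echo_cost,
                           target = c("params", "echo_cost")))
  add(gamma_spec_from_mean(params$ecg_stress_cost,
                           target = c("params", "ecg_stress_cost")))
  if (params$gp_followup_cost > 0)
    add(gamma_spec_from_mean(params$gp_followup_cost,
                             target = c("params", "gp_followup_cost")))
  for (i in rownames(params$annual_hf_cost))
    for (j in colnames(params$annual_hf_cost))
      add(gamma_spec_from_mean(params$annual_hf_cost[i, j],
                               target = c("params", "annual_hf_cost", i, j)))

  alpha <- as.vector(b) * params$cohort_size / sum(b)
  names(alpha) <- paste(rep(colnames(b), each = 4L), rownames(b), sep = ".")
  add(dirichlet_spec(alpha, block_total = sum(b),
                     target = c("params", "baseline_hf_distribution")))
  specs
}

#' Sample one parameter set from distribution specifications
#'
#' Returns a copy of the base object with each targeted field replaced by
#' one draw; fixed specs (and untargeted fields) are untouched. Draws are
#' independent given the RNG state.
#'
#' @param base An `hf_params` object, or a combined
#'   `list(params = , strategies = )` model object.
#' @param specs List of `dist_spec` objects.
#' @param rng_seed Optional integer seed; if `NULL` the current RNG stream
#'   is used.
#' @return Object of the same shape as `base` with sampled values.
#' @export
sample_parameters <- function(base, specs, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  wrapped <- inherits(base, "hf_params")
  obj <- if (wrapped) list(params = base) else base
  for (sp in specs) {
    if (is.null(sp$target)) next
    if (sp$family == "fixed" && is.null(sp$value)) next
    path <- sp$target
    if (wrapped && path[1L] != "params")
      stop("configuration error: spec targets '", path[1L],
           "' but only a parameter set was supplied", call. = FALSE)
    obj <- set_path(obj, path, draw_spec(sp))
  }
  if (wrapped) {
    structure(obj$params, class = "hf_params")
  } else {
    obj$params <- structure(obj$params, class = "hf_params")
    obj
  }
}

# -- PSA ----------------------------------------------------------------

#' Run the probabilistic sensitivity analysis
#'
#' For each Monte-Carlo draw, samples one parameter set (and strategy test
#' characteristics) from the distribution specifications and evaluates the
#' full pipeline — cohort simulation and discounted accrual — for every
#' strategy on that same draw (common random parameters across strategies
#' within a draw). Draws producing an invalid parameter set are rejected
#' and redrawn.
#'
#' @param strategies Strategy list from [screening_strategies()].
#' @param base An `hf_params` object (the base case the sampling is
#'   mean-centred on).
#' @param specs List of `dist_spec`s; defaults to [psa_specs()].
#' @param n Number of Monte-Carlo samples (the reference analysis uses
#'   10,000).
#' @param seed Integer seed; the same seed reproduces the cloud exactly.
#' @return An `hf_psa`: list with `samples` (`data.frame` of `draw`,
#'   `strategy`, `qalys`, `cost`), `n_samples`, `seed`, `rejections`, and
#'   `base_results` (deterministic results per strategy).
#' @export
run_psa <- function(strategies, base, specs = NULL, n = 10000L, seed = 1L) {
  stopifnot(n >= 1L)
  if (is.null(specs)) specs <- psa_specs(base, strategies)
  set.seed(seed)
  model0 <- list(params = base, strategies = strategies)
  S <- length(strategies)
  qal <- matrix(NA_real_, n, S)
  cst <- matrix(NA_real_, n, S)
  rejections <- 0L

  for (d in seq_len(n)) {
    model <- NULL
    for (try in 1:100) {
      cand <- sample_parameters(model0, specs)
      ok <- tryCatch({validate_parameters(cand$params); TRUE},
                     error = function(e) FALSE)
      if (ok) { model <- cand; break }
      rejections <- rejections + 1L
    }
    if (is.null(model))
      stop("PSA draw ", d, ": no valid parameter set in 100 attempts",
           call. = FALSE)
    res <- evaluate_strategies(model$strategies, model$params)
    qal[d, ] <- vapply(res, `[[`, 0, "qalys")
    cst[d, ] <- vapply(res, `[[`, 0, "total_cost")
  }

  ids <- vapply(strategies, `[[`, 0L, "id")
  samples <- data.frame(
    draw = rep(seq_len(n), times = S),
    strategy = rep(ids, each = n),
    qalys = as.vector(qal), cost = as.vector(cst))
  structure(list(samples = samples, n_samples = n, seed = seed,
                 rejections = rejections,
                 base_results = evaluate_strategies(strategies, base)),
            class = "hf_psa")
}

# deterministic pipeline for a set of strategies under one parameter set,
# sharing the per-cycle transition matrices
evaluate_strategies <- function(strategies, params, half_cycle = FALSE) {
  cl <- params$cycle_length
  ages <- params$start_age + (seq_len(ceiling((110 - params$start_age) / cl)
                                      + 1L) - 1L) * cl
  mats <- transition_matrices(params, ages)
  lapply(strategies, function(st)
    accrue(run_cohort(st, params, matrices = mats), params,
           half_cycle = half_cycle))
}

#' @export
print.hf_psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis: ", x$n_samples,
      " draws (seed ", x$seed, ", ", x$rejections, " rejected)\n", sep = "")
  ag <- stats::aggregate(cbind(qalys, cost) ~ strategy, x$samples, mean)
  cat("cloud means:\n")
  print(ag, row.names = FALSE)
  invisible(x)
}

#' Plot the PSA cloud on the cost-effectiveness plane
#'
#' Incremental QALYs and costs of each strategy versus the comparator.
#'
#' @param x An `hf_psa`.
#' @param comparator Strategy id used as origin (default 0).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hf_psa <- function(x, comparator = 0L, ...) {
  s <- x$samples
  ref <- s[s$strategy == comparator, ]
  others <- setdiff(unique(s$strategy), comparator)
  cols <- grDevices::hcl.colors(length(others), "Dark 3")
  dq <- dc <- NULL
  for (k in seq_along(others)) {
    si <- s[s$strategy == others[k], ]
    dq <- cbind(dq, si$qalys - ref$qalys)
    dc <- cbind(dc, si$cost - ref$cost)
  }
  graphics::plot(range(dq), range(dc), type = "n",
                 xlab = "Incremental QALYs", ylab = "Incremental cost (EUR)",
                 ...)
  for (k in seq_along(others))
    graphics::points(dq[, k], dc[, k], pch = ".", col = cols[k])
  graphics::legend("topleft", legend = paste("strategy", others),
                   col = cols, pch = 19, cex = 0.8, bty = "n")
  invisible(x)
}

# -- CEAC ---------------------------------------------------------------

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, the probability that each strategy is
#' optimal: the fraction of PSA draws in which it attains the strictly
#' highest net monetary benefit (exact ties split equally).
#'
#' @param cloud An `hf_psa` from [run_psa()].
#' @param wtp_grid Vector of willingness-to-pay values (EUR per QALY).
#' @return A `ceac_curve`: list with `wtp` and `prob_optimal` (matrix
#'   willingness-to-pay x strategy).
#' @export
ceac <- function(cloud, wtp_grid) {
  stopifnot(inherits(cloud, "hf_psa"), length(wtp_grid) >= 1L)
  s <- cloud$samples
  ids <- sort(unique(s$strategy))
  n <- cloud$n_samples
  qal <- matrix(s$qalys[order(match(s$strategy, ids), s$draw)], n,
                length(ids))
  cst <- matrix(s$cost[order(match(s$strategy, ids), s$draw)], n,
                length(ids))
  prob <- matrix(0, length(wtp_grid), length(ids),
                 dimnames = list(NULL, paste0("s", ids)))
  for (w in seq_along(wtp_grid)) {
    nmb <- wtp_grid[w] * qal - cst
    best <- nmb == row_maxs(nmb)
    wts <- best / rowSums(best)   # ties split equally
    prob[w, ] <- colSums(wts) / n
  }
  structure(list(wtp = wtp_grid, prob_optimal = prob, strategies = ids),
            class = "ceac_curve")
}

row_maxs <- function(m) do.call(pmax, as.data.frame(m))

#' @export
print.ceac_curve <- function(x, ...) {
  cat("Cost-effectiveness acceptability curves over ", length(x$wtp),
      " WTP values [", min(x$wtp), ", ", max(x$wtp), "]\n", sep = "")
  best <- x$strategies[apply(x$prob_optimal, 1L, which.max)]
  sw <- which(diff(best) != 0)
  if (length(sw)) {
    cat("most-probable strategy switches:\n")
    for (i in sw)
      cat(sprintf("  WTP %s: strategy %d -> %d\n",
                  format(x$wtp[i + 1L], big.mark = ","), best[i],
                  best[i + 1L]))
  } else cat("strategy", best[1L], "most probable throughout\n")
  invisible(x)
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param x A `ceac_curve`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ceac_curve <- function(x, ...) {
  graphics::matplot(x$wtp, x$prob_optimal, type = "l", lty = 1,
                    xlab = "Willingness to pay (EUR/QALY)",
                    ylab = "Probability cost-effective", ylim = c(0, 1),
                    ...)
  graphics::legend("right", legend = colnames(x$prob_optimal),
                   col = seq_len(ncol(x$prob_optimal)), lty = 1,
                   cex = 0.8, bty = "n")
  invisible(x)
}

#' @export
as.data.frame.ceac_curve <- function(x, ...) {
  data.frame(wtp = x$wtp, x$prob_optimal, check.names = FALSE)
}

# -- scenario grid ------------------------------------------------------

#' HFpEF treatment-effectiveness scenario grid
#'
#' Re-runs the deterministic pipeline for each value of the relative HFpEF
#' treatment effectiveness `rho` (0 = base case, no HFpEF effect; 1 = full
#' HFrEF-equivalent effect in the HFpEF share) and records the incremental
#' cost-effectiveness ratios for the requested strategy comparisons.
#'
#' @param strategies Strategy list from [screening_strategies()].
#' @param base An `hf_params` object.
#' @param rho_values Vector in \[0, 1\] (default the 11-point grid 0,
#'   0.1, ..., 1).
#' @param comparisons List of id pairs `c(strategy, comparator)`; default
#'   EMR/symptoms vs no screening and echocardiography vs EMR/symptoms.
#' @return A `data.frame` with columns `rho`, `comparison`, `delta_qalys`,
#'   `delta_cost`, `icer`, classed `scenario_grid`.
#' @export
scenario_grid <- function(strategies, base,
                          rho_values = seq(0, 1, by = 0.1),
                          comparisons = list(c(1L, 0L), c(5L, 1L))) {
  stopifnot(all(rho_values >= 0), all(rho_values <= 1))
  ids <- vapply(strategies, `[[`, 0L, "id")
  rows <- list()
  for (rho in rho_values) {
    p <- base
    p$hfpef_relative_effectiveness <- rho
    res <- evaluate_strategies(strategies, p)
    for (cmp in comparisons) {
      a <- res[[which(ids == cmp[1L])]]
      b <- res[[which(ids == cmp[2L])]]
      dq <- a$qalys - b$qalys
      dcst <- a$total_cost - b$total_cost
      rows[[length(rows) + 1L]] <- data.frame(
        rho = rho,
        comparison = paste(cmp[1L], "vs", cmp[2L]),
        delta_qalys = dq, delta_cost = dcst,
        icer = if (dq != 0) dcst / dq else NA_real_)
    }
  }
  structure(do.call(rbind, rows), class = c("scenario_grid", "data.frame"))
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat("HFpEF treatment-effectiveness scenario grid\n")
  y <- as.data.frame(x)
  y$delta_qalys <- signif(y$delta_qalys, 4)
  y$delta_cost <- round(y$delta_cost)
  y$icer <- round(y$icer)
  print(y, row.names = FALSE)
  invisible(x)
}
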