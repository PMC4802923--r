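# Top-level experiment drivers: deterministic base case, full analysis
# (both genders, PSA, CEAC, scenario grid), and a run manifest. These
# functions, the plotting methods and the analysis scripts are the
# package's user interface; results are plain data structures that export
# to delimited text via the as.data.frame methods and write.csv.

#' Deterministic base-case analysis
#'
#' Runs all six strategies under one parameter set, accrues discounted
#' outcomes, and performs the incremental cost-effectiveness analysis.
#'
#' @param params An `hf_params` object, or anything [load_parameters()]
#'   accepts.
#' @param strategies Strategy list (default [screening_strategies()]).
#' @param half_cycle Apply a half-cycle correction in the accrual.
#' @return An `hf_base_case`: list with `results` (per-strategy
#'   `econ_result`s), `absolute` (`data.frame`, one row per strategy),
#'   `cea` (a [incremental_analysis()] result) and `gender`.
#' @export
#' @examples
#' \donttest{
#' bc <- run_base_case("men")
#' bc$absolute
#' }
run_base_case <- function(params, strategies = screening_strategies(),
                          half_cycle = FALSE) {
  params <- load_parameters(params)
  results <- evaluate_strategies(strategies, params, half_cycle = half_cycle)
  absolute <- do.call(rbind, lapply(results, as.data.frame))
  rownames(absolute) <- NULL
  structure(list(results = results, absolute = absolute,
                 cea = incremental_analysis(results),
                 gender = params$gender),
            class = "hf_base_case")
}

#' @export
print.hf_base_case <- function(x, ...) {
  cat("Base-case analysis (", x$gender, ")\n\n", sep = "")
  ab <- x$absolute
  ab$life_years <- round(ab$life_years, 3)
  ab$qalys <- round(ab$qalys, 3)
  for (cc in grep("cost", names(ab))) ab[[cc]] <- round(ab[[cc]])
  print(ab[, c("strategy", "name", "life_years", "qalys", "total_cost")],
        row.names = FALSE)
  cat("\n")
  print(x$cea)
  invisible(x)
}

#' Full analysis: base case, PSA, CEAC and scenario grid
#'
#' @param config_men,config_women Parameter sources for the two genders
#'   (anything [load_parameters()] accepts).
#' @param n_psa Monte-Carlo samples for the probabilistic sensitivity
#'   analysis (the reference analysis uses 10,000).
#' @param seed Integer seed for the PSA.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curves.
#' @param rho_values HFpEF-effectiveness grid for the scenario analysis.
#' @param out_dir Optional directory; when given, every table is written
#'   as CSV and a run manifest as YAML.
#' @return A list with elements `base_case`, `psa`, `ceac`, `scenario`
#'   (each a named list over genders) and `manifest`.
#' @export
run_full <- function(config_men = "men", config_women = "women",
                     n_psa = 10000L, seed = 1L,
                     wtp_grid = seq(0, 80000, by = 500),
                     rho_values = seq(0, 1, by = 0.1),
                     out_dir = NULL) {
  strategies <- screening_strategies()
  cfgs <- list(men = config_men, women = config_women)
  out <- list(base_case = list(), psa = list(), ceac = list(),
              scenario = list())
  for (g in names(cfgs)) {
    p <- load_parameters(cfgs[[g]])
    out$base_case[[g]] <- run_base_case(p, strategies)
    out$psa[[g]] <- run_psa(strategies, p, n = n_psa, seed = seed)
    out$ceac[[g]] <- ceac(out$psa[[g]], wtp_grid)
    out$scenario[[g]] <- scenario_grid(strategies, p, rho_values)
  }
  out$manifest <- list(
    package_version = as.character(utils::packageVersion("hfscreen")),
    seed = seed, n_psa = n_psa,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = character(0))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      path <- file.path(out_dir, paste0(name, ".csv"))
      utils::write.csv(df, path, row.names = FALSE)
      out$manifest$outputs <<- c(out$manifest$outputs, path)
    }
    for (g in names(cfgs)) {
      wr(out$base_case[[g]]$absolute, paste0("base_case_", g))
      wr(out$base_case[[g]]$cea$table, paste0("cea_", g))
      wr(out$psa[[g]]$samples, paste0("psa_cloud_", g))
      wr(as.data.frame(out$ceac[[g]]), paste0("ceac_", g))
      wr(as.data.frame(out$scenario[[g]]), paste0("scenario_", g))
    }
    yaml::write_yaml(out$manifest, file.path(out_dir, "manifest.yaml"))
  }
  out
}
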