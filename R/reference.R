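#' Published per-strategy reference outcomes
#'
#' The per-strategy discounted totals — life expectancy, QALY expectancy
#' and expected lifetime cost per person — reported by the published Dutch
#' evaluation of these six screening strategies, which the default
#' parameter sets emulate. Useful as calibration targets and as inputs to
#' [incremental_analysis()] to reproduce the published dominance
#' structure.
#'
#' @param gender `"men"` or `"women"`.
#' @return `data.frame` with columns `strategy` (0-5), `life_years`,
#'   `effect` (QALYs) and `cost` (EUR).
#' @export
#' @examples
#' incremental_analysis(reference_outcomes("men"))
reference_outcomes <- function(gender = c("men", "women")) {
  gender <- match.arg(gender)
  if (gender == "men") {
    data.frame(
      strategy = 0:5,
      life_years = c(14.726, 14.742, 14.742, 14.742, 14.742, 14.742),
      effect = c(12.345, 12.477, 12.477, 12.477, 12.477, 12.479),
      cost = c(6795, 7605, 7611, 7625, 7642, 7667))
  } else {
    data.frame(
      strategy = 0:5,
      life_years = c(16.830, 16.851, 16.851, 16.851, 16.851, 16.852),
      effect = c(14.047, 14.215, 14.215, 14.216, 14.215, 14.217),
      cost = c(5024, 6086, 6093, 6107, 6125, 6152))
    }
}
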