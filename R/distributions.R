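# Distribution specifications for probabilistic sensitivity analysis.
# A spec couples a sampling family (beta / gamma / dirichlet / fixed) with
# the parameter-set field it perturbs; every spec is mean-centred on the
# base-case point estimate so the PSA cloud scatters around the
# deterministic result.

new_spec <- function(family, parameters, target = NULL, value = NULL,
                     block_total = NULL) {
  structure(list(family = family, parameters = parameters,
                 target = target, value = value,
                 block_total = block_total),
            class = "dist_spec")
}

#' Gamma specification with variance equal to the mean
#'
#' Cost parameters are sampled from Gamma distributions whose variance
#' equals their mean; under the shape-scale convention this is shape =
#' mean, scale = 1.
#'
#' @param mean_cost Positive mean (EUR).
#' @param target Optional field path (character vector) the spec perturbs.
#' @return A `dist_spec`.
#' @export
#' @examples
#' sp <- gamma_spec_from_mean(169.38)
#' spec_mean(sp)
gamma_spec_from_mean <- function(mean_cost, target = NULL) {
  if (!is.finite(mean_cost) || mean_cost <= 0)
    stop("mean_cost must be positive", call. = FALSE)
  new_spec("gamma", list(shape = mean_cost, scale = 1), target)
}

#' Beta specification from true-positive / false-negative counts
#'
#' Screening sensitivities are sampled from Beta distributions
#' parameterized by the (possibly non-integer, effective) counts of true
#' positives and false negatives, so the mean equals the point sensitivity
#' TP / (TP + FN). A count of zero on either side makes the distribution
#' degenerate; such inputs are treated as fixed at 0 or 1 and are not
#' sampled.
#'
#' @param true_positives,false_negatives Non-negative effective counts,
#'   not both zero.
#' @param target Optional field path.
#' @return A `dist_spec` (family `"beta"`, or `"fixed"` when degenerate).
#' @export
#' @examples
#' spec_mean(beta_spec_from_counts(29, 5))  # 29/34
beta_spec_from_counts <- function(true_positives, false_negatives,
                                  target = NULL) {
  if (true_positives < 0 || false_negatives < 0)
    stop("counts must be non-negative", call. = FALSE)
  if (true_positives + false_negatives <= 0)
    stop("at least one count must be positive", call. = FALSE)
  if (true_positives == 0)
    return(new_spec("fixed", list(), target, value = 0))
  if (false_negatives == 0)
    return(new_spec("fixed", list(), target, value = 1))
  new_spec("beta", list(shape1 = true_positives, shape2 = false_negatives),
           target)
}

#' Beta specification from a mean and standard error
#'
#' Method-of-moments Beta for utility parameters, for which only means are
#' published: shape1 + shape2 = m(1-m)/se^2 - 1.
#'
#' @param mean Mean in (0, 1).
#' @param se Standard error; must satisfy se^2 < mean(1-mean).
#' @param target Optional field path.
#' @return A `dist_spec`.
#' @export
beta_spec_from_mean_se <- function(mean, se, target = NULL) {
  if (mean <= 0 || mean >= 1)
    stop("mean must lie strictly in (0, 1)", call. = FALSE)
  if (se <= 0 || se^2 >= mean * (1 - mean))
    stop("se^2 must be smaller than mean*(1-mean)", call. = FALSE)
  nu <- mean * (1 - mean) / se^2 - 1
  new_spec("beta", list(shape1 = mean * nu, shape2 = (1 - mean) * nu),
           target)
}

#' Dirichlet specification for a probability block
#'
#' Baseline prevalence cells are sampled jointly from a Dirichlet
#' distribution with concentrations equal to the effective counts; the
#' draw is rescaled so the block keeps its base-case total (the remaining
#' mass stays in the no-heart-failure state). Cells with zero
#' concentration remain fixed at zero.
#'
#' @param concentrations Non-negative concentration parameters (named).
#' @param block_total Total probability mass of the block after rescaling.
#' @param target Optional field path of the block.
#' @return A `dist_spec`.
#' @export
dirichlet_spec <- function(concentrations, block_total, target = NULL) {
  if (sum(concentrations > 0) < 2)
    stop("dirichlet needs at least two positive concentrations",
         call. = FALSE)
  if (any(concentrations < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  new_spec("dirichlet", list(alpha = concentrations), target,
           block_total = block_total)
}

#' Fixed (degenerate) specification
#'
#' @param value The fixed value (may be `NULL`, meaning "leave the base
#'   value untouched").
#' @param target Optional field path.
#' @return A `dist_spec`.
#' @export
fixed_spec <- function(value = NULL, target = NULL)
  new_spec("fixed", list(), target, value = value)

#' Analytic mean of a distribution specification
#'
#' @param spec A `dist_spec`.
#' @return Numeric mean (a vector for Dirichlet blocks; `NA` for fixed
#'   specs without a stored value).
#' @export
spec_mean <- function(spec) {
  switch(spec$family,
    gamma = spec$parameters$shape * spec$parameters$scale,
    beta  = spec$parameters$shape1 /
            (spec$parameters$shape1 + spec$parameters$shape2),
    dirichlet = {
      a <- spec$parameters$alpha
      pos <- sum(a)
      if (pos <= 0) a else a / pos * spec$block_total
    },
    fixed = if (is.null(spec$value)) NA_real_ else spec$value,
    stop("unknown family: ", spec$family))
}

# One random draw from a spec, using the current RNG stream.
draw_spec <- function(spec) {
  switch(spec$family,
    gamma = stats::rgamma(1L, shape = spec$parameters$shape,
                          scale = spec$parameters$scale),
    beta  = stats::rbeta(1L, spec$parameters$shape1,
                         spec$parameters$shape2),
    dirichlet = {
      a <- spec$parameters$alpha
      g <- numeric(length(a))
      pos <- a > 0
      g[pos] <- stats::rgamma(sum(pos), shape = a[pos], rate = 1)
      if (sum(g) > 0) g <- g / sum(g) * spec$block_total
      names(g) <- names(a)
      g
    },
    fixed = spec$value,
    stop("unknown family: ", spec$family))
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec ", x$family, ">", sep = "")
  if (!is.null(x$target))
    cat(" -> ", paste(x$target, collapse = "$"), sep = "")
  if (x$family != "fixed")
    cat("  (", paste(names(unlist(x$parameters)),
                     signif(unlist(x$parameters), 5),
                     sep = "=", collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}
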