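#' Model health states
#'
#' The cohort model distinguishes eleven mutually exclusive health states:
#' diabetes without diagnosed heart failure, the four NYHA symptom classes
#' each split into an undetected (`_U`) and a detected (`_D`) variant, and
#' two absorbing death states (death from heart failure and death from
#' other causes).
#'
#' @return Character vector of the eleven state labels, in model order.
#' @export
#' @examples
#' health_states()
health_states <- function() STATE_LABELS

STATE_LABELS <- c("DIAB_NO_HF",
                  "NYHA1_U", "NYHA1_D",
                  "NYHA2_U", "NYHA2_D",
                  "NYHA3_U", "NYHA3_D",
                  "NYHA4_U", "NYHA4_D",
                  "DEATH_HF", "DEATH_OTHER")

NYHA_LABELS <- c("NYHA1", "NYHA2", "NYHA3", "NYHA4")

# index helpers (fixed layout, used throughout the engine)
I_NOHF  <- 1L
I_U     <- c(2L, 4L, 6L, 8L)   # NYHA 1-4 undetected
I_D     <- c(3L, 5L, 7L, 9L)   # NYHA 1-4 detected
I_DHF   <- 10L
I_DOTH  <- 11L
I_ALIVE <- 1:9
I_DEAD  <- c(10L, 11L)

#' Construct a state distribution
#'
#' A probability mass over the eleven health states. Missing states get
#' probability zero.
#'
#' @param ... Named state probabilities, or a single named numeric vector.
#' @return Named numeric vector of length 11 summing over supplied mass.
#' @export
#' @examples
#' state_distribution(DIAB_NO_HF = 0.8, NYHA2_U = 0.2)
state_distribution <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]])))
    args <- as.list(args[[1]])
  bad <- setdiff(names(args), STATE_LABELS)
  if (length(bad))
    stop("unknown health state(s): ", paste(bad, collapse = ", "))
  x <- stats::setNames(numeric(11L), STATE_LABELS)
  x[names(args)] <- unlist(args)
  if (any(x < 0)) stop("state probabilities must be non-negative")
  x
}
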