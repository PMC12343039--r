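#' Round half away from zero
#'
#' Commercial rounding used for all report display: ties go away from zero
#' (2.5 -> 3, -2.5 -> -3), unlike [base::round()]'s round-half-even.
#' Unrounded values are always retained internally; this is a display policy.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places (may be negative).
#' @return numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_up(c(2.5, -2.5, 460.57))  # 3 -3 461
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Population standard deviation
#'
#' Dispersion with divisor `n` (not `n - 1`). All assemblage summaries in this
#' package use the population convention: the printed literature summaries the
#' fixtures reproduce are only consistent with division by `n`.
#'
#' @param x numeric vector (length >= 1); `NA`s are an error by design.
#' @return scalar standard deviation.
#' @export
#' @examples
#' pop_sd(c(1, 2, 3))        # sqrt(2/3)
#' sd(c(1, 2, 3))            # sample convention, larger
pop_sd <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L, !anyNA(x))
  sqrt(mean((x - mean(x))^2))
}

## stop() with a consistent prefix, no call
abort <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## single quote a taxon name for messages
sq <- function(x) paste0("'", x, "'")
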