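#' Round half away from zero
#'
#' Decimal rounding with ties going up (away from zero), the convention used
#' at every percentage-reporting boundary in this package. Base [round()]
#' rounds half to even, which would render 139/204 as 68.14 vs 68.13
#' depending on floating noise; half-up is deterministic for the two-decimal
#' percentages reported here.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return numeric vector rounded half-up to `digits` places
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Render a proportion as a percentage rounded half-up to two decimals
#' @param x numerator
#' @param n denominator
#' @return numeric percentage (e.g. 34.71)
#' @export
percent2 <- function(x, n) {
  round_half_up(100 * x / n, 2)
}

abort <- function(..., class = "chdtriage_error") {
  stop(errorCondition(paste0(...), class = c(class, "chdtriage_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strict scalar checks used by readers/validators
assert_in <- function(x, choices, what) {
  bad <- setdiff(unique(x), choices)
  if (length(bad)) {
    abort(what, " contains invalid value(s): ", paste(bad, collapse = ", "),
          " (valid: ", paste(choices, collapse = ", "), ")",
          class = "chdtriage_validation_error")
  }
  invisible(x)
}
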