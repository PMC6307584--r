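#' @importFrom rlang abort warn inform .data %||%
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

abort_bad_param <- function(msg) {
  abort(msg, class = "bedrelease_error_parameter")
}

abort_validation <- function(msg) {
  abort(msg, class = "bedrelease_error_validation")
}

check_number <- function(x, name, lower = -Inf, strict = FALSE, len = 1L) {
  ok <- is.numeric(x) && length(x) == len && all(is.finite(x)) &&
    (if (strict) all(x > lower) else all(x >= lower))
  if (!ok) {
    cmp <- if (strict) "greater than" else "at least"
    abort_bad_param(sprintf("`%s` must be a finite numeric value %s %s.", name, cmp, format(lower)))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= lower && x == trunc(x)
  if (!ok) abort_bad_param(sprintf("`%s` must be an integer of at least %d.", name, lower))
  invisible(as.integer(x))
}
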