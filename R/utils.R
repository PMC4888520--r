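# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported cohort counts here use
#' the conventional "half away from zero" rule so that e.g. 0.5 becomes 1.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 93.1909))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Percent string at one decimal, e.g. "77.5 %"; NA renders as "undefined".
fmt_pct <- function(x, digits = 1) {
  out <- sprintf(paste0("%.", digits, "f %%"), 100 * x)
  out[is.na(x)] <- "undefined"
  out
}

# Structured validation failure naming the offending field; mapped to
# exit code 2 by the command-line wrapper.
validation_error <- function(field, msg) {
  stop(errorCondition(
    sprintf("invalid `%s`: %s", field, msg),
    field = field,
    class = c("screenval_validation_error", "screenval_error")
  ))
}

check_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    validation_error(field, "must be a single non-missing number")
  }
  as.numeric(x)
}

check_prob <- function(x, field) {
  x <- check_number(x, field)
  if (x < 0 || x > 1) validation_error(field, "must lie in [0, 1]")
  x
}

check_count <- function(x, field) {
  x <- check_number(x, field)
  if (x < 1 || x != floor(x)) validation_error(field, "must be a positive integer")
  as.integer(x)
}

check_nonneg <- function(x, field) {
  x <- check_number(x, field)
  if (x < 0) validation_error(field, "must be non-negative")
  x
}

check_string <- function(x, field) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    validation_error(field, "must be a non-empty string")
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
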