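#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join semi_join bind_rows bind_cols distinct
#'   n rename
#'   across all_of pull count
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats lm coef integrate median quantile setNames rlnorm runif
#' @importFrom utils head
NULL

#' Half-up decimal rounding
#'
#' Rounds half away from zero toward plus infinity on ties (`round()` in R
#' is round-half-even), matching how report tables print one-decimal
#' percentages (7.95 prints as 8.0). Used only for formatting; internal
#' arithmetic stays at full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' @keywords internal
stop_bad_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "pollishock_input_error")
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_bad_input("%s is missing required column(s): %s",
                   what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

assert_fraction <- function(x, what, lo = 0, hi = 1) {
  bad <- !is.finite(x) | x < lo | x > hi
  if (any(bad)) {
    stop_bad_input("%s must lie in [%g, %g]; %d value(s) do not",
                   what, lo, hi, sum(bad))
  }
  invisible(x)
}
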