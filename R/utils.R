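# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base `round()` rounds half to even; administrative reports conventionally
#' round half up, so 0.5% becomes 1%. Used for all integer-percent reporting.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))   # 1 2 3
#' round_half_up(67.32)              # 67
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Integer percent with the "<1" convention: nonzero shares that round to zero
# are reported as "<1" (the smallest honest integer statement).
format_pct <- function(numerator, denominator) {
  if (denominator == 0) return(NA_character_)
  p <- 100 * numerator / denominator
  r <- round_half_up(p)
  if (numerator > 0 && r == 0) "<1" else as.character(r)
}

pct_int <- function(numerator, denominator) {
  if (denominator == 0) return(NA_real_)
  round_half_up(100 * numerator / denominator)
}

# Minutes between two POSIXct vectors (b - a), as a signed double.
minutes_between <- function(a, b) {
  as.numeric(difftime(b, a, units = "mins"))
}

# Floor a POSIXct to minute resolution (seconds truncated, never rounded up).
floor_minute <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 60) * 60,
             origin = "1970-01-01", tz = "UTC")
}

# Deterministic, locale-independent ordering for character keys.
order_radix <- function(...) order(..., method = "radix")

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

empty_df <- function(...) {
  spec <- list(...)
  out <- lapply(spec, function(cls) vector(cls, 0L))
  as.data.frame(out, stringsAsFactors = FALSE)
}
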