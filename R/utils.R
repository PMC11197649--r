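# Shared internal helpers: rounding, formatting, error classes, hashing.

#' Round half away from zero
#'
#' Dashboard tables display percentages to one decimal using commercial
#' (half-up) rounding, not the IEEE round-half-even rule of [base::round()].
#' A small absolute guard (1e-9) absorbs binary floating-point representation
#' error in ratios of integer counts so that values that are exactly on a
#' .x5 boundary in decimal round upwards.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1, the dashboard display
#'   convention).
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(21.65)  # 21.7
#' round_half_up(0.25, 1)  # 0.3 (round() would give 0.2)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# one-decimal percentage string, "NA" for missing
fmt_pct <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.1f", round_half_up(x, 1)))
}

# error constructors -------------------------------------------------------

stop_schema <- function(message, ...) {
  abort(message, class = c("dhisdash_schema_error", "dhisdash_error"), ...)
}

stop_domain <- function(message, ...) {
  abort(message, class = c("dhisdash_domain_error", "dhisdash_error"), ...)
}

stop_duplicate <- function(message, ...) {
  abort(message, class = c("dhisdash_duplicate_error", "dhisdash_error"), ...)
}

stop_config <- function(message, ...) {
  abort(message, class = c("dhisdash_config_error", "dhisdash_error"), ...)
}

stop_consistency <- function(message, ...) {
  abort(message, class = c("dhisdash_consistency_error", "dhisdash_error"), ...)
}

# polynomial rolling hash of a serialised object; stable fingerprint used to
# stamp every output table of a run with its configuration
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE,
                        null = "null")
  bytes <- as.integer(charToRaw(as.character(s)))
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", h)
}

# collapse a character vector for error messages
oxford <- function(x, max = 5) {
  x <- as.character(x)
  if (length(x) > max) {
    x <- c(head(x, max), sprintf("... (%d more)", length(x) - max))
  }
  paste(x, collapse = ", ")
}
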