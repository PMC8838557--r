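# Internal helpers shared across modules.

stop_config <- function(msg, ...) {
  abort(msg, class = "wearcheck_config_error", ...)
}

stop_data <- function(msg, ...) {
  abort(msg, class = "wearcheck_data_error", ...)
}

stop_format <- function(msg, ...) {
  abort(msg, class = c("wearcheck_format_error", "wearcheck_data_error"), ...)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == trunc(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Mean of x[a..b] in O(1) given cs = c(0, cumsum(x)).
cumsum_mean <- function(cs, a, b) {
  (cs[b + 1L] - cs[a]) / (b - a + 1L)
}
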