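# Internal helpers shared across stages.

# Consistent condition classes so callers can distinguish bad inputs from bad
# configuration.
stop_input <- function(msg) rlang::abort(msg, class = "rppg_input_error")
stop_config <- function(msg) rlang::abort(msg, class = "rppg_config_error")

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    stop_config(sprintf("`%s` must be in [%g, %g], got %g", name, lower, upper, x))
  }
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Periodic Hann taper for spectral windows.
hann_window <- function(n) {
  if (n <= 1L) return(rep(1, n))
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
}

is_raw_trace <- function(x) inherits(x, "rppg_trace")
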