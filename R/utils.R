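# internal helpers shared across modules

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# frequency -> column label, kHz units throughout ("amp_100kHz" ... "amp_1750kHz")
freq_label <- function(hz, prefix = "amp") {
  paste0(prefix, "_", format(round(hz / 1e3), trim = TRUE, scientific = FALSE), "kHz")
}

pi_label <- function(hz) freq_label(hz, prefix = "pi")

# nearest odd integer >= 3, for runmed windows
odd_window <- function(n) {
  n <- max(3L, as.integer(round(n)))
  if (n %% 2L == 0L) n + 1L else n
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_if_not_scalar_pos <- function(x, name) {
  if (!is_scalar_num(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

# derive independent sub-seeds from one master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
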