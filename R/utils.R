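# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Stop with a classed condition so the CLI can map error categories to exit
# codes without string matching.
abort <- function(msg, class = "epcatr_error", ...) {
  stop(structure(
    class = c(class, "epcatr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

abort_config <- function(msg) abort(msg, class = "epcatr_config_error")
abort_input <- function(msg) abort(msg, class = "epcatr_input_error")

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    abort_config(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && x <= hi
  if (!ok)
    abort_config(sprintf("'%s' must be a single number in %s%g, %g]",
                         name, if (lo_open) "(" else "[", lo, hi))
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    abort_config(sprintf("'%s' must be a single positive number", name))
  as.numeric(x)
}

# Deterministic seed splitting: every stochastic sub-step of a generator gets
# seed = root * 1000 + offset (mod 2^31 - 1) so fixtures are reproducible and
# independent of evaluation order. Offsets are fixed per purpose.
split_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

# Half-away-from-zero rounding (base round() is round-half-even).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Gap between two 0-based half-open intervals; 0 if they overlap or touch.
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

intervals_overlap <- function(s1, e1, s2, e2) {
  pmax(s1, s2) < pmin(e1, e2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
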