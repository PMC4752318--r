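# Condition helpers: every user-facing failure is classed so callers (and the
# CLI exit-code mapping) can distinguish validation, parse, numeric and I/O
# failures without string-matching messages.

stop_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "nrlmf_validation_error")
}

stop_parse <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = c("nrlmf_parse_error", "nrlmf_validation_error"))
}

stop_divergence <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "nrlmf_divergence_error")
}

stop_io <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "nrlmf_io_error")
}

#' Numerically safe log(1 + exp(x))
#'
#' Evaluates `log(1 + exp(x))` without overflow for large positive `x`
#' (where it tends to `x`) and without cancellation for large negative `x`.
#' Inner products grow during training, so the likelihood must stay finite
#' for arguments of magnitude several hundred.
#'
#' @param x numeric vector or matrix.
#' @return object of the same shape as `x`.
#' @keywords internal
log1pexp <- function(x) {
  out <- x  # NaN propagates unchanged so divergence is caught, not masked
  pos <- !is.na(x) & x > 0
  neg <- !is.na(x) & x <= 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[neg] <- log1p(exp(x[neg]))
  out
}

# Round half-up to `digits` decimals (display convention for dataset
# statistics; stored values are full precision).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Deterministic full-precision formatting used by all labeled-matrix writers;
# 17 significant digits round-trip IEEE doubles exactly.
format_num <- function(x) {
  formatC(x, digits = 17, format = "g")
}
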