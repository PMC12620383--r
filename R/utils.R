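# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# truncated-normal draws via inverse CDF; exact, vectorised
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# clamp to scale bounds (truncation, not resampling)
clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)

pm_warn <- function(code, fmt, ...) {
  warning(sprintf("[%s] %s", code, sprintf(fmt, ...)), call. = FALSE)
}

pm_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) >= 1L && all(!is.na(x)) && all(x == floor(x))
}

outcome_col <- function(outcome, wave) paste0(outcome, "_w", wave)
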