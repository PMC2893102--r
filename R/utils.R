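#' @keywords internal
"_PACKAGE"

## Argument checking helpers -------------------------------------------------

stop_arg <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop_arg("`%s` must be a positive integer count (got %s)", name,
             paste(format(x), collapse = ","))
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_arg("`%s` must be a positive number", name)
  as.numeric(x)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_arg("`%s` must lie in [0, 1]", name)
  as.numeric(x)
}

## Derived seeds --------------------------------------------------------------

#' Derive a stream-specific seed from a master seed
#'
#' All stochastic operations in the package draw their seed from one master
#' integer through this function, so that independent stages (layout, copy
#' number, expression, clinical, permutations, bootstrap) use decorrelated
#' streams while the whole analysis stays reproducible from a single seed.
#'
#' @param seed master integer seed.
#' @param stream integer stream index (>= 0).
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  seed <- as.numeric(seed)
  stream <- as.numeric(stream)
  ## 2147483629 is prime; the multiplier keeps nearby master seeds apart
  as.integer((abs(seed) * 48271 + stream * 16807 + 1) %% 2147483629)
}

## Percentage formatting used by bookkeeping summaries ------------------------

#' Percentage to one decimal place
#'
#' Bookkeeping summaries (transcripts retained after filtering, transcripts
#' mapped from at least five SNPs) report percentages rounded to one decimal,
#' e.g. 23484 of 54675 is 43.0.
#'
#' @param numerator,denominator non-negative counts.
#' @return numeric percentage rounded to one decimal place.
#' @export
percent1 <- function(numerator, denominator) {
  if (denominator <= 0) stop_arg("`denominator` must be positive")
  round(100 * numerator / denominator, 1)
}

## Kaplan-Meier survival at a time point --------------------------------------

## Product-limit estimate S(t); step function carried beyond the last
## observed time. Kept as a minimal internal evaluator because the
## time-dependent ROC loops it over every score cutpoint; unit tests check it
## against survival::survfit.
km_surv_at <- function(time, event, t) {
  stopifnot(length(time) == length(event))
  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  ut <- unique(time[event > 0 & time <= t])
  if (length(ut) == 0L) return(1)
  n <- length(time)
  s <- 1
  for (tt in ut) {
    d <- sum(time == tt & event > 0)
    at_risk <- sum(time >= tt)
    s <- s * (1 - d / at_risk)
  }
  s
}
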