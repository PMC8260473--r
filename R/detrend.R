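#' Fit a baseline drift model to a trace
#'
#' Photobleaching, indicator loss and cell damage produce slow baseline drift.
#' A second-degree polynomial in time captures both linear and (over the span
#' of a recording) exponential drifts. The polynomial is fitted to
#' baseline-phase samples only — within each pacing cycle, the values in the
#' lowest quartile — so transient peaks do not bias the trend.
#'
#' @param trace a [ca_trace()] spanning at least 2 full pacing cycles.
#' @param pacing_hz pacing frequency in Hz.
#' @return an object of class `ca_drift`: coefficients `(c2, c1, c0)` of the
#'   trend in time (ms), the fitted trend, and the diagnostic
#'   `slope_fraction` = (trend change over the trace) / (initial baseline).
#' @export
fit_drift <- function(trace, pacing_hz) {
  stopifnot(inherits(trace, "ca_trace"))
  v <- trace$values
  n <- length(v)
  cyc <- trace$fps / pacing_hz
  if (n < 2 * cyc) stop("trace must span at least 2 full pacing cycles", call. = FALSE)
  t_ms <- trace_times_ms(trace)
  starts <- seq(1, n - floor(cyc) + 1, by = floor(cyc))
  sel <- unlist(lapply(starts, function(s) {
    w <- s:min(n, s + floor(cyc) - 1)
    w[v[w] <= quantile(v[w], 0.25)]
  }))
  sel <- sort(unique(sel))
  if (length(sel) < 3) stop("fewer than 3 baseline samples for drift fit", call. = FALSE)
  fit <- lm(y ~ x + I(x^2), data = data.frame(x = t_ms[sel], y = v[sel]))
  co <- coef(fit)
  trend <- co[1] + co[2] * t_ms + co[3] * t_ms^2
  slope_fraction <- (trend[n] - trend[1]) / trend[1]
  structure(list(coefficients = c(c2 = unname(co[3]), c1 = unname(co[2]),
                                  c0 = unname(co[1])),
                 trend = trend, applied = FALSE,
                 slope_fraction = unname(slope_fraction)),
            class = "ca_drift")
}

#' @export
print.ca_drift <- function(x, ...) {
  cat(sprintf("<ca_drift> trend change %.2f%% of initial baseline%s\n",
              100 * x$slope_fraction, if (x$applied) " (applied)" else ""))
  invisible(x)
}

#' Remove a fitted drift trend from a trace
#'
#' Subtracts the trend re-anchored at its first-frame value, so the absolute
#' intensity scale of the trace is preserved and a drift-free trace is
#' unchanged up to the (near-zero) fitted curvature.
#'
#' @param trace the [ca_trace()] the model was fitted on.
#' @param model a `ca_drift` from [fit_drift()].
#' @return the detrended [ca_trace()] with `detrended = TRUE`.
#' @export
detrend <- function(trace, model) {
  stopifnot(inherits(trace, "ca_trace"), inherits(model, "ca_drift"))
  if (length(model$trend) != length(trace$values))
    stop("drift model was fitted on a trace of different length", call. = FALSE)
  trace$values <- trace$values - (model$trend - model$trend[1])
  trace$detrended <- TRUE
  trace
}

#' Photobleach correction policy
#'
#' Applies [fit_drift()] + [detrend()] according to the configured mode:
#' `"off"` returns the trace bit-identically, `"force"` always corrects, and
#' `"auto"` corrects only when the fitted trend changes by more than
#' `drift_trigger_fraction` (default 3%) of the initial baseline.
#'
#' @param trace a [ca_trace()].
#' @param config a [ca_config()].
#' @return list with the (possibly corrected) `trace` and the `ca_drift`
#'   `model` (NULL in off mode).
#' @export
correct_photobleach <- function(trace, config) {
  if (config$photobleach_correct == "off")
    return(list(trace = trace, model = NULL))
  model <- fit_drift(trace, config$pacing_hz)
  apply_it <- config$photobleach_correct == "force" ||
    abs(model$slope_fraction) > config$drift_trigger_fraction
  if (apply_it) {
    trace <- detrend(trace, model)
    model$applied <- TRUE
  }
  list(trace = trace, model = model)
}
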