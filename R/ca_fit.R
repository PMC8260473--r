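#' Analyze a calcium transient trace
#'
#' The full per-cell pipeline: optional photobleach detrending, onset
#' detection on the frame-to-frame difference array (through the decimated
#' path at high acquisition rates), beat segmentation, averaging, kinetic
#' parameter interpolation, exponential tau fitting, SNR quality control,
#' pacing-adherence checking and EAD/DAD-like aberration detection. When
#' irregular beats are found and `config$exclude_irregular` is TRUE (the
#' default), parameters are recomputed on the regular beats only.
#'
#' Every failure mode (flat trace, no detectable onsets, failed tau fit)
#' produces a flagged record rather than an error, so a multi-cell run never
#' aborts on one bad cell.
#'
#' @param trace a [ca_trace()].
#' @param config a [ca_config()].
#' @param onsets optional manual onset override: frame indices of known
#'   pacing events, bypassing difference-array detection.
#' @return an object of class `ca_fit` with components `params` (the
#'   [compute_parameters()] record including tau and SNR), `avg`, `segments`,
#'   `onsets`, `irregularity`, `drift`, `per_beat` (when requested) and
#'   `flags`. Methods: `print`, `summary`, `coef`, `plot`, `residuals`,
#'   `fitted`, `simulate`.
#' @export
#' @examples
#' spec <- waveform_spec(pacing_hz = 1, n_beats = 5, fps = 100)
#' tr <- make_transient_trace(spec)$trace
#' fit <- ca_analyze(tr, ca_config(pacing_hz = 1))
#' coef(fit)["tau"]
ca_analyze <- function(trace, config = ca_config(), onsets = NULL) {
  stopifnot(inherits(trace, "ca_trace"))
  validate_config(config)
  flags <- character(0)

  drift <- NULL
  if (config$photobleach_correct != "off") {
    corr <- tryCatch(correct_photobleach(trace, config), error = function(e) {
      flags <<- c(flags, paste0("drift_fit_failed: ", conditionMessage(e)))
      list(trace = trace, model = NULL)
    })
    trace <- corr$trace
    drift <- corr$model
  }

  manual_onsets <- !is.null(onsets)
  if (manual_onsets) {
    onsets <- as.integer(onsets)
    da <- NULL
  } else {
    onsets <- detect_onsets(trace, config)
    da <- attr(onsets, "diff")
    onsets <- as.integer(onsets)
  }
  if (length(onsets) == 0) {
    return(flagged_fit(trace, config, c(flags, "no_onsets_detected"), drift))
  }

  segments <- tryCatch(segment_transients(trace, onsets, config),
                       error = function(e) list())
  if (length(segments) == 0) {
    return(flagged_fit(trace, config, c(flags, "no_complete_segments"), drift))
  }
  if (any(vapply(segments, function(s) s$clamped, logical(1))))
    flags <- c(flags, "segment_clamped_at_start")

  avg <- average_transient(segments)
  params <- compute_parameters(avg, config, trace$fps)
  flags <- union(flags, params$flags)

  # quality control on the whole (corrected) trace against the baseline
  snr <- signal_to_noise(trace, params$f0, config$snr_warn_threshold)
  if (!is.null(attr(snr, "flag"))) flags <- union(flags, attr(snr, "flag"))
  below <- trace$values[trace$values < params$f0]
  noise_sd <- if (length(below) >= 2) sd(below) else 0
  trace$snr <- as.numeric(snr)

  peak_times_ms <- vapply(segments, function(s) {
    (s$start_frame - 1 + which.max(s$values) - 1) * 1000 / trace$fps
  }, numeric(1))
  duration_s <- length(trace$values) / trace$fps
  adheres <- check_pacing_adherence(length(onsets), config$pacing_hz, duration_s)
  if (!isTRUE(as.logical(adheres))) flags <- union(flags, "pacing_non_adherent")

  events <- detect_aberrations(segments, params, config, trace$fps,
                               noise_sd = noise_sd, snr = as.numeric(snr))
  if (isTRUE(attr(events, "skipped"))) flags <- union(flags, "aberration_detection_skipped")
  report <- irregularity_report(segments, events, adheres, peak_times_ms)

  used_avg <- avg
  if (length(events) > 0 && config$exclude_irregular) {
    reg <- analyze_regular_subset(segments, events, config, trace$fps)
    if (length(reg$regular_beats) > 0) {
      params <- reg$params
      used_avg <- reg$avg
      flags <- union(flags, "irregular_beats_excluded")
    } else {
      flags <- union(flags, "all_beats_irregular")
    }
  }

  tf <- fit_tau(used_avg, params, trace$fps)
  params$tau <- tf$tau
  params$fit_a <- tf$a; params$fit_b <- tf$b; params$fit_c <- tf$c
  params$fit_gof <- tf$gof
  if (!is.null(tf$flag)) flags <- union(flags, tf$flag)
  params$snr <- as.numeric(snr)
  params$beat_to_beat_ms <- report$beat_to_beat_ms
  params$n_intervals <- report$n_intervals
  params$n_beats <- used_avg$n_beats
  params$flags <- flags

  per_beat <- NULL
  if (config$per_beat_output && length(segments) >= 1) {
    pb <- lapply(segments, function(s) {
      pp <- compute_parameters(s, config, trace$fps)
      ptf <- fit_tau(s, pp, trace$fps)
      pp$tau <- ptf$tau; pp$fit_a <- ptf$a; pp$fit_b <- ptf$b
      pp$fit_c <- ptf$c; pp$fit_gof <- ptf$gof
      pp
    })
    num <- vapply(pb, function(p) {
      vapply(PARAMETER_COLUMNS, function(cn) {
        v <- p[[cn]]; if (is.null(v) || length(v) != 1) NA_real_ else as.numeric(v)
      }, numeric(1))
    }, numeric(length(PARAMETER_COLUMNS)))
    sds <- apply(matrix(num, nrow = length(PARAMETER_COLUMNS)), 1, sd, na.rm = TRUE)
    names(sds) <- PARAMETER_COLUMNS
    per_beat <- list(params = pb, sd = sds)
  }

  structure(list(trace = trace, config = config, onsets = onsets,
                 diff = da, segments = segments, avg = avg, used_avg = used_avg,
                 params = params, per_beat = per_beat, irregularity = report,
                 drift = drift, flags = flags),
            class = "ca_fit")
}

flagged_fit <- function(trace, config, flags, drift = NULL) {
  p <- structure(list(f0 = NA_real_, fmax = NA_real_, magnitude = NA_real_,
                      fmax_over_f0 = NA_real_, tau = NA_real_, snr = NA_real_,
                      n_beats = 0L, flags = flags), class = "ca_params")
  structure(list(trace = trace, config = config, onsets = integer(0),
                 diff = NULL, segments = list(), avg = NULL, used_avg = NULL,
                 params = p, per_beat = NULL, irregularity = NULL,
                 drift = drift, flags = flags),
            class = "ca_fit")
}

#' Is a fit flagged as unusable?
#' @param fit a `ca_fit`.
#' @return TRUE when the record carries no usable parameters.
#' @export
is_flagged <- function(fit) {
  is.null(fit$avg) || !is.finite(fit$params$magnitude) || fit$params$magnitude <= 0
}

#' @export
print.ca_fit <- function(x, ...) {
  cat(sprintf("Calcium transient analysis: cell %d, %d beat(s) @ %g FPS, pacing %g Hz\n",
              x$trace$cell_id, length(x$segments), x$trace$fps, x$config$pacing_hz))
  print(x$params)
  invisible(x)
}

#' @export
summary.ca_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.ca_fit")
}

#' @export
print.summary.ca_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (!is.null(f$drift))
    cat(sprintf("Drift: trend change %.2f%% of baseline (%s)\n",
                100 * f$drift$slope_fraction,
                if (f$drift$applied) "corrected" else "not corrected"))
  if (!is.null(f$irregularity)) print(f$irregularity)
  if (!is.null(f$per_beat)) {
    cat("Per-beat SD (quality control):\n")
    sds <- f$per_beat$sd
    print(round(sds[c("tau", "t50_on", "t50_off", "cd", "fmax_over_f0")], 3))
  }
  invisible(x)
}

#' @export
coef.ca_fit <- function(object, ...) {
  p <- object$params
  vapply(PARAMETER_COLUMNS, function(cn) {
    v <- p[[cn]]; if (is.null(v) || length(v) != 1) NA_real_ else as.numeric(v)
  }, numeric(1))
}

#' @export
fitted.ca_fit <- function(object, ...) {
  if (is_flagged(object)) return(numeric(0))
  v <- object$used_avg$values
  ip <- which.max(v)
  p <- object$params
  if (!is.finite(p$fit_b)) return(numeric(0))
  t_ms <- (seq_len(length(v) - ip + 1) - 1) * 1000 / object$trace$fps
  p$fit_a * exp(p$fit_b * t_ms) + p$fit_c
}

#' @export
residuals.ca_fit <- function(object, ...) {
  f <- fitted(object)
  if (length(f) == 0) return(numeric(0))
  v <- object$used_avg$values
  v[(which.max(v)):length(v)] - f
}

#' @export
plot.ca_fit <- function(x, which = c("trace", "average"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  if ("trace" %in% which) {
    t_ms <- trace_times_ms(x$trace)
    plot(t_ms, x$trace$values, type = "l", xlab = "time (ms)",
         ylab = "fluorescence (AU)", main = "trace with detected onsets", ...)
    if (length(x$onsets)) abline(v = (x$onsets - 1) * 1000 / x$trace$fps,
                                 col = "red", lty = 3)
  }
  if ("average" %in% which && !is_flagged(x)) {
    v <- x$used_avg$values
    t_ms <- (seq_along(v) - 1) * 1000 / x$trace$fps
    plot(t_ms, v, type = "l", xlab = "time within beat (ms)",
         ylab = "fluorescence (AU)", main = "averaged transient", ...)
    abline(h = x$params$redefined_baseline, col = "grey", lty = 2)
    f <- fitted(x)
    if (length(f)) lines(t_ms[(which.max(v)):length(v)], f, col = "blue")
  }
  invisible(x)
}

#' @export
simulate.ca_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is_flagged(object)) stop("cannot simulate from a flagged fit", call. = FALSE)
  p <- object$params
  tau <- if (is.finite(p$tau)) p$tau else 300
  t_on <- if (is.finite(p$t_on) && p$t_on > 0) p$t_on else 70
  # rise time constant with matching time-to-peak: tp = tau_on*log(1+tau/tau_on)
  tau_on <- tryCatch(
    stats::uniroot(function(s) s * log(1 + tau / s) - t_on,
                   interval = c(1e-3, 10 * t_on))$root,
    error = function(e) t_on / 3)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    spec <- waveform_spec(pacing_hz = object$config$pacing_hz,
                          n_beats = max(1L, length(object$segments)),
                          fps = object$trace$fps,
                          baseline = p$f0, magnitude = p$magnitude,
                          tau_on = tau_on, tau_off = tau,
                          seed = if (is.null(seed)) i else seed + i - 1)
    make_transient_trace(spec)$trace
  })
}
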