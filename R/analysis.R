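#' Frame-to-frame difference array and transient onsets
#'
#' The trace is converted to the array of differences of each intensity value
#' with its previous value, `d[i] = values[i+1] - values[i]`. The steep
#' upstroke of every calcium transient produces a prominent peak in `d`; peaks
#' with prominence at least `prominence_fraction` (default 50%) of the
#' maximum observed prominence are taken as transient onsets. Onset indices
#' refer to the parent trace (the frame at the top of the difference peak).
#'
#' @param trace a [ca_trace()].
#' @param prominence_fraction relative prominence threshold in (0,1).
#' @return an object of class `ca_diff`: the difference array `d`, the
#'   thresholded `peak_indices` (into the parent trace), their prominences,
#'   and a diagnostic when no peak is found.
#' @export
difference_array <- function(trace, prominence_fraction = 0.5) {
  v <- if (inherits(trace, "ca_trace")) trace$values else as.numeric(trace)
  if (length(v) < 2) stop("trace too short for a difference array", call. = FALSE)
  d <- diff(v)
  pp <- prominent_peaks(d, prominence_fraction)
  diagnostic <- if (length(pp$peaks) == 0) "no prominent peaks in difference array" else NULL
  structure(list(d = d,
                 peak_indices = pp$peaks + 1L,  # frame at the top of the jump
                 prominence = pp$prominence,
                 diagnostic = diagnostic),
            class = "ca_diff")
}

#' @export
print.ca_diff <- function(x, ...) {
  cat(sprintf("<ca_diff> %d samples, %d onset(s) at frames: %s\n",
              length(x$d), length(x$peak_indices),
              paste(head(x$peak_indices, 10), collapse = ", ")))
  invisible(x)
}

#' Decimate a trace for onset detection
#'
#' At very high acquisition rates the frame-to-frame differences shrink and
#' onset peaks lose prominence against noise. Traces faster than `target_fps`
#' are block-averaged down to (approximately) the target rate solely for
#' onset detection; parameters are always measured on the native-rate data.
#'
#' @param trace a [ca_trace()].
#' @param target_fps decimation target in Hz (default 100).
#' @return the decimated [ca_trace()] with attribute `factor` (the integer
#'   decimation factor); the trace itself when `fps <= target_fps`.
#' @export
downsample_for_onsets <- function(trace, target_fps = 100) {
  stopifnot(inherits(trace, "ca_trace"))
  if (trace$fps <= target_fps) {
    attr(trace, "factor") <- 1L
    return(trace)
  }
  k <- max(2L, as.integer(floor(trace$fps / target_fps)))
  n <- length(trace$values)
  nb <- n %/% k
  v <- colMeans(matrix(trace$values[seq_len(nb * k)], nrow = k))
  out <- ca_trace(v, fps = trace$fps / k, cell_id = trace$cell_id)
  attr(out, "factor") <- k
  out
}

#' Detect transient onsets in a trace
#'
#' Runs [difference_array()] onset detection, via the decimated path of
#' [downsample_for_onsets()] when the acquisition rate exceeds
#' `config$downsample_target_fps`. Onsets found on the decimated trace are
#' mapped back to the native-rate frame at the center of the decimation
#' block. No native-rate refinement is attempted: at high rates the
#' frame-to-frame differences are noise-dominated, which is the very reason
#' detection runs on the decimated trace.
#'
#' @param trace a [ca_trace()].
#' @param config a [ca_config()].
#' @return integer vector of onset frame indices into `trace` (possibly
#'   empty), with the `ca_diff` object as attribute `diff`.
#' @export
detect_onsets <- function(trace, config) {
  ds <- downsample_for_onsets(trace, config$downsample_target_fps)
  k <- attr(ds, "factor")
  da <- difference_array(ds, config$prominence_fraction)
  onsets <- da$peak_indices
  if (k > 1L && length(onsets) > 0) {
    onsets <- (onsets - 1L) * k + as.integer(ceiling((k + 1) / 2))
    onsets <- sort(unique(pmin(onsets, length(trace$values))))
  }
  structure(onsets, diff = da)
}

#' Crop individual transients from a trace
#'
#' Each detected onset starts a segment at `onset - offset` and ends just
#' before the next onset's start, where `offset` is 10% of the pacing cycle
#' (100 ms at 1 Hz) by default. The final onset yields a segment running to
#' the trace end when at least a full cycle remains, and is dropped otherwise.
#' Segments that would start before the first frame are clamped to frame 1
#' and flagged.
#'
#' @param trace a [ca_trace()].
#' @param onsets integer onset frames from [detect_onsets()], or a `ca_diff`.
#' @param config a [ca_config()].
#' @return list of `ca_segment` objects: `values`, `start_frame`,
#'   `end_frame`, `beat_index`, `onset_frame`, `clamped`.
#' @export
segment_transients <- function(trace, onsets, config) {
  if (inherits(onsets, "ca_diff")) onsets <- onsets$peak_indices
  onsets <- as.integer(onsets)
  if (length(onsets) == 0) stop("no onsets to segment", call. = FALSE)
  n <- length(trace$values)
  cycle_frames <- trace$fps / config$pacing_hz
  offset <- round(config$onset_offset_fraction * cycle_frames)
  starts <- onsets - offset
  clamped <- starts < 1L
  starts[clamped] <- 1L
  segs <- list()
  for (b in seq_along(onsets)) {
    s <- starts[b]
    if (b < length(onsets)) {
      e <- starts[b + 1] - 1L
    } else {
      # keep the final beat when a full cycle (to within one frame) remains
      if (n - s + 1 < floor(cycle_frames) - 1L) break
      e <- min(n, s + as.integer(ceiling(cycle_frames)) - 1L)
    }
    if (e <= s) next
    segs[[length(segs) + 1]] <- structure(
      list(values = trace$values[s:e], start_frame = s, end_frame = e,
           beat_index = b, onset_frame = onsets[b], clamped = clamped[b]),
      class = "ca_segment")
  }
  segs
}

#' Average aligned transient segments
#'
#' Segments are aligned at their start (onset-anchored) and truncated to the
#' shortest before the pointwise mean and SD are taken. Averaging across
#' beats suppresses uncorrelated noise by roughly the square root of the
#' number of beats.
#'
#' @param segments list of `ca_segment` from [segment_transients()].
#' @return object of class `ca_avg`: `values`, `per_beat_sd`, `n_beats`.
#' @export
average_transient <- function(segments) {
  if (length(segments) == 0) stop("no segments to average", call. = FALSE)
  len <- min(vapply(segments, function(s) length(s$values), integer(1)))
  m <- vapply(segments, function(s) s$values[seq_len(len)], numeric(len))
  m <- matrix(m, nrow = len)
  structure(list(values = rowMeans(m),
                 per_beat_sd = if (ncol(m) > 1) apply(m, 1, sd) else rep(0, len),
                 n_beats = length(segments)),
            class = "ca_avg")
}

# linear interpolation of the first upward crossing of `thr` in v[1..ip]
# returns fractional frame index (1-based) or NA; attr n_crossings
first_rise_crossing <- function(v, ip, thr) {
  if (ip < 1) return(NA_real_)
  if (v[1] >= thr) return(structure(1, n_crossings = 0L))  # already above at start
  idx <- which(v[seq_len(ip - 1)] < thr & v[2:ip] >= thr)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  frac <- (thr - v[i]) / (v[i + 1] - v[i])
  structure(i + frac, n_crossings = length(idx))
}

# first downward crossing of `thr` in v[ip..n]
first_fall_crossing <- function(v, ip, thr) {
  n <- length(v)
  if (ip >= n) return(NA_real_)
  w <- ip:(n - 1)
  idx <- which(v[w] > thr & v[w + 1] <= thr)
  if (length(idx) == 0) return(NA_real_)
  i <- w[idx[1]]
  frac <- (v[i] - thr) / (v[i] - v[i + 1])
  structure(i + frac, n_crossings = length(idx))
}

#' Kinetic parameters of an averaged transient
#'
#' The baseline F0 is the mean of the final window of the cycle (20% of the
#' cycle length by default), the peak Fmax is the maximum sample, and the
#' magnitude is Fmax - F0. Because traces may not have fully decayed at the
#' cycle end, a redefined baseline F0 + 0.03 x magnitude (and the magnitude
#' recalculated against it) is used for all interpolated timing parameters:
#' rising-limb times are linear interpolations of the first crossings of 0%,
#' 10%, 50% and 90% of the recalculated magnitude, measured from the 0%
#' crossing (the transient foot, T0); T_on is the time from T0 to the first
#' sample attaining Fmax. Falling-limb times are measured from the peak sample
#' to the interpolated crossings of 90%, 50%, 10% and 0% remaining (i.e. 10,
#' 50, 90 and 100% decay). The transient duration CD runs from T0 to full
#' decay, so CD = T_on + T_off. Noise-induced multiple crossings take the
#' first crossing and raise a flag.
#'
#' @param avg a `ca_avg` from [average_transient()] (or a `ca_segment` in
#'   per-beat mode).
#' @param config a [ca_config()].
#' @param fps native acquisition rate in Hz.
#' @return object of class `ca_params`; all times in ms. Degenerate inputs
#'   (zero magnitude) yield a flagged record, never an error.
#' @export
compute_parameters <- function(avg, config, fps) {
  v <- avg$values
  n <- length(v)
  dt_ms <- 1000 / fps
  flags <- character(0)
  k <- max(1L, round(config$baseline_window_fraction * fps / config$pacing_hz))
  k <- min(k, n)
  f0 <- mean(v[(n - k + 1):n])
  fmax <- max(v)
  ip <- which.max(v)
  magnitude <- fmax - f0
  empty <- list(f0 = f0, fmax = fmax, magnitude = magnitude,
                fmax_over_f0 = if (f0 > 0) fmax / f0 else NA_real_,
                redefined_baseline = NA_real_,
                t_on = NA_real_, t10_on = NA_real_, t50_on = NA_real_,
                t90_on = NA_real_, t_off = NA_real_, t10_off = NA_real_,
                t50_off = NA_real_, t90_off = NA_real_, cd = NA_real_,
                tau = NA_real_, fit_a = NA_real_, fit_b = NA_real_,
                fit_c = NA_real_, fit_gof = NA_real_, snr = NA_real_,
                n_beats = if (!is.null(avg$n_beats)) avg$n_beats else 1L,
                beat_to_beat_ms = NA_real_, n_intervals = NA_real_,
                peak_frame = ip, t0_frame = NA_real_, flags = flags)
  if (!is.finite(magnitude) || magnitude <= 0) {
    empty$flags <- c(flags, "zero_magnitude")
    return(structure(empty, class = "ca_params"))
  }
  b2 <- f0 + config$baseline_redefine_fraction * magnitude
  m2 <- fmax - b2
  p <- empty
  p$redefined_baseline <- b2

  cross_t <- function(x) if (is.na(x)) NA_real_ else as.numeric(x - 1) * dt_ms
  note_multi <- function(cr) {
    nc <- attr(cr, "n_crossings")
    if (!is.null(nc) && nc > 1) flags <<- union(flags, "multi_crossing")
    cr
  }
  t0 <- note_multi(first_rise_crossing(v, ip, b2))
  r10 <- note_multi(first_rise_crossing(v, ip, b2 + 0.1 * m2))
  r50 <- note_multi(first_rise_crossing(v, ip, b2 + 0.5 * m2))
  r90 <- note_multi(first_rise_crossing(v, ip, b2 + 0.9 * m2))
  ip_first <- which(v == fmax)[1]
  if (is.na(t0)) {
    flags <- union(flags, "no_onset_crossing")
    p$flags <- flags
    return(structure(p, class = "ca_params"))
  }
  p$t0_frame <- t0
  p$t_on <- cross_t(ip_first) - cross_t(t0)
  p$t10_on <- cross_t(r10) - cross_t(t0)
  p$t50_on <- cross_t(r50) - cross_t(t0)
  p$t90_on <- cross_t(r90) - cross_t(t0)

  f90 <- note_multi(first_fall_crossing(v, ip, b2 + 0.9 * m2))
  f50 <- note_multi(first_fall_crossing(v, ip, b2 + 0.5 * m2))
  f10 <- note_multi(first_fall_crossing(v, ip, b2 + 0.1 * m2))
  f00 <- note_multi(first_fall_crossing(v, ip, b2))
  tp_ms <- cross_t(ip)
  p$t10_off <- cross_t(f90) - tp_ms
  p$t50_off <- cross_t(f50) - tp_ms
  p$t90_off <- cross_t(f10) - tp_ms
  p$t_off <- cross_t(f00) - tp_ms
  if (is.na(p$t_off)) flags <- union(flags, "incomplete_decay")
  p$cd <- if (!is.na(p$t_off)) (cross_t(f00) - cross_t(t0)) else NA_real_
  p$flags <- flags
  structure(p, class = "ca_params")
}

#' @export
print.ca_params <- function(x, ...) {
  cat("<ca_params>\n")
  cat(sprintf("  F0 %.4g | Fmax %.4g | Fmax/F0 %.4g | magnitude %.4g\n",
              x$f0, x$fmax, x$fmax_over_f0, x$magnitude))
  cat(sprintf("  T_on %.1f ms (10/50/90: %.1f/%.1f/%.1f) | T_off %.1f ms (10/50/90: %.1f/%.1f/%.1f)\n",
              x$t_on, x$t10_on, x$t50_on, x$t90_on,
              x$t_off, x$t10_off, x$t50_off, x$t90_off))
  cat(sprintf("  CD %.1f ms | tau %.1f ms (R2 %.4f) | SNR %.3g\n",
              x$cd, x$tau, if (is.na(x$fit_gof)) NA else x$fit_gof, x$snr))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Exponential fit of the transient decay (tau)
#'
#' Fits `f(t) = a * exp(b * t) + c` (with `b < 0`) by nonlinear least squares
#' to the decaying arm of the averaged transient, from the peak sample to the
#' end of the cycle, and reports `tau = -1/b` in ms together with the
#' coefficient of determination of the fit. Initialization uses the half-life
#' heuristic `b = -ln(2) / T50_off`, `a` = recalculated magnitude, `c` =
#' redefined baseline. Non-convergence, or a non-decaying fit, yields missing
#' tau with a flag rather than an error.
#'
#' @param avg a `ca_avg` (or any object with `$values`).
#' @param params the `ca_params` of the same transient (for initialization).
#' @param fps acquisition rate in Hz.
#' @return list `tau`, `a`, `b`, `c` (time unit ms), `gof`, `flag`.
#' @export
fit_tau <- function(avg, params, fps) {
  v <- avg$values
  ip <- which.max(v)
  if (length(v) - ip + 1 < 5)
    return(list(tau = NA_real_, a = NA_real_, b = NA_real_, c = NA_real_,
                gof = NA_real_, flag = "decay_arm_too_short"))
  y <- v[ip:length(v)]
  t_ms <- (seq_along(y) - 1) * 1000 / fps
  b0 <- if (!is.null(params$t50_off) && is.finite(params$t50_off) && params$t50_off > 0)
    -log(2) / params$t50_off else -4 / max(t_ms)
  a0 <- max(y) - min(y)
  c0 <- min(y)
  if (!is.null(params$redefined_baseline) && is.finite(params$redefined_baseline)) {
    c0 <- params$redefined_baseline
    a0 <- max(y) - c0
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(b * t_ms) + c,
                      start = list(a = a0, b = b0, c = c0),
                      lower = c(a = 0, b = -Inf, c = -Inf),
                      upper = c(a = Inf, b = -1e-9, c = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(tau = NA_real_, a = NA_real_, b = NA_real_, c = NA_real_,
                gof = NA_real_, flag = "tau_fit_failed"))
  co <- coef(fit)
  if (co[["b"]] >= 0)
    return(list(tau = NA_real_, a = co[["a"]], b = co[["b"]], c = co[["c"]],
                gof = NA_real_, flag = "non_decaying_fit"))
  rss <- sum(residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  gof <- if (tss > 0) 1 - rss / tss else NA_real_
  tau <- -1 / co[["b"]]
  flag <- NULL
  # model-mismatch QC: a near-linear arm drives b toward 0 (tau far beyond
  # the observation window), and a bad fit shows in the R^2
  if (tau > 10 * max(t_ms)) flag <- "tau_implausible"
  else if (is.finite(gof) && gof < 0.95) flag <- "poor_fit"
  list(tau = tau, a = co[["a"]], b = co[["b"]], c = co[["c"]],
       gof = gof, flag = flag)
}
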