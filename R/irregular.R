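#' Check adherence to the pacing protocol
#'
#' A trace adheres to pacing when the number of detected onsets does not
#' exceed what the pacing frequency justifies over the recording duration
#' (plus a tolerance of one for a beat straddling the recording edge). More
#' onsets than paced stimuli indicate spontaneous or triggered activity.
#'
#' @param n_onsets number of detected onsets (or a `ca_diff`).
#' @param pacing_hz pacing frequency in Hz.
#' @param duration_s recording duration in seconds.
#' @param tolerance extra onsets allowed (default 1).
#' @return logical; FALSE with attribute `flag = "empty_trace"` when no onset
#'   was detected at all.
#' @export
check_pacing_adherence <- function(n_onsets, pacing_hz, duration_s, tolerance = 1) {
  if (inherits(n_onsets, "ca_diff")) n_onsets <- length(n_onsets$peak_indices)
  if (n_onsets == 0) return(structure(FALSE, flag = "empty_trace"))
  n_onsets <= ceiling(pacing_hz * duration_s) + tolerance
}

#' Detect EAD/DAD-like aberrations within beats
#'
#' Scans each beat for secondary positive deflections after the primary peak.
#' A deflection qualifies when its prominence is at least
#' `aberration_prominence_fraction` (default 10%) of the beat's recalculated
#' magnitude *and* at least `aberration_sd_multiple` (default 3) times the
#' below-baseline SD, guarding against noise. Qualifying events occurring
#' before the trace has returned to the redefined baseline are classified as
#' early afterdepolarization-like (EAD); events after the return but before
#' the next onset as delayed afterdepolarization-like (DAD). The beat is
#' lightly smoothed (~30 ms centered moving average) before peak finding so
#' single-sample noise cannot masquerade as an event. Detection requires
#' adequate SNR and is skipped (with a quality flag) below the warning
#' threshold.
#'
#' @param segments list of `ca_segment`.
#' @param params a `ca_params` context (redefined baseline, magnitude) from
#'   the averaged transient.
#' @param config a [ca_config()].
#' @param fps acquisition rate in Hz.
#' @param noise_sd below-baseline SD of the trace (the SNR denominator); 0
#'   for noiseless input.
#' @param snr trace SNR; detection is skipped when below the warn threshold.
#' @return list of events `(beat, class, frame, time_ms, prominence)`, with
#'   attribute `skipped = TRUE` when SNR was insufficient.
#' @export
detect_aberrations <- function(segments, params, config, fps,
                               noise_sd = 0, snr = Inf) {
  if (is.finite(snr) && snr < config$snr_warn_threshold)
    return(structure(list(), skipped = TRUE))
  if (!is.finite(params$magnitude) || params$magnitude <= 0 ||
      !is.finite(params$redefined_baseline))
    return(structure(list(), skipped = TRUE))
  m2 <- params$fmax - params$redefined_baseline
  thr <- max(config$aberration_prominence_fraction * m2,
             config$aberration_sd_multiple * noise_sd)
  smooth_w <- max(3L, round(0.030 * fps))
  events <- list()
  add_event <- function(beat, cls, fr, prom) {
    events[[length(events) + 1]] <<- list(
      beat = beat, class = cls, frame = fr,
      time_ms = (fr - 1) * 1000 / fps, prominence = prom)
  }
  for (k in seq_along(segments)) {
    seg <- segments[[k]]
    v <- moving_average(seg$values, smooth_w)
    ip <- which.max(v)
    if (ip >= length(v) - 1) next
    post <- v[ip:length(v)]
    # frame (post coords) where the decay first returns to the redefined baseline
    ret <- which(post <= params$redefined_baseline)
    ret <- if (length(ret) == 0) length(post) + 1L else ret[1]

    # EAD scan: decay limb before the return, on the decay-compensated
    # residual so a bump's full height counts against the threshold
    resid <- post - fit_decay_envelope(post, fps)
    ead_end <- min(ret, length(post))
    pk <- local_maxima(resid[seq_len(ead_end)])
    if (length(pk) > 0) {
      prom <- peak_prominence(resid[seq_len(ead_end)], pk)
      for (j in which(prom >= thr & pk > smooth_w)) # skip the main-peak shoulder
        add_event(seg$beat_index, "EAD", seg$start_frame + ip - 1L + pk[j] - 1L,
                  prom[j])
    }

    # DAD scan: diastolic window stitched across the segment boundary, from
    # the return to the next beat's onset (its head lives in segment k + 1)
    if (ret <= length(post)) {
      d_start <- seg$start_frame + ip - 1L + ret - 1L
      d_end <- seg$end_frame
      if (k < length(segments)) {
        nxt <- segments[[k + 1]]
        # stop ~30 ms short of the next onset: the detected onset lags the
        # true rise start, and the upstroke must not enter the window
        pre_end <- nxt$onset_frame - nxt$start_frame - smooth_w
        if (pre_end >= 1) d_end <- nxt$start_frame + pre_end - 1L
      }
      diast_raw <- c(seg$values[(ip + ret - 1L):length(seg$values)],
                     if (k < length(segments) && d_end >= segments[[k + 1]]$start_frame)
                       segments[[k + 1]]$values[seq_len(d_end - segments[[k + 1]]$start_frame + 1L)])
      if (length(diast_raw) >= 3) {
        diast <- moving_average(diast_raw, min(smooth_w, length(diast_raw)))
        # the diastolic tail still declines slowly; remove the linear trend so
        # the decline itself cannot register as prominence
        idx <- seq_along(diast)
        diast <- diast - fitted(lm(diast ~ idx))
        pk <- local_maxima(diast)
        if (length(pk) > 0) {
          prom <- peak_prominence(diast, pk)
          for (j in which(prom >= thr))
            add_event(seg$beat_index, "DAD", d_start + pk[j] - 1L, prom[j])
        }
      }
    }
  }
  events[order(vapply(events, function(e) e$frame, numeric(1)))]
}

# Exponential decay baseline of a post-peak arm, for bump compensation.
# Falls back to the arm itself (no compensation) if the fit cannot be made.
fit_decay_envelope <- function(post, fps) {
  t_ms <- (seq_along(post) - 1) * 1000 / fps
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(b * t) + c,
                      data = list(y = post, t = t_ms),
                      start = list(a = max(post) - min(post),
                                   b = -4 / max(t_ms), c = min(post)),
                      lower = c(a = 0, b = -Inf, c = -Inf),
                      upper = c(a = Inf, b = -1e-9, c = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(rep(0, length(post)) + min(post))
  as.numeric(predict(fit))
}

#' Build an irregularity report
#'
#' @param segments all segmented beats.
#' @param events aberration events from [detect_aberrations()].
#' @param adheres pacing adherence from [check_pacing_adherence()].
#' @param peak_times_ms absolute peak times of all beats, for the beat-to-beat
#'   interval statistics.
#' @return object of class `ca_irregularity`.
#' @export
irregularity_report <- function(segments, events, adheres, peak_times_ms) {
  irregular_beats <- unique(vapply(events, function(e) e$beat, numeric(1)))
  intervals <- diff(peak_times_ms)
  structure(list(
    n_total_beats = length(segments),
    n_irregular = length(irregular_beats),
    n_excluded = length(irregular_beats),
    events = events,
    adheres_to_pacing = isTRUE(as.logical(adheres)),
    beat_to_beat_ms = if (length(intervals) >= 1) mean(intervals) else NA_real_,
    n_intervals = length(intervals)
  ), class = "ca_irregularity")
}

#' @export
print.ca_irregularity <- function(x, ...) {
  cat(sprintf("<ca_irregularity> %d beat(s), %d irregular (%d event(s)); %s pacing; beat-to-beat %.1f ms over %d interval(s)\n",
              x$n_total_beats, x$n_irregular, length(x$events),
              if (x$adheres_to_pacing) "adheres to" else "does NOT adhere to",
              x$beat_to_beat_ms, x$n_intervals))
  for (e in x$events)
    cat(sprintf("  beat %d: %s at %.0f ms\n", e$beat, e$class, e$time_ms))
  invisible(x)
}

#' Analyze the regular subset of a contaminated trace
#'
#' Beats containing any aberration are excluded in full, and the averaged
#' parameters are recomputed from the remaining regular beats, so a handful
#' of EAD/DAD-contaminated beats does not bias the kinetic estimates.
#'
#' @param segments all segmented beats.
#' @param events aberration events.
#' @param config a [ca_config()].
#' @param fps acquisition rate in Hz.
#' @return list: `params` (a `ca_params` from regular beats, or a flagged
#'   record when none remain), `avg` (the regular-subset average or NULL),
#'   `regular_beats` (indices kept).
#' @export
analyze_regular_subset <- function(segments, events, config, fps) {
  bad <- unique(vapply(events, function(e) e$beat, numeric(1)))
  keep <- vapply(segments, function(s) !(s$beat_index %in% bad), logical(1))
  if (!any(keep)) {
    p <- structure(list(flags = "all_beats_irregular"), class = "ca_params")
    return(list(params = p, avg = NULL, regular_beats = integer(0)))
  }
  avg <- average_transient(segments[keep])
  params <- compute_parameters(avg, config, fps)
  list(params = params, avg = avg,
       regular_beats = vapply(segments[keep], function(s) s$beat_index, integer(1)))
}
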