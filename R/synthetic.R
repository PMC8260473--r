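#' Synthetic transient waveform specification
#'
#' Defines a phenomenological paced calcium transient: per beat, a saturating
#' exponential rise with time constant `tau_on` up to the peak time
#' `tp = tau_on * log(1 + tau_off / tau_on)` after the onset, followed by a
#' pure exponential decay with time constant `tau_off` — so `tau_off` is the
#' exact ground-truth decay constant an ideal analysis should recover. Beats
#' repeat at the pacing period and incompletely decayed tails superpose, as
#' they do in real recordings at physiological pacing; the generated trace is
#' in the periodic steady state, so every beat is identical.
#'
#' @param pacing_hz pacing frequency in Hz (default 1).
#' @param n_beats number of beats (default 5).
#' @param fps sampling rate in Hz (default 100).
#' @param baseline resting fluorescence in AU (default 100).
#' @param magnitude transient amplitude in AU (default 100).
#' @param tau_on rise time constant in ms (default 30).
#' @param tau_off decay time constant in ms — the ground-truth tau
#'   (default 300).
#' @param latency_ms delay from beat (stimulus) time to transient onset
#'   (default 100 ms).
#' @param seed integer seed used by the stochastic generator stages.
#' @return an object of class `ca_waveform_spec`.
#' @export
waveform_spec <- function(pacing_hz = 1, n_beats = 5, fps = 100,
                          baseline = 100, magnitude = 100,
                          tau_on = 30, tau_off = 300,
                          latency_ms = 100, seed = 1L) {
  stopifnot(pacing_hz > 0, n_beats >= 1, fps > 0, baseline > 0,
            magnitude > 0, tau_on > 0, tau_off > 0, latency_ms >= 0)
  structure(list(pacing_hz = pacing_hz, n_beats = as.integer(n_beats),
                 fps = fps, baseline = baseline, magnitude = magnitude,
                 tau_on = tau_on, tau_off = tau_off, latency_ms = latency_ms,
                 seed = as.integer(seed)),
            class = "ca_waveform_spec")
}

# unit-peak single-beat shape, t in ms since onset (vectorized)
beat_shape <- function(t, tau_on, tau_off) {
  tp <- tau_on * log(1 + tau_off / tau_on)
  out <- numeric(length(t))
  rising <- t >= 0 & t < tp
  falling <- t >= tp
  out[rising] <- (1 - exp(-t[rising] / tau_on)) / (1 - exp(-tp / tau_on))
  out[falling] <- exp(-(t[falling] - tp) / tau_off)
  out
}

# continuous steady-state waveform value at times t_ms (with tail superposition)
waveform_value <- function(spec, t_ms) {
  period <- 1000 / spec$pacing_hz
  tp <- spec$tau_on * log(1 + spec$tau_off / spec$tau_on)
  n_tail <- min(60, ceiling(23 * spec$tau_off / period) + 1)
  v <- rep(spec$baseline, length(t_ms))
  for (k in seq(-n_tail, spec$n_beats - 1)) {
    tt <- t_ms - k * period - spec$latency_ms
    v <- v + spec$magnitude * beat_shape(tt, spec$tau_on, spec$tau_off)
  }
  v
}

#' Generate a synthetic transient trace with ground truth
#'
#' Samples the continuous steady-state waveform of `spec` at the configured
#' frame rate. The ground truth carries the onset and peak times, the exact
#' decay constant, closed-form single-beat threshold-crossing times (relative
#' to the true baseline and magnitude), and the dense-grid oracle parameters
#' of [oracle_parameters()].
#'
#' @param spec a [waveform_spec()].
#' @return list with `trace` (a noiseless [ca_trace()]) and `truth` (class
#'   `ca_ground_truth`).
#' @export
make_transient_trace <- function(spec) {
  stopifnot(inherits(spec, "ca_waveform_spec"))
  period <- 1000 / spec$pacing_hz
  n <- round(spec$n_beats * period / 1000 * spec$fps)
  t_ms <- (seq_len(n) - 1) * 1000 / spec$fps
  values <- waveform_value(spec, t_ms)
  tp <- spec$tau_on * log(1 + spec$tau_off / spec$tau_on)
  onsets <- (seq_len(spec$n_beats) - 1) * period + spec$latency_ms
  # closed-form single-beat crossings, relative to true baseline/magnitude
  rise_cross <- function(p) -spec$tau_on *
    log(1 - p * (1 - exp(-tp / spec$tau_on)))
  fall_cross <- function(p) tp + spec$tau_off * log(1 / p)
  truth <- structure(list(
    spec = spec,
    onset_times_ms = onsets,
    peak_times_ms = onsets + tp,
    time_to_peak_ms = tp,
    tau = spec$tau_off,
    t10_on = rise_cross(0.1), t50_on = rise_cross(0.5), t90_on = rise_cross(0.9),
    t50_off = fall_cross(0.5) - tp, t90_off = fall_cross(0.1) - tp,
    fmax_over_f0 = (spec$baseline + spec$magnitude) / spec$baseline,
    events = list(), drift = NULL, target_snr = NA_real_
  ), class = "ca_ground_truth")
  list(trace = ca_trace(values, fps = spec$fps), truth = truth)
}

#' Dense-grid oracle parameters for a waveform specification
#'
#' Recomputes the timing parameters of the steady-state cycle by brute force
#' on a heavily oversampled grid of the continuous waveform, mirroring the
#' parameter definitions (terminal-window baseline, redefined baseline,
#' interpolated crossings) with plain grid arithmetic that shares no code
#' with the analysis path. Used as the independent reference in validation.
#'
#' @param spec a [waveform_spec()].
#' @param oversample grid oversampling factor relative to the frame rate
#'   (default 1000).
#' @param window_start_ms start of the cycle window in ms (default: the
#'   segment start the pipeline would use, onset - 10% of the cycle).
#' @param baseline_window_fraction,baseline_redefine_fraction conventions
#'   mirrored from [ca_config()].
#' @return list of oracle times (ms) and intensities.
#' @export
oracle_parameters <- function(spec, oversample = 1000,
                              window_start_ms = NULL,
                              baseline_window_fraction = 0.20,
                              baseline_redefine_fraction = 0.03) {
  period <- 1000 / spec$pacing_hz
  if (is.null(window_start_ms))
    window_start_ms <- spec$latency_ms - 0.10 * period + 1000 / spec$fps
  dt <- (1000 / spec$fps) / oversample
  tg <- seq(window_start_ms, window_start_ms + period, by = dt)
  vg <- waveform_value(spec, tg)
  nk <- round(baseline_window_fraction * length(tg))
  f0 <- mean(vg[(length(vg) - nk + 1):length(vg)])
  fmax <- max(vg)
  ipk <- which.max(vg)
  mag <- fmax - f0
  b2 <- f0 + baseline_redefine_fraction * mag
  m2 <- fmax - b2
  up <- function(thr) {
    i <- which(vg[seq_len(ipk - 1)] < thr & vg[2:ipk] >= thr)[1]
    tg[i] + dt * (thr - vg[i]) / (vg[i + 1] - vg[i])
  }
  down <- function(thr) {
    w <- ipk:(length(vg) - 1)
    i <- w[which(vg[w] > thr & vg[w + 1] <= thr)[1]]
    if (is.na(i)) return(NA_real_)
    tg[i] + dt * (vg[i] - thr) / (vg[i] - vg[i + 1])
  }
  t0 <- up(b2)
  list(f0 = f0, fmax = fmax, fmax_over_f0 = fmax / f0,
       redefined_baseline = b2,
       t0_ms = t0, peak_time_ms = tg[ipk],
       t_on = tg[ipk] - t0,
       t10_on = up(b2 + 0.1 * m2) - t0,
       t50_on = up(b2 + 0.5 * m2) - t0,
       t90_on = up(b2 + 0.9 * m2) - t0,
       t10_off = down(b2 + 0.9 * m2) - tg[ipk],
       t50_off = down(b2 + 0.5 * m2) - tg[ipk],
       t90_off = down(b2 + 0.1 * m2) - tg[ipk],
       t_off = down(b2) - tg[ipk],
       cd = down(b2) - t0)
}

#' Frequency-scaled waveform family
#'
#' Higher pacing produces smaller, faster calcium transients. This helper
#' maps a pacing frequency to a [waveform_spec()] with magnitude and decay
#' constant scaled relative to the 1 Hz reference:
#' `magnitude ~ pacing^-0.3`, `tau_off ~ pacing^-0.5`, `tau_on ~ pacing^-0.2`.
#'
#' @param pacing_hz pacing frequency in Hz.
#' @param ... further arguments to [waveform_spec()] (the 1 Hz reference
#'   values of `magnitude`, `tau_off`, `tau_on` among them).
#' @return a [waveform_spec()].
#' @export
freq_scaled_spec <- function(pacing_hz, ...) {
  args <- list(...)
  base <- list(magnitude = 100, tau_off = 300, tau_on = 30)
  for (nm in names(base)) if (!is.null(args[[nm]])) base[[nm]] <- args[[nm]]
  args$magnitude <- base$magnitude * pacing_hz^-0.3
  args$tau_off <- base$tau_off * pacing_hz^-0.5
  args$tau_on <- base$tau_on * pacing_hz^-0.2
  args$pacing_hz <- pacing_hz
  do.call(waveform_spec, args)
}

#' Add white noise to a trace
#'
#' In `noise_sd_multiple` mode the noise SD is the given multiple of the SD
#' of the final 300 ms of the clean trace. In `target_snr` mode the SD is
#' chosen so the measured SNR (see [signal_to_noise()]) is approximately the
#' target: the numerator is taken from the clean trace and the denominator
#' accounts for the below-baseline half-normal truncation of the added noise.
#'
#' @param trace a clean [ca_trace()] with at least 300 ms of tail.
#' @param noise_sd_multiple multiple of the terminal-300-ms SD.
#' @param target_snr alternative: target signal-to-noise ratio.
#' @param seed integer seed (default: `spec$seed` convention, 1).
#' @param baseline baseline used in snr mode; default: mean of the final
#'   300 ms.
#' @return the noisy [ca_trace()]; the realized noise SD is attached as
#'   attribute `noise_sd`.
#' @export
add_noise <- function(trace, noise_sd_multiple = NULL, target_snr = NULL,
                      seed = 1L, baseline = NULL) {
  stopifnot(inherits(trace, "ca_trace"))
  tail_n <- round(0.300 * trace$fps)
  if (tail_n < 2 || tail_n > length(trace$values))
    stop("trace needs at least 300 ms of tail", call. = FALSE)
  tail_v <- tail(trace$values, tail_n)
  if (!is.null(noise_sd_multiple)) {
    if (noise_sd_multiple == 0) {
      attr(trace, "noise_sd") <- 0
      return(trace)
    }
    sd_n <- noise_sd_multiple * sd(tail_v)
  } else if (!is.null(target_snr)) {
    if (is.null(baseline)) baseline <- mean(tail_v)
    above <- trace$values[trace$values > baseline]
    numerator <- mean(above - baseline)
    # first guess from the half-normal approximation of the noise floor,
    # then one empirical correction pass against the measured SNR
    sd_n <- numerator / (target_snr * sqrt(1 - 2 / pi))
    set.seed(seed)
    probe <- trace$values + rnorm(length(trace$values), sd = sd_n)
    measured <- as.numeric(signal_to_noise(probe, baseline))
    if (is.finite(measured) && measured > 0)
      sd_n <- sd_n * measured / target_snr
  } else {
    stop("give either noise_sd_multiple or target_snr", call. = FALSE)
  }
  set.seed(seed)
  trace$values <- trace$values + rnorm(length(trace$values), sd = sd_n)
  attr(trace, "noise_sd") <- sd_n
  trace
}

#' Inject baseline drift into a trace
#'
#' Adds a drifting offset to the baseline component: the offset follows a
#' linear ramp or an exponential decay from 0 at the start to
#' `-fraction * baseline` at the trace end, leaving transient amplitudes
#' untouched (additive drift, as produced by slow background loss).
#'
#' @param trace a [ca_trace()].
#' @param kind `"linear"` or `"exponential"`.
#' @param fraction drift depth in `[0, 0.5]`: the baseline reaches
#'   `(1 - fraction)` of its starting value at the trace end.
#' @param baseline the baseline intensity being scaled; defaults to the 10th
#'   percentile of the trace.
#' @return list with the drifting `trace` and `truth` (kind, fraction, the
#'   injected offset).
#' @export
add_drift <- function(trace, kind = c("linear", "exponential"), fraction,
                      baseline = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(trace, "ca_trace"), fraction >= 0, fraction <= 0.5)
  if (is.null(baseline)) baseline <- unname(quantile(trace$values, 0.1))
  n <- length(trace$values)
  u <- (seq_len(n) - 1) / (n - 1)
  mult <- if (kind == "linear") 1 - fraction * u
          else exp(u * log(1 - fraction + 1e-12))
  offset <- baseline * (mult - 1)
  trace$values <- trace$values + offset
  list(trace = trace,
       truth = list(kind = kind, fraction = fraction, baseline = baseline,
                    offset = offset))
}

#' Inject EAD/DAD-like aberrations into a trace
#'
#' Adds Gaussian-bump deflections to specified beats. For EAD-like events the
#' bump center is placed at `phase` (0..1) of the decay window, between the
#' beat's peak and its return to near-baseline; for DAD-like events at
#' `phase` of the diastolic window between the return and the next onset. A
#' DAD is only possible when the transient decays before the next beat;
#' otherwise the phase/class combination is rejected.
#'
#' @param trace a [ca_trace()] from [make_transient_trace()].
#' @param events data.frame with columns `beat` (1-based), `class`
#'   (`"EAD"`/`"DAD"`), `phase` in (0,1), `amplitude` (fraction of the
#'   transient magnitude).
#' @param truth the `ca_ground_truth` of the trace.
#' @param width_ms Gaussian bump SD in ms (default 25).
#' @return list with the contaminated `trace` and the updated `truth` (the
#'   injected events, with their center times, appended).
#' @export
inject_irregularity <- function(trace, events, truth, width_ms = 25) {
  stopifnot(inherits(trace, "ca_trace"), is.data.frame(events))
  if (nrow(events) == 0) return(list(trace = trace, truth = truth))
  spec <- truth$spec
  period <- 1000 / spec$pacing_hz
  tp <- truth$time_to_peak_ms
  # time after the peak at which the decay has returned to ~3% of magnitude
  t_return <- tp + spec$tau_off * log(1 / 0.03)
  t_ms <- trace_times_ms(trace)
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (!(e$class %in% c("EAD", "DAD"))) stop("class must be EAD or DAD", call. = FALSE)
    if (!is.finite(e$phase) || e$phase <= 0 || e$phase >= 1)
      stop("phase must lie strictly in (0, 1)", call. = FALSE)
    onset <- truth$onset_times_ms[e$beat]
    if (is.na(onset)) stop("beat ", e$beat, " out of range", call. = FALSE)
    next_onset <- onset - spec$latency_ms + period + spec$latency_ms
    if (e$class == "EAD") {
      win_end <- min(onset + t_return, next_onset)
      center <- onset + tp + e$phase * (win_end - onset - tp)
    } else {
      if (onset + t_return >= next_onset)
        stop("DAD impossible: transient does not decay before the next beat ",
             "(class/phase mismatch)", call. = FALSE)
      center <- onset + t_return + e$phase * (next_onset - onset - t_return)
    }
    bump <- e$amplitude * spec$magnitude * exp(-(t_ms - center)^2 / (2 * width_ms^2))
    trace$values <- trace$values + bump
    truth$events[[length(truth$events) + 1]] <-
      list(beat = e$beat, class = e$class, phase = e$phase,
           amplitude = e$amplitude, center_ms = center)
  }
  list(trace = trace, truth = truth)
}

#' Generate a synthetic multi-cell image stack
#'
#' Renders a field of view with beating rod-shaped cells (anti-aliased
#' ellipses whose interior intensity follows each cell's waveform) and
#' optional static round "dead" cells, over a constant background with
#' Gaussian shot-like noise (SD proportional to the square root of the pixel
#' intensity). The ground truth records each cell's footprint label image and
#' waveform spec.
#'
#' @param cells list of cell descriptions: `center = c(row, col)`,
#'   `axes = c(major, minor)` in px, `angle` in degrees, `spec` a
#'   [waveform_spec()].
#' @param field list: `shape = c(rows, cols)`, `background` (AU, default 10),
#'   `n_dead` round static cells (default 0), `dead_radius` (px, default 12),
#'   `dead_intensity` (AU, default mean cell baseline), `noise_gain`
#'   (shot-noise scale, default 0.5), `overlap_warn` footprint-overlap
#'   fraction above which a warning is recorded (default 0.1).
#' @param n_frames,fps frames to render and rate; default from the first
#'   cell's spec.
#' @param seed integer seed.
#' @return list with `stack` (a [ca_stack()]) and `truth`: `label_image`
#'   (live cells 1..n), `dead_label_image`, per-cell specs, any overlap
#'   warnings.
#' @export
make_image_stack <- function(cells, field = list(), n_frames = NULL,
                             fps = NULL, seed = 1L) {
  shape <- if (!is.null(field$shape)) field$shape else c(128, 128)
  background <- if (!is.null(field$background)) field$background else 10
  n_dead <- if (!is.null(field$n_dead)) field$n_dead else 0
  dead_radius <- if (!is.null(field$dead_radius)) field$dead_radius else 12
  noise_gain <- if (!is.null(field$noise_gain)) field$noise_gain else 0.5
  overlap_warn <- if (!is.null(field$overlap_warn)) field$overlap_warn else 0.1
  if (length(cells) == 0 && n_dead == 0) {
    if (is.null(n_frames)) n_frames <- 50
    if (is.null(fps)) fps <- 25
  } else if (length(cells) > 0) {
    if (is.null(fps)) fps <- cells[[1]]$spec$fps
    if (is.null(n_frames))
      n_frames <- round(cells[[1]]$spec$n_beats / cells[[1]]$spec$pacing_hz * fps)
  } else {
    if (is.null(fps)) fps <- 25
    if (is.null(n_frames)) n_frames <- 50
  }
  set.seed(seed)
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)

  # per-cell soft footprint weights (anti-aliased ellipse, ~1 px feather)
  weights <- lapply(cells, function(cl) {
    th <- cl$angle * pi / 180
    dr <- rows - cl$center[1]; dc <- cols - cl$center[2]
    u <- (dr * cos(th) + dc * sin(th)) / cl$axes[1]
    w <- (-dr * sin(th) + dc * cos(th)) / cl$axes[2]
    q <- sqrt(u^2 + w^2)
    feather <- 1 / min(cl$axes)
    pmin(1, pmax(0, (1 - q) / feather + 0.5))
  })
  label_image <- matrix(0L, shape[1], shape[2])
  for (k in seq_along(weights)) label_image[weights[[k]] >= 0.5] <- k

  warnings <- character(0)
  if (length(weights) >= 2) {
    for (a in seq_along(weights)) for (b in seq_along(weights)) if (a < b) {
      fa <- weights[[a]] >= 0.5; fb <- weights[[b]] >= 0.5
      ov <- sum(fa & fb) / min(sum(fa), sum(fb))
      if (ov > overlap_warn)
        warnings <- c(warnings, sprintf("cells %d and %d overlap by %.0f%%",
                                        a, b, 100 * ov))
    }
  }

  dead_label <- matrix(0L, shape[1], shape[2])
  dead_weights <- list()
  if (n_dead > 0) {
    mean_base <- if (length(cells)) mean(vapply(cells, function(c) c$spec$baseline,
                                                numeric(1))) else 100
    dead_int <- if (!is.null(field$dead_intensity)) field$dead_intensity
                else mean_base
    for (k in seq_len(n_dead)) {
      for (att in 1:50) {
        ctr <- c(runif(1, dead_radius + 2, shape[1] - dead_radius - 2),
                 runif(1, dead_radius + 2, shape[2] - dead_radius - 2))
        q <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2) / dead_radius
        w <- pmin(1, pmax(0, (1 - q) * dead_radius + 0.5))
        near <- q <= 1 + 4 / dead_radius  # footprint plus ~4 px clearance
        clear <- sum(near & label_image > 0) == 0 &&
          sum(near & dead_label > 0) == 0
        if (clear) {  # no clear spot within the attempts: skip this cell
          dead_weights[[length(dead_weights) + 1]] <- w * dead_int
          dead_label[w >= 0.5] <- k
          break
        }
      }
    }
  }

  values <- lapply(cells, function(cl) {
    t_ms <- (seq_len(n_frames) - 1) * 1000 / fps
    waveform_value(cl$spec, t_ms)
  })
  frames <- array(background, dim = c(n_frames, shape[1], shape[2]))
  for (f in seq_len(n_frames)) {
    img <- matrix(background, shape[1], shape[2])
    for (k in seq_along(cells)) img <- img + weights[[k]] * values[[k]][f]
    for (w in dead_weights) img <- img + w
    img <- img + rnorm(length(img), sd = noise_gain * sqrt(pmax(img, 0)))
    frames[f, , ] <- pmax(img, 0)
  }
  stack <- ca_stack(frames, fps = fps, source_path = "<synthetic>")
  list(stack = stack,
       truth = list(label_image = label_image, dead_label_image = dead_label,
                    specs = lapply(cells, function(c) c$spec),
                    warnings = warnings, seed = seed))
}

#' Generate a random multi-cell field specification
#'
#' Places rod-shaped beating cells (random position, orientation and axes)
#' into a field of view by rejection sampling so that no cell's footprint
#' overlaps the others by more than `max_overlap` of its area, then renders
#' the field with [make_image_stack()] including `n_dead` static round cells.
#' Cells that cannot be placed within 100 attempts are skipped, so the
#' returned truth lists the cells actually placed.
#'
#' @param n_rod rods requested.
#' @param n_dead round dead cells.
#' @param shape field size in px (default c(192, 192)).
#' @param major_range,minor_range semi-axis ranges in px.
#' @param max_overlap maximum pairwise footprint overlap fraction
#'   (default 0.1).
#' @param min_gap_px clearance margin in px added around each footprint when
#'   testing overlap (default 4), emulating moderate plating density; set to
#'   0 to allow touching cells (high density).
#' @param fps,n_beats,pacing_hz waveform settings for the live cells.
#' @param seed integer seed.
#' @return as [make_image_stack()].
#' @export
make_random_field <- function(n_rod, n_dead = 0, shape = c(192, 192),
                              major_range = c(16, 24), minor_range = c(5, 8),
                              max_overlap = 0.1, min_gap_px = 4, fps = 25,
                              n_beats = 2, pacing_hz = 1, seed = 1L) {
  set.seed(seed)
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  footprint <- function(ctr, axes, angle) {
    th <- angle * pi / 180
    dr <- rows - ctr[1]; dc <- cols - ctr[2]
    u <- (dr * cos(th) + dc * sin(th)) / axes[1]
    w <- (-dr * sin(th) + dc * cos(th)) / axes[2]
    u^2 + w^2 <= 1
  }
  occupied <- matrix(FALSE, shape[1], shape[2])
  cells <- list()
  margin <- max(major_range) + 2
  for (k in seq_len(n_rod)) {
    for (att in 1:100) {
      axes <- c(runif(1, major_range[1], major_range[2]),
                runif(1, minor_range[1], minor_range[2]))
      ctr <- c(runif(1, margin, shape[1] - margin),
               runif(1, margin, shape[2] - margin))
      angle <- runif(1, 0, 180)
      fp <- footprint(ctr, axes, angle)
      fp_padded <- footprint(ctr, axes + min_gap_px, angle)
      if (sum(fp_padded & occupied) <= max_overlap * sum(fp)) {
        occupied <- occupied | fp_padded
        cells[[length(cells) + 1]] <- list(
          center = ctr, axes = axes, angle = angle,
          spec = waveform_spec(pacing_hz = pacing_hz, n_beats = n_beats,
                               fps = fps, seed = seed + k))
        break
      }
    }
  }
  make_image_stack(cells, field = list(shape = shape, n_dead = n_dead),
                   fps = fps, seed = seed + 1000L)
}

#' Generate a dual-excitation ratiometric channel pair
#'
#' Converts a calcium concentration waveform forward through a calibration
#' curve to an excitation ratio, then splits the ratio into two channel
#' traces (`ch1 = gain1 * R * base`, `ch2 = gain2 * base`), optionally with
#' additive channel noise.
#'
#' @param ca_nM numeric calcium concentration trace in nM.
#' @param curve a parametric [calibration_curve()].
#' @param gains length-2 channel gains (default c(1, 1)).
#' @param base denominator-channel base intensity in AU (default 1000).
#' @param noise_sd additive Gaussian SD per channel in AU (default 0).
#' @param seed integer seed.
#' @return list `ch1`, `ch2` (numeric vectors) and `ratio` (the noiseless
#'   forward ratio).
#' @export
make_ratiometric_pair <- function(ca_nM, curve, gains = c(1, 1), base = 1000,
                                  noise_sd = 0, seed = 1L) {
  stopifnot(inherits(curve, "ca_calibration"), curve$mode == "parametric")
  p <- curve$parametric
  if (any(ca_nM < 0)) stop("calcium concentrations must be non-negative", call. = FALSE)
  x <- ca_nM / (p$kd * p$beta)
  ratio <- (p$rmin + x * p$rmax) / (1 + x)
  ch1 <- gains[1] * ratio * base
  ch2 <- gains[2] * rep(base, length(ratio))
  if (noise_sd > 0) {
    set.seed(seed)
    ch1 <- ch1 + rnorm(length(ch1), sd = noise_sd)
    ch2 <- ch2 + rnorm(length(ch2), sd = noise_sd)
  }
  list(ch1 = ch1, ch2 = ch2, ratio = ratio)
}
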