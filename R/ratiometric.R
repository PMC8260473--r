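#' Ratiometric calibration curve
#'
#' Parametric mode implements the standard dual-excitation ratiometric
#' conversion (Grynkiewicz form) used for Fura-2-class indicators:
#' `[Ca] = Kd * beta * (R - Rmin) / (Rmax - R)`, with `Rmin`/`Rmax` the
#' ratios at zero and saturating calcium and `beta` the free/bound ratio of
#' the denominator-wavelength fluorescence. Empirical mode is built from
#' measured (calcium, ratio) points with [build_calibration()].
#'
#' @param kd indicator dissociation constant in nM.
#' @param rmin,rmax ratio at zero / saturating calcium (`rmin < rmax`).
#' @param beta dimensionless calibration factor (> 0).
#' @return an object of class `ca_calibration` (mode `"parametric"`).
#' @export
calibration_curve <- function(kd, rmin, rmax, beta) {
  stopifnot(kd > 0, beta > 0)
  if (!(rmin < rmax)) stop("rmin must be < rmax", call. = FALSE)
  structure(list(mode = "parametric",
                 parametric = list(kd = kd, rmin = rmin, rmax = rmax, beta = beta),
                 valid_range = c(rmin, rmax)),
            class = "ca_calibration")
}

#' Build an empirical calibration curve from measured points
#'
#' Fits a monotone interpolating map from ratio to calcium concentration
#' through at least 3 (calcium, ratio) calibration points. Ratios outside the
#' calibrated range are flagged on conversion rather than extrapolated.
#'
#' @param points data.frame with columns `calcium_nM` and `ratio`.
#' @return an object of class `ca_calibration` (mode `"empirical"`).
#' @export
build_calibration <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("calcium_nM", "ratio") %in% names(points)))
  if (nrow(points) < 3)
    stop("calibration needs at least 3 points", call. = FALSE)
  o <- order(points$calcium_nM)
  ca <- points$calcium_nM[o]
  r <- points$ratio[o]
  if (any(duplicated(r)) || any(duplicated(ca)))
    stop("calibration points must be distinct in both calcium and ratio",
         call. = FALSE)
  if (!(all(diff(r) > 0)))
    stop("calibration points must be strictly monotone (ratio increasing with calcium)",
         call. = FALSE)
  fn <- splinefun(r, ca, method = "monoH.FC")
  structure(list(mode = "empirical",
                 empirical = list(points = data.frame(calcium_nM = ca, ratio = r),
                                  map = fn),
                 valid_range = range(r)),
            class = "ca_calibration")
}

#' @export
print.ca_calibration <- function(x, ...) {
  if (x$mode == "parametric") {
    p <- x$parametric
    cat(sprintf("<ca_calibration> parametric: Kd %g nM, Rmin %g, Rmax %g, beta %g\n",
                p$kd, p$rmin, p$rmax, p$beta))
  } else {
    cat(sprintf("<ca_calibration> empirical: %d points, ratio range [%g, %g]\n",
                nrow(x$empirical$points), x$valid_range[1], x$valid_range[2]))
  }
  invisible(x)
}

#' Convert a ratio trace to calcium concentration
#'
#' Applies the calibration curve sample-wise; the conversion is monotone in
#' the ratio. Ratios at or beyond the upper validity limit (`Rmax` in
#' parametric mode) are clipped just inside it and flagged; ratios below the
#' lower limit are clipped to it. A smoothed companion trace (centered moving
#' average) is returned alongside the raw conversion.
#'
#' @param ratio numeric ratio trace.
#' @param curve a `ca_calibration`.
#' @param smooth_window centered moving-average window in samples (default 3).
#' @return list: `ca_nM` (raw), `ca_nM_smoothed`, `flags` (per-sample logical
#'   out-of-range indicator).
#' @export
ratio_to_calcium <- function(ratio, curve, smooth_window = 3) {
  stopifnot(inherits(curve, "ca_calibration"))
  lo <- curve$valid_range[1]; hi <- curve$valid_range[2]
  flags <- ratio < lo | ratio >= hi
  if (curve$mode == "parametric") {
    p <- curve$parametric
    eps <- 1e-6 * (hi - lo)
    r <- pmin(pmax(ratio, lo), hi - eps)
    ca <- p$kd * p$beta * (r - p$rmin) / (p$rmax - r)
  } else {
    r <- pmin(pmax(ratio, lo), hi)
    ca <- curve$empirical$map(r)
  }
  list(ca_nM = ca, ca_nM_smoothed = moving_average(ca, smooth_window),
       flags = flags)
}

moving_average <- function(x, window) {
  if (window <= 1 || length(x) < window) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]  # edges keep the raw values
  sm
}

#' Kinetic parameters in concentration units
#'
#' Runs the standard transient analysis on a calcium concentration trace and
#' reports, in addition to the timing parameters, the baseline, peak and
#' amplitude of intracellular calcium in nM.
#'
#' @param ca_nM numeric calcium concentration trace (nM).
#' @param fps acquisition rate in Hz.
#' @param config a [ca_config()].
#' @return a `ca_fit` whose `params` gains `baseline_nM`, `peak_nM`,
#'   `amplitude_nM`.
#' @export
concentration_parameters <- function(ca_nM, fps, config = ca_config()) {
  tr <- ca_trace(ca_nM, fps = fps)
  fit <- ca_analyze(tr, config)
  fit$params$baseline_nM <- fit$params$f0
  fit$params$peak_nM <- fit$params$fmax
  fit$params$amplitude_nM <- fit$params$magnitude
  fit
}

#' Write a concentration trace to CSV
#'
#' Columns: `time_ms`, `ca_nM_raw`, `ca_nM_smoothed`.
#'
#' @param converted result of [ratio_to_calcium()].
#' @param fps acquisition rate in Hz.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentration_trace <- function(converted, fps, path) {
  n <- length(converted$ca_nM)
  write.csv(data.frame(time_ms = (seq_len(n) - 1) * 1000 / fps,
                       ca_nM_raw = converted$ca_nM,
                       ca_nM_smoothed = converted$ca_nM_smoothed),
            path, row.names = FALSE)
  invisible(path)
}
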