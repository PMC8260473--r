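#' Analysis configuration
#'
#' Collects every tunable of the analysis pipeline with the field-standard
#' defaults. All timing fractions are expressed relative to the pacing cycle
#' length: the transient onset offset is 10% of the cycle (100 ms at 1 Hz),
#' the terminal baseline window is 20% of the cycle (200 ms at 1 Hz), and the
#' baseline is redefined upward by 3% of the transient magnitude before timing
#' parameters are interpolated.
#'
#' @param pacing_hz electrical pacing frequency in Hz (> 0).
#' @param onset_offset_fraction fraction of the cycle length subtracted from
#'   each detected onset to place the segment start (default 0.10).
#' @param baseline_window_fraction fraction of the cycle length, taken from the
#'   end of the averaged transient, over which the baseline F0 is averaged
#'   (default 0.20).
#' @param baseline_redefine_fraction fraction of the transient magnitude added
#'   to F0 to form the redefined baseline used for all interpolated timing
#'   parameters (default 0.03).
#' @param prominence_fraction onsets are peaks of the difference array with
#'   prominence at least this fraction of the maximum observed prominence
#'   (default 0.50).
#' @param photobleach_correct one of `"auto"`, `"off"`, `"force"`. `"auto"`
#'   detrends only when the fitted baseline trend changes by more than
#'   `drift_trigger_fraction` of the initial baseline; `"off"` passes traces
#'   through untouched; `"force"` always detrends.
#' @param drift_trigger_fraction auto-mode trigger threshold as a fraction of
#'   the initial baseline (default 0.03).
#' @param per_beat_output report parameters for every beat (plus their SD
#'   across beats) in addition to the averaged-transient parameters.
#' @param ratiometric treat traces as ratiometric (dual-excitation) input.
#' @param exclude_irregular when irregular beats are detected, recompute
#'   parameters on the regular beats only (default TRUE).
#' @param downsample_target_fps acquisition rates above this are decimated to
#'   this rate for onset detection only; parameters are always measured on the
#'   native-rate data (default 100 Hz).
#' @param snr_warn_threshold traces with signal-to-noise ratio below this value
#'   are flagged as potentially unreliable (default 15).
#' @param random_seed optional integer seed recorded in outputs.
#' @param dog_sigma_small,dog_sigma_large difference-of-Gaussians sigmas in
#'   pixels for multi-cell segmentation (defaults 2 and 20).
#' @param clahe_limit contrast-limited adaptive histogram equalization clip
#'   limit (EBImage parameterization, default 2).
#' @param clahe_tiles number of CLAHE tiles per image side (default 8).
#' @param morph_radius disk radius in pixels for the erosion-dilation step
#'   (default 3).
#' @param min_eccentricity regions with eccentricity below this are rejected as
#'   non-elongated (rounded, typically non-viable) cells (default 0.75).
#' @param min_area_px regions smaller than this many pixels are rejected
#'   (default 200).
#' @param merge_area_factor accepted regions larger than this multiple of the
#'   median accepted area are rejected as possible merges of touching cells
#'   (default 3).
#' @param aberration_prominence_fraction secondary deflections within a beat
#'   must have prominence at least this fraction of the recalculated magnitude
#'   to count as EAD/DAD-like events (default 0.10).
#' @param aberration_sd_multiple ... and at least this multiple of the
#'   below-baseline SD (default 3).
#' @param smoothing_window centered moving-average window (samples) for the
#'   smoothed calcium concentration trace (default 3).
#' @param channel optional channel index for multi-channel input; by default
#'   the channel with maximum mean intensity is used.
#'
#' @return an object of class `ca_config` (a validated list).
#' @export
#' @examples
#' cfg <- ca_config(pacing_hz = 1)
#' cfg$onset_offset_fraction
ca_config <- function(pacing_hz = 1,
                      onset_offset_fraction = 0.10,
                      baseline_window_fraction = 0.20,
                      baseline_redefine_fraction = 0.03,
                      prominence_fraction = 0.50,
                      photobleach_correct = c("auto", "off", "force"),
                      drift_trigger_fraction = 0.03,
                      per_beat_output = FALSE,
                      ratiometric = FALSE,
                      exclude_irregular = TRUE,
                      downsample_target_fps = 100,
                      snr_warn_threshold = 15,
                      random_seed = NULL,
                      dog_sigma_small = 2,
                      dog_sigma_large = 20,
                      clahe_limit = 2,
                      clahe_tiles = 8,
                      morph_radius = 3,
                      min_eccentricity = 0.75,
                      min_area_px = 200,
                      merge_area_factor = 3,
                      aberration_prominence_fraction = 0.10,
                      aberration_sd_multiple = 3,
                      smoothing_window = 3,
                      channel = NULL) {
  photobleach_correct <- match.arg(photobleach_correct)
  cfg <- list(
    pacing_hz = pacing_hz,
    onset_offset_fraction = onset_offset_fraction,
    baseline_window_fraction = baseline_window_fraction,
    baseline_redefine_fraction = baseline_redefine_fraction,
    prominence_fraction = prominence_fraction,
    photobleach_correct = photobleach_correct,
    drift_trigger_fraction = drift_trigger_fraction,
    per_beat_output = isTRUE(per_beat_output),
    ratiometric = isTRUE(ratiometric),
    exclude_irregular = isTRUE(exclude_irregular),
    downsample_target_fps = downsample_target_fps,
    snr_warn_threshold = snr_warn_threshold,
    random_seed = random_seed,
    dog_sigma_small = dog_sigma_small,
    dog_sigma_large = dog_sigma_large,
    clahe_limit = clahe_limit,
    clahe_tiles = clahe_tiles,
    morph_radius = morph_radius,
    min_eccentricity = min_eccentricity,
    min_area_px = min_area_px,
    merge_area_factor = merge_area_factor,
    aberration_prominence_fraction = aberration_prominence_fraction,
    aberration_sd_multiple = aberration_sd_multiple,
    smoothing_window = smoothing_window,
    channel = channel
  )
  class(cfg) <- "ca_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$pacing_hz), length(cfg$pacing_hz) == 1)
  if (!(cfg$pacing_hz > 0)) stop("pacing_hz must be > 0", call. = FALSE)
  for (f in c("onset_offset_fraction", "baseline_window_fraction",
              "baseline_redefine_fraction", "prominence_fraction",
              "drift_trigger_fraction", "aberration_prominence_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0 || v >= 1)
      stop(sprintf("%s must be a single number in (0, 1)", f), call. = FALSE)
  }
  if (cfg$downsample_target_fps <= 0) stop("downsample_target_fps must be > 0", call. = FALSE)
  invisible(cfg)
}

#' Read an analysis configuration from a YAML file
#'
#' Flat keys mirror the arguments of [ca_config()]; unknown keys are an error
#' so typos never silently fall back to defaults.
#'
#' @param path path to a YAML file.
#' @return a `ca_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(ca_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(ca_config, vals)
}

#' @export
print.ca_config <- function(x, ...) {
  cat("<ca_config> pacing", x$pacing_hz, "Hz;",
      "photobleach:", x$photobleach_correct, ";",
      "onset offset", x$onset_offset_fraction,
      "| baseline window", x$baseline_window_fraction,
      "| redefine", x$baseline_redefine_fraction, "\n")
  invisible(x)
}
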