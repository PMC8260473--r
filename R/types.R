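#' Image stack container
#'
#' An ordered set of grayscale frames with its acquisition rate. Frames are
#' stored as a 3-D array indexed `[frame, row, col]`; frame `i` (0-based in
#' time terms) is acquired at `(i - 1) / fps` seconds. Reported times are
#' always in milliseconds.
#'
#' @param frames 3-D numeric array `[frame, row, col]`, non-negative.
#' @param fps acquisition rate in frames per second (> 0).
#' @param pixel_depth nominal bit depth of the source data.
#' @param source_path provenance, for the run manifest.
#' @return an object of class `ca_stack`.
#' @export
ca_stack <- function(frames, fps, pixel_depth = NA_integer_, source_path = NA_character_) {
  if (!is.array(frames) || length(dim(frames)) != 3)
    stop("frames must be a 3-D array [frame, row, col]", call. = FALSE)
  if (dim(frames)[1] < 2) stop("an image stack needs at least 2 frames", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1 || !(fps > 0))
    stop("fps must be a single positive number", call. = FALSE)
  structure(list(frames = frames, fps = fps, pixel_depth = pixel_depth,
                 source_path = source_path),
            class = "ca_stack")
}

#' @export
print.ca_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ca_stack> %d frames of %dx%d px @ %g FPS (%.2f s)\n",
              d[1], d[2], d[3], x$fps, d[1] / x$fps))
  invisible(x)
}

#' Fluorescence trace container
#'
#' One cell's fluorescence intensity per frame, in arbitrary units, with the
#' processing history the pipeline needs downstream.
#'
#' @param values numeric vector, one intensity per frame, finite.
#' @param fps acquisition rate in Hz.
#' @param cell_id integer cell identifier.
#' @param background_subtracted,detrended processing flags.
#' @param snr signal-to-noise ratio, filled in after analysis.
#' @return an object of class `ca_trace`.
#' @export
ca_trace <- function(values, fps, cell_id = 1L,
                     background_subtracted = FALSE, detrended = FALSE,
                     snr = NA_real_) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("a trace needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(values))) stop("trace values must be finite", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1 || !(fps > 0))
    stop("fps must be a single positive number", call. = FALSE)
  structure(list(values = values, fps = fps, cell_id = as.integer(cell_id),
                 background_subtracted = isTRUE(background_subtracted),
                 detrended = isTRUE(detrended), snr = snr),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace> cell %d: %d frames @ %g FPS (%.2f s)%s%s\n",
              x$cell_id, length(x$values), x$fps, length(x$values) / x$fps,
              if (x$background_subtracted) ", bg-subtracted" else "",
              if (x$detrended) ", detrended" else ""))
  invisible(x)
}

#' @export
length.ca_trace <- function(x) length(x$values)

#' Time points of a trace in milliseconds
#'
#' Frame `i` (1-based) maps to `(i - 1) / fps * 1000` ms.
#'
#' @param trace a [ca_trace()].
#' @return numeric vector of times in ms.
#' @export
trace_times_ms <- function(trace) {
  (seq_along(trace$values) - 1) / trace$fps * 1000
}

#' Trace table container
#'
#' A set of equally long traces acquired together under the same pacing.
#'
#' @param traces list of [ca_trace()] objects, all the same length and fps.
#' @param fps acquisition rate in Hz.
#' @param pacing_hz pacing frequency in Hz.
#' @return an object of class `ca_trace_table`.
#' @export
ca_trace_table <- function(traces, fps, pacing_hz) {
  if (length(traces) == 0) stop("trace table is empty", call. = FALSE)
  lens <- vapply(traces, function(t) length(t$values), integer(1))
  fpss <- vapply(traces, function(t) t$fps, numeric(1))
  if (length(unique(lens)) != 1) stop("all traces must have the same length", call. = FALSE)
  if (any(fpss != fps)) stop("all traces must share the table fps", call. = FALSE)
  structure(list(traces = traces, fps = fps, pacing_hz = pacing_hz),
            class = "ca_trace_table")
}

#' @export
print.ca_trace_table <- function(x, ...) {
  cat(sprintf("<ca_trace_table> %d traces of %d frames @ %g FPS, pacing %g Hz\n",
              length(x$traces), length(x$traces[[1]]$values), x$fps, x$pacing_hz))
  invisible(x)
}
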