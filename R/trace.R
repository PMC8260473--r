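#' Extract a cell's fluorescence trace from a masked stack
#'
#' The raw fluorescence of cell `cell_id` at frame `t` is the sum of all pixel
#' intensities inside that cell's (fixed) labeled region. Extraction is linear
#' in the pixel intensities.
#'
#' @param stack a [ca_stack()].
#' @param mask a [ca_mask()] computed from the same stack.
#' @param cell_id label of an accepted cell.
#' @return a [ca_trace()].
#' @export
extract_trace <- function(stack, mask, cell_id) {
  stopifnot(inherits(stack, "ca_stack"), inherits(mask, "ca_mask"))
  row <- match(cell_id, mask$props$label)
  if (is.na(row)) stop("unknown cell label: ", cell_id, call. = FALSE)
  if (!mask$props$accepted[row])
    stop("cell ", cell_id, " was rejected (",
         mask$props$rejection_reason[row], ")", call. = FALSE)
  idx <- which(mask$label_image == cell_id)
  nf <- dim(stack$frames)[1]
  npx <- prod(dim(stack$frames)[2:3])
  fl <- matrix(stack$frames, nrow = nf, ncol = npx)  # frame-major flattening
  values <- rowSums(fl[, idx, drop = FALSE])
  ca_trace(values, fps = stack$fps, cell_id = as.integer(cell_id))
}

#' Subtract the imaging background from a trace
#'
#' The background region is everything outside any labeled region, eroded by
#' `erode_px` to keep out-of-focus halos around cells from contaminating the
#' estimate. Per frame, the mean background intensity times the cell area is
#' removed from the summed-intensity trace, so a spatially uniform offset
#' cancels exactly.
#'
#' @param trace a [ca_trace()] from [extract_trace()].
#' @param stack,mask the stack and mask the trace came from.
#' @param erode_px background erosion radius in pixels (default 3).
#' @return the corrected [ca_trace()] with `background_subtracted = TRUE`.
#' @export
subtract_background <- function(trace, stack, mask, erode_px = 3) {
  stopifnot(inherits(trace, "ca_trace"), inherits(stack, "ca_stack"),
            inherits(mask, "ca_mask"))
  bg <- (mask$label_image == 0) * 1
  if (erode_px > 0)
    bg <- EBImage::imageData(EBImage::erode(EBImage::Image(bg),
                                            EBImage::makeBrush(2 * erode_px + 1, "disc")))
  bg_idx <- which(bg > 0)
  if (length(bg_idx) == 0)
    stop("mask covers the entire frame: no background pixels", call. = FALSE)
  nf <- dim(stack$frames)[1]
  fl <- matrix(stack$frames, nrow = nf, ncol = prod(dim(stack$frames)[2:3]))
  bg_mean <- rowMeans(fl[, bg_idx, drop = FALSE])
  area <- sum(mask$label_image == trace$cell_id)
  trace$values <- trace$values - bg_mean * area
  trace$background_subtracted <- TRUE
  trace
}

#' Signal-to-noise ratio of a trace
#'
#' SNR = mean excess of above-baseline values over the baseline, divided by
#' the SD of the values lying below the baseline. Traces with SNR below the
#' warning threshold (default 15) should be treated with caution. When no
#' value lies below the baseline, or the below-baseline SD is zero (noiseless
#' input), `Inf` is returned with a `"degenerate"` quality flag attached as an
#' attribute rather than an error.
#'
#' @param trace a [ca_trace()] or numeric vector.
#' @param baseline baseline intensity (same units as the trace).
#' @param warn_threshold SNR below this attaches a `"low_snr"` flag.
#' @return SNR (dimensionless) with optional `flag` attribute.
#' @export
signal_to_noise <- function(trace, baseline, warn_threshold = 15) {
  v <- if (inherits(trace, "ca_trace")) trace$values else as.numeric(trace)
  above <- v[v > baseline]
  below <- v[v < baseline]
  if (length(above) == 0) {
    return(structure(0, flag = "no_signal_above_baseline"))
  }
  if (length(below) < 2 || sd(below) == 0) {
    return(structure(Inf, flag = "degenerate_noise_floor"))
  }
  snr <- mean(above - baseline) / sd(below)
  if (snr < warn_threshold) attr(snr, "flag") <- "low_snr"
  snr
}
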