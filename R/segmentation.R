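#' Time-averaged frame of a stack
#'
#' Pixelwise mean over all frames; the static image from which the fixed cell
#' mask is derived. Cells appear as bright footprints at their time-averaged
#' intensity, insensitive to the beat phase of any single frame.
#'
#' @param stack a [ca_stack()].
#' @return numeric matrix `[row, col]`.
#' @export
average_frame <- function(stack) {
  stopifnot(inherits(stack, "ca_stack"))
  colMeans(stack$frames, dims = 1)
}

#' Cell mask container
#'
#' @param label_image integer matrix, 0 = background, k = region k.
#' @param props data.frame with one row per region: `label`, `area_px`,
#'   `eccentricity`, bounding box, `accepted`, `rejection_reason`.
#' @param diagnostic optional message for degenerate inputs.
#' @return an object of class `ca_mask`.
#' @export
ca_mask <- function(label_image, props, diagnostic = NULL) {
  structure(list(label_image = label_image, props = props,
                 n_cells = sum(props$accepted), diagnostic = diagnostic),
            class = "ca_mask")
}

#' @export
print.ca_mask <- function(x, ...) {
  cat(sprintf("<ca_mask> %d region(s), %d accepted\n", nrow(x$props), x$n_cells))
  if (!is.null(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}

empty_mask <- function(shape, diagnostic) {
  ca_mask(matrix(0L, shape[1], shape[2]),
          data.frame(label = integer(0), area_px = numeric(0),
                     eccentricity = numeric(0),
                     bbox_r0 = integer(0), bbox_c0 = integer(0),
                     bbox_r1 = integer(0), bbox_c1 = integer(0),
                     accepted = logical(0), rejection_reason = character(0),
                     stringsAsFactors = FALSE),
          diagnostic = diagnostic)
}

#' Segment cells from a time-averaged frame
#'
#' Single-cell mode (high magnification) takes the largest connected component
#' of the Otsu-thresholded mean image as the cell footprint; no shape filter
#' is applied. Multi-cell mode (low magnification) enhances local boundaries
#' with a difference-of-Gaussians filter and CLAHE, binarizes with Otsu's
#' threshold, applies one erosion and one dilation with a disk, labels
#' connected components, and rejects regions that are too small, not elongated
#' (rounded cells are typically dead or non-viable), or large enough to be a
#' merge of touching cells. The mask is computed once and applied unchanged to
#' every frame.
#'
#' @param mean_image matrix from [average_frame()].
#' @param mode `"single"` or `"multi"`.
#' @param config a [ca_config()] providing the segmentation tunables.
#' @return a [ca_mask()]. When nothing survives filtering the mask is empty
#'   and carries a diagnostic rather than throwing.
#' @export
segment_cells <- function(mean_image, mode = c("multi", "single"),
                          config = ca_config()) {
  mode <- match.arg(mode)
  if (!all(is.finite(mean_image))) stop("mean image must be finite", call. = FALSE)
  rng <- range(mean_image)
  if (diff(rng) == 0)
    return(empty_mask(dim(mean_image), "constant image: no contrast to segment"))
  img <- (mean_image - rng[1]) / diff(rng)

  if (mode == "single") {
    bw <- img > EBImage::otsu(EBImage::Image(img), range = c(0, 1))
    lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
    labm <- EBImage::imageData(lab)
    if (max(labm) == 0) return(empty_mask(dim(img), "no foreground at Otsu threshold"))
    areas <- tabulate(labm[labm > 0])
    keep <- which.max(areas)
    labm2 <- matrix(0L, nrow(labm), ncol(labm))
    labm2[labm == keep] <- 1L
    props <- region_props(labm2)
    props$accepted <- TRUE
    props$rejection_reason <- ""
    return(ca_mask(labm2, props))
  }

  # the blur kernel (2*ceil(3*sigma)+1 wide) must fit inside the image
  sig_cap <- (min(dim(img)) - 3) / 6.5
  s_small <- min(config$dog_sigma_small, sig_cap)
  s_large <- min(config$dog_sigma_large, sig_cap)
  dog <- EBImage::gblur(EBImage::Image(img), sigma = s_small) -
    EBImage::gblur(EBImage::Image(img), sigma = s_large)
  dog <- EBImage::imageData(dog)
  drng <- range(dog)
  if (diff(drng) == 0) return(empty_mask(dim(img), "flat response to DoG filter"))
  dog <- (dog - drng[1]) / diff(drng)
  enh <- EBImage::clahe(EBImage::Image(dog),
                        nx = config$clahe_tiles, ny = config$clahe_tiles,
                        limit = config$clahe_limit)
  th <- EBImage::otsu(enh, range = c(0, 1))
  bw <- EBImage::Image((EBImage::imageData(enh) > th) * 1)
  brush <- EBImage::makeBrush(2 * config$morph_radius + 1, shape = "disc")
  bw <- EBImage::dilate(EBImage::erode(bw, brush), brush)
  labm <- EBImage::imageData(EBImage::bwlabel(bw))
  if (max(labm) == 0) return(empty_mask(dim(img), "no regions after morphology"))

  props <- region_props(labm)
  props$accepted <- TRUE
  props$rejection_reason <- ""
  small <- props$area_px < config$min_area_px
  props$accepted[small] <- FALSE
  props$rejection_reason[small] <- "too small"
  round_ <- !small & props$eccentricity < config$min_eccentricity
  props$accepted[round_] <- FALSE
  props$rejection_reason[round_] <- "non-elongated"
  if (any(props$accepted)) {
    med <- median(props$area_px[props$accepted])
    big <- props$accepted & props$area_px > config$merge_area_factor * med
    props$accepted[big] <- FALSE
    props$rejection_reason[big] <- "possible merge"
  }
  diag <- if (!any(props$accepted)) "no region passed the elongation/size filters" else NULL
  ca_mask(labm, props, diagnostic = diag)
}

region_props <- function(labm) {
  labs <- sort(unique(labm[labm > 0]))
  img <- EBImage::Image(labm)
  sh <- EBImage::computeFeatures.shape(img)
  mo <- EBImage::computeFeatures.moment(img)
  sh <- matrix(sh, nrow = length(labs), dimnames = list(NULL, colnames(sh)))
  mo <- matrix(mo, nrow = length(labs), dimnames = list(NULL, colnames(mo)))
  bbox <- t(vapply(labs, function(l) {
    idx <- which(labm == l, arr.ind = TRUE)
    c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]), max(idx[, 2]))
  }, numeric(4)))
  data.frame(label = as.integer(labs),
             area_px = as.numeric(sh[, "s.area"]),
             eccentricity = as.numeric(mo[, "m.eccentricity"]),
             bbox_r0 = bbox[, 1], bbox_c0 = bbox[, 2],
             bbox_r1 = bbox[, 3], bbox_c1 = bbox[, 4],
             accepted = logical(length(labs)),
             rejection_reason = character(length(labs)),
             stringsAsFactors = FALSE)
}

#' Apply user exclusions to a mask
#'
#' The user-review step: labels listed in `exclusions` are marked rejected
#' with reason `"user"`. Labels are never renumbered, so cell identities are
#' stable across review rounds.
#'
#' @param mask a [ca_mask()].
#' @param exclusions integer vector of labels to reject.
#' @return the updated [ca_mask()].
#' @export
review_mask <- function(mask, exclusions = integer(0)) {
  stopifnot(inherits(mask, "ca_mask"))
  if (length(exclusions) == 0) return(mask)
  unknown <- setdiff(exclusions, mask$props$label)
  if (length(unknown) > 0)
    stop("unknown label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  sel <- mask$props$label %in% exclusions
  mask$props$accepted[sel] <- FALSE
  mask$props$rejection_reason[sel] <- "user"
  mask$n_cells <- sum(mask$props$accepted)
  mask
}

#' Export a mask overlay for user review
#'
#' Writes a PNG of the mean image with accepted regions outlined; the label
#' image itself can be written as TIFF for downstream tools.
#'
#' @param mask a [ca_mask()].
#' @param mean_image the matrix the mask was computed from.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
export_mask_overlay <- function(mask, mean_image, path) {
  rng <- range(mean_image)
  img <- if (diff(rng) > 0) (mean_image - rng[1]) / diff(rng) else mean_image * 0
  rgb <- array(rep(img, 3), dim = c(dim(img), 3))
  edge <- mask$label_image > 0 &
    (EBImage::imageData(EBImage::erode(EBImage::Image((mask$label_image > 0) * 1),
                                       EBImage::makeBrush(3, "disc"))) == 0)
  acc <- matrix(mask$props$accepted[match(mask$label_image, mask$props$label)],
                nrow(mask$label_image))
  r <- rgb[, , 1]; g <- rgb[, , 2]
  g[edge & acc %in% TRUE] <- 1
  r[edge & !(acc %in% TRUE)] <- 1
  rgb[, , 1] <- r; rgb[, , 2] <- g
  png::writePNG(rgb, path)
  invisible(path)
}
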