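#' Temporal resolution advisory
#'
#' By the Nyquist-style criterion used for transient kinetics, the resolvable
#' temporal feature size is 1/2.3 of the sampling frequency: at 25 FPS the
#' sampling interval is 40 ms and the theoretical resolution 92 ms. Rates
#' below 25 FPS draw an explicit low-rate warning.
#'
#' @param fps acquisition rate in Hz.
#' @return list: `sampling_interval_ms`, `resolution_ms`, `low_rate_warning`.
#' @export
#' @examples
#' temporal_resolution_advisory(25)
temporal_resolution_advisory <- function(fps) {
  stopifnot(is.numeric(fps), fps > 0)
  out <- list(sampling_interval_ms = 1000 / fps,
              resolution_ms = 2.3 * 1000 / fps,
              low_rate_warning = fps < 25)
  if (out$low_rate_warning)
    warning(sprintf("acquisition rate %g FPS is below the recommended minimum of 25 FPS",
                    fps), call. = FALSE)
  out
}

#' Analyze every input file in a directory
#'
#' Batch entry point: TIFF stacks are segmented (multi-cell mode by default)
#' and every accepted cell analyzed; delimited trace tables are analyzed
#' trace by trace. One failing file or cell never aborts the run — failures
#' are recorded in the manifest and flagged rows are written for failing
#' cells. Outputs (parameter CSVs and a JSON manifest) land in `output_dir`.
#'
#' @param dir input directory.
#' @param config a [ca_config()].
#' @param output_dir output directory (default: `dir`/calcitrace_out).
#' @param fps acquisition rate of the inputs in Hz (required; image files do
#'   not carry it).
#' @param segmentation_mode `"multi"` or `"single"` for image stacks.
#' @param exclusions optional named list: file name -> integer labels to
#'   exclude at mask review.
#' @return the run manifest (list), invisibly written as
#'   `manifest.json`. Fields: per-file status, per-cell flags, counts, the
#'   configuration snapshot, package version and seed.
#' @export
run_directory <- function(dir, config, output_dir = NULL, fps = 25,
                          segmentation_mode = c("multi", "single"),
                          exclusions = list()) {
  segmentation_mode <- match.arg(segmentation_mode)
  if (!dir.exists(dir)) stop("not a directory: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = "\\.(tif|tiff|csv|tsv|txt|xlsx)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0) stop("no readable inputs in ", dir, call. = FALSE)
  if (is.null(output_dir)) output_dir <- file.path(dir, "calcitrace_out")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$random_seed)) set.seed(config$random_seed)

  adv <- temporal_resolution_advisory(fps)
  manifest <- list(
    software = paste0("calcitrace ",
                      as.character(utils::packageVersion("calcitrace"))),
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    seed = config$random_seed,
    fps = fps,
    advisory = adv,
    files = list()
  )

  all_fits <- list()
  for (path in files) {
    fname <- basename(path)
    entry <- list(file = fname, status = "processed", cells = list())
    res <- tryCatch({
      ext <- tolower(tools::file_ext(path))
      if (ext %in% c("tif", "tiff")) {
        stack <- read_image_stack(path, fps = fps, channel = config$channel)
        mask <- segment_cells(average_frame(stack), mode = segmentation_mode,
                              config = config)
        if (!is.null(exclusions[[fname]]))
          mask <- review_mask(mask, exclusions[[fname]])
        labels <- mask$props$label[mask$props$accepted]
        fits <- lapply(labels, function(lab) {
          tryCatch({
            tr <- extract_trace(stack, mask, lab)
            tr <- subtract_background(tr, stack, mask)
            ca_analyze(tr, config)
          }, error = function(e) {
            flagged_fit(ca_trace(c(0, 1), fps = fps, cell_id = lab),
                        config, paste0("cell_failed: ", conditionMessage(e)))
          })
        })
        fits
      } else {
        tab <- read_trace_table(path, fps = fps, pacing_hz = config$pacing_hz)
        lapply(tab$traces, function(tr) {
          tryCatch(ca_analyze(tr, config), error = function(e)
            flagged_fit(tr, config, paste0("cell_failed: ", conditionMessage(e))))
        })
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      entry$status <- "failed"
      entry$error <- conditionMessage(res)
    } else if (length(res) == 0) {
      entry$status <- "skipped"
      entry$reason <- "no accepted cells"
    } else {
      entry$cells <- lapply(res, function(f)
        list(cell_id = f$trace$cell_id, flags = as.list(f$flags),
             snr = f$params$snr))
      stem <- file.path(output_dir, tools::file_path_sans_ext(fname))
      write_parameters(res, paste0(stem, "_parameters.csv"))
      all_fits <- c(all_fits, res)
    }
    manifest$files[[fname]] <- entry
    message(sprintf("[calcitrace] %s: %s (%d cell(s))", fname, entry$status,
                    length(entry$cells)))
  }

  statuses <- vapply(manifest$files, function(f) f$status, character(1))
  manifest$n_processed <- sum(statuses == "processed")
  manifest$n_failed <- sum(statuses == "failed")
  manifest$n_skipped <- sum(statuses == "skipped")
  manifest$n_cells <- length(all_fits)
  manifest$n_unflagged_cells <- sum(!vapply(all_fits, is_flagged, logical(1)))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
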