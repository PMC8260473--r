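#' Read a multi-frame image stack
#'
#' Reads a multi-frame grayscale TIFF stack into a [ca_stack()]. Multi-channel
#' frames are reduced to one channel: the configured channel index if given,
#' otherwise the channel with the highest mean intensity (calcium indicators
#' are single-channel; other channels are bleed-through or brightfield).
#' Additional readers for video containers can be registered with
#' [register_stack_reader()].
#'
#' @param path file path.
#' @param fps acquisition rate in Hz (TIFF carries no rate metadata).
#' @param channel optional channel index for multi-channel input.
#' @return a [ca_stack()].
#' @export
read_image_stack <- function(path, fps, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  reader <- .stack_readers$get(ext)
  if (is.null(reader))
    stop(sprintf("no reader registered for '.%s' files (TIFF is built in)", ext),
         call. = FALSE)
  reader(path, fps = fps, channel = channel)
}

# pluggable reader registry keyed by file extension
.stack_readers <- local({
  readers <- new.env(parent = emptyenv())
  list(
    set = function(ext, fn) assign(tolower(ext), fn, envir = readers),
    get = function(ext) if (exists(tolower(ext), envir = readers))
      get(tolower(ext), envir = readers) else NULL
  )
})

#' Register a stack reader for a file extension
#'
#' The reader must be a `function(path, fps, channel)` returning a
#' [ca_stack()]. This is the extension point for video containers (.avi,
#' .mp4, ...) or microscope formats decoded by external tools.
#'
#' @param ext file extension without the dot.
#' @param reader reader function.
#' @export
register_stack_reader <- function(ext, reader) {
  stopifnot(is.function(reader))
  .stack_readers$set(ext, reader)
  invisible(NULL)
}

read_tiff_stack <- function(path, fps, channel = NULL) {
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                     error = function(e)
                       stop("unreadable TIFF: ", path, " (", conditionMessage(e), ")",
                            call. = FALSE))
  if (!is.list(frames)) frames <- list(frames)
  if (length(frames) < 2)
    stop("single-frame file: an image stack needs at least 2 frames", call. = FALSE)
  frames <- lapply(frames, reduce_channels, channel = channel)
  d <- dim(frames[[1]])
  arr <- array(NA_real_, dim = c(length(frames), d[1], d[2]))
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d))
      stop("frames differ in shape within ", path, call. = FALSE)
    arr[i, , ] <- frames[[i]]
  }
  depth <- attr(frames[[1]], "bits.per.sample")
  ca_stack(arr, fps = fps,
           pixel_depth = if (is.null(depth)) NA_integer_ else as.integer(depth),
           source_path = path)
}

reduce_channels <- function(frame, channel = NULL) {
  if (length(dim(frame)) == 2 || is.null(dim(frame))) return(as.matrix(frame))
  nch <- dim(frame)[3]
  if (is.null(channel)) {
    means <- vapply(seq_len(nch), function(k) mean(frame[, , k]), numeric(1))
    channel <- which.max(means)
  }
  if (channel < 1 || channel > nch)
    stop("channel index ", channel, " out of range (1..", nch, ")", call. = FALSE)
  frame[, , channel]
}

.onLoad <- function(libname, pkgname) {
  register_stack_reader("tif", read_tiff_stack)
  register_stack_reader("tiff", read_tiff_stack)
}

#' Write an image stack as a multi-frame TIFF
#'
#' Intensities are quantized to the requested bit depth; a stack read back
#' with [read_image_stack()] reproduces the quantized integer values exactly.
#'
#' @param stack a [ca_stack()].
#' @param path output path.
#' @param bits 8 or 16.
#' @param max_intensity full-scale value used for quantization; defaults to
#'   the stack maximum.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, bits = 16, max_intensity = NULL) {
  stopifnot(inherits(stack, "ca_stack"), bits %in% c(8, 16))
  if (is.null(max_intensity)) max_intensity <- max(stack$frames)
  if (max_intensity <= 0) max_intensity <- 1
  full <- 2^bits - 1
  frames <- lapply(seq_len(dim(stack$frames)[1]), function(i) {
    m <- stack$frames[i, , ]
    round(pmin(pmax(m / max_intensity, 0), 1) * full) / full
  })
  tiff::writeTIFF(frames, path, bits.per.sample = bits)
  invisible(path)
}

#' Read a trace table from a delimited file or spreadsheet
#'
#' Wide format: one numeric column per cell (an optional `frame` or `time`
#' column is dropped). Long format: columns `cell` (or `cell_id`) and `value`
#' (or `intensity`), optionally `frame`. `.csv`, `.tsv`/`.txt` and — when the
#' readxl package is installed — `.xlsx` files are supported.
#'
#' @param path file path.
#' @param fps acquisition rate in Hz.
#' @param pacing_hz pacing frequency in Hz.
#' @return a [ca_trace_table()].
#' @export
read_trace_table <- function(path, fps, pacing_hz) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = read.csv(path, check.names = FALSE),
    tsv = ,
    txt = read.delim(path, check.names = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading .xlsx requires the readxl package", call. = FALSE)
      as.data.frame(readxl::read_excel(path))
    },
    stop("unsupported trace-table format: .", ext, call. = FALSE)
  )
  if (nrow(df) == 0 || ncol(df) == 0) stop("empty trace table: ", path, call. = FALSE)
  nm <- tolower(names(df))
  long <- any(nm %in% c("cell", "cell_id")) && any(nm %in% c("value", "intensity"))
  if (long) {
    idc <- which(nm %in% c("cell", "cell_id"))[1]
    vc <- which(nm %in% c("value", "intensity"))[1]
    vals <- check_numeric_column(df[[vc]], names(df)[vc])
    ids <- df[[idc]]
    traces <- lapply(seq_along(unique(ids)), function(k) {
      id <- unique(ids)[k]
      ca_trace(vals[ids == id], fps = fps, cell_id = k)
    })
  } else {
    drop <- nm %in% c("frame", "time", "time_ms", "t")
    df <- df[, !drop, drop = FALSE]
    if (ncol(df) == 0) stop("trace table has no intensity columns", call. = FALSE)
    traces <- lapply(seq_len(ncol(df)), function(k) {
      v <- check_numeric_column(df[[k]], names(df)[k])
      if (all(is.na(v))) stop("column '", names(df)[k], "' is empty", call. = FALSE)
      ca_trace(v, fps = fps, cell_id = k)
    })
  }
  ca_trace_table(traces, fps = fps, pacing_hz = pacing_hz)
}

check_numeric_column <- function(v, name) {
  if (is.numeric(v)) return(v)
  suppress <- suppressWarnings(as.numeric(as.character(v)))
  bad <- which(is.na(suppress) & !is.na(v) & nzchar(as.character(v)))
  if (length(bad) > 0)
    stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                 name, bad[1], as.character(v[bad[1]])), call. = FALSE)
  suppress
}

#' Write traces to CSV
#'
#' Columns: `frame` (0-based), `time_ms`, then one column per cell.
#'
#' @param table a [ca_trace_table()] or list of [ca_trace()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(table, path) {
  traces <- if (inherits(table, "ca_trace_table")) table$traces else table
  n <- length(traces[[1]]$values)
  out <- data.frame(frame = seq_len(n) - 1L,
                    time_ms = trace_times_ms(traces[[1]]))
  for (tr in traces) out[[paste0("cell_", tr$cell_id)]] <- tr$values
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# fixed, documented column order of the parameter table
PARAMETER_COLUMNS <- c(
  "f0", "fmax", "magnitude", "fmax_over_f0", "redefined_baseline",
  "t_on", "t10_on", "t50_on", "t90_on",
  "t_off", "t10_off", "t50_off", "t90_off",
  "cd", "tau", "fit_a", "fit_b", "fit_c", "fit_gof",
  "snr", "n_beats", "beat_to_beat_ms", "n_intervals"
)

params_to_row <- function(p) {
  row <- lapply(PARAMETER_COLUMNS, function(cn) {
    v <- p[[cn]]
    if (is.null(v) || length(v) != 1) NA_real_ else as.numeric(v)
  })
  names(row) <- PARAMETER_COLUMNS
  row$flags <- paste(p$flags, collapse = ";")
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Write per-cell parameter tables
#'
#' Writes the analysis results as plain CSV, one file per output class sharing
#' the stem of `path`: `<stem>.csv` holds one row per cell (averaged-transient
#' parameters), `<stem>_beats.csv` holds per-beat rows plus one `SD` row per
#' cell (the across-beat SD quality-control metric) when per-beat output is
#' present, and `<stem>_irregularity.csv` holds per-event rows when
#' irregularity reports are present.
#'
#' @param fits nonempty list of [ca_analyze()] results (class `ca_fit`), or a
#'   single `ca_fit`.
#' @param path output path; its extension is replaced per output class.
#' @return named character vector of the files written, invisibly.
#' @export
write_parameters <- function(fits, path) {
  if (inherits(fits, "ca_fit")) fits <- list(fits)
  if (length(fits) == 0) stop("no records to write", call. = FALSE)
  stem <- tools::file_path_sans_ext(path)
  written <- c(parameters = paste0(stem, ".csv"))

  main <- do.call(rbind, lapply(fits, function(f) {
    cbind(data.frame(cell_id = f$trace$cell_id), params_to_row(f$params))
  }))
  write.csv(main, written[["parameters"]], row.names = FALSE)

  beats <- lapply(fits, function(f) {
    if (is.null(f$per_beat)) return(NULL)
    pb <- do.call(rbind, lapply(seq_along(f$per_beat$params), function(b) {
      cbind(data.frame(cell_id = f$trace$cell_id, beat = as.character(b)),
            params_to_row(f$per_beat$params[[b]]))
    }))
    sdrow <- cbind(data.frame(cell_id = f$trace$cell_id, beat = "SD"),
                   as.data.frame(as.list(f$per_beat$sd)), flags = "")
    names(sdrow) <- names(pb)
    rbind(pb, sdrow)
  })
  beats <- do.call(rbind, beats[!vapply(beats, is.null, logical(1))])
  if (!is.null(beats) && nrow(beats) > 0) {
    written[["beats"]] <- paste0(stem, "_beats.csv")
    write.csv(beats, written[["beats"]], row.names = FALSE)
  }

  irr <- lapply(fits, function(f) {
    r <- f$irregularity
    if (is.null(r) || length(r$events) == 0) return(NULL)
    do.call(rbind, lapply(r$events, function(e) {
      data.frame(cell_id = f$trace$cell_id, beat = e$beat, class = e$class,
                 time_ms = e$time_ms)
    }))
  })
  irr <- do.call(rbind, irr[!vapply(irr, is.null, logical(1))])
  if (!is.null(irr) && nrow(irr) > 0) {
    written[["irregularity"]] <- paste0(stem, "_irregularity.csv")
    write.csv(irr, written[["irregularity"]], row.names = FALSE)
  }
  invisible(written)
}
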