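#' Multichannel resting-state recording
#'
#' Container for a multichannel time series with sampling rate, per-channel
#' metadata (label, 2-D layout position, hemisphere, optional region label),
#' optional artifact reference channels (cardiac, ocular) and bad-segment
#' annotations. All preprocessing and spectral functions operate on this
#' class.
#'
#' @param data numeric matrix, channels x samples.
#' @param sfreq sampling rate in Hz (> 0).
#' @param channel_meta data.frame with one row per channel and at least a
#'   `label` column; columns `x`, `y` (layout position) and `hemisphere`
#'   (`"L"`, `"R"` or `"midline"`) are filled with defaults when absent.
#' @param reference named list of numeric vectors (e.g. `ecg`, `eog`), each
#'   the same length as a data row.
#' @param annotations data.frame with columns `start`, `end` (seconds) and
#'   `kind`, marking bad segments.
#' @return An object of class `meg_recording`.
#' @export
meg_recording <- function(data, sfreq, channel_meta = NULL,
                          reference = list(), annotations = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_invalid("data must be a numeric channels x samples matrix")
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0)
    stop_invalid("sampling rate must be a single positive number, got %s",
                 deparse(sfreq))
  nch <- nrow(data)
  if (is.null(channel_meta)) channel_meta <- default_channel_meta(nch)
  if (!is.data.frame(channel_meta) || nrow(channel_meta) != nch)
    stop_invalid("channel_meta must have one row per channel (%d)", nch)
  if (is.null(channel_meta$label))
    channel_meta$label <- sprintf("CH%03d", seq_len(nch))
  rownames(data) <- channel_meta$label
  if (is.null(annotations))
    annotations <- data.frame(start = numeric(0), end = numeric(0),
                              kind = character(0))
  dur <- ncol(data) / sfreq
  if (nrow(annotations)) {
    if (any(annotations$end <= annotations$start))
      stop_invalid("annotation end must exceed start")
    if (any(annotations$start < 0) || any(annotations$end > dur + 1e-9))
      stop_invalid("annotations must lie within [0, %.3f] s", dur)
  }
  for (nm in names(reference)) {
    if (length(reference[[nm]]) != ncol(data))
      stop_invalid("reference channel '%s' length differs from data", nm)
  }
  structure(list(data = data, sfreq = sfreq, channel_meta = channel_meta,
                 reference = reference, annotations = annotations),
            class = "meg_recording")
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf("<meg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sfreq, duration(x)))
  if (length(x$reference))
    cat("  reference channels:", paste(names(x$reference), collapse = ", "), "\n")
  if (nrow(x$annotations))
    cat(sprintf("  %d bad-segment annotation(s)\n", nrow(x$annotations)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `meg_recording`.
#' @export
duration <- function(rec) ncol(rec$data) / rec$sfreq

#' Default circular 2-D sensor layout
#'
#' Places `n` sensors on concentric rings of a unit disc and labels each as
#' left-, right-hemisphere or midline by its x coordinate. Stands in for a
#' helmet geometry when none is supplied.
#'
#' @param n number of channels.
#' @return data.frame with columns `label`, `x`, `y`, `hemisphere`.
#' @export
default_channel_meta <- function(n) {
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 0.5
  r <- sqrt(i / n)
  th <- i * golden
  x <- r * cos(th)
  y <- r * sin(th)
  hemi <- ifelse(abs(x) < 0.05, "midline", ifelse(x < 0, "L", "R"))
  data.frame(label = sprintf("CH%03d", seq_len(n)),
             x = x, y = y, hemisphere = hemi)
}

#' Drop channels from a recording
#' @param rec a `meg_recording`.
#' @param labels channel labels to remove (e.g. sensors with low
#'   signal-to-noise ratio, which are excluded rather than interpolated).
#' @export
drop_channels <- function(rec, labels) {
  if (!length(labels)) return(rec)
  keep <- !(rec$channel_meta$label %in% labels)
  if (!any(keep)) stop_invalid("dropping all channels")
  rec$data <- rec$data[keep, , drop = FALSE]
  rec$channel_meta <- rec$channel_meta[keep, , drop = FALSE]
  rec
}

#' Write / read a recording as a self-describing directory
#'
#' The on-disk form is plain text: `meta.json` carries the sampling rate,
#' channel table and annotations; `data.tsv` the channels x samples matrix;
#' `reference.tsv` the reference traces. `read_recording` is the exact
#' inverse (numeric round-trip at full double precision).
#'
#' @param rec a `meg_recording`.
#' @param path directory to create/overwrite.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `meg_recording`.
#' @export
write_recording <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(sfreq = rec$sfreq,
               channel_meta = rec$channel_meta,
               annotations = rec$annotations,
               reference_names = names(rec$reference) %||% character(0))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE)
  data.table::fwrite(data.table::as.data.table(t(rec$data)),
                     file.path(path, "data.tsv"), sep = "\t")
  if (length(rec$reference))
    data.table::fwrite(data.table::as.data.table(rec$reference),
                       file.path(path, "reference.tsv"), sep = "\t")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  dat <- t(as.matrix(data.table::fread(file.path(path, "data.tsv"))))
  ref <- list()
  rf <- file.path(path, "reference.tsv")
  if (file.exists(rf)) {
    rtab <- data.table::fread(rf)
    ref <- lapply(as.list(rtab), as.numeric)
  }
  ann <- as.data.frame(meta$annotations)
  if (!nrow(ann)) ann <- NULL
  meg_recording(dat, meta$sfreq,
                channel_meta = as.data.frame(meta$channel_meta),
                reference = ref, annotations = ann)
}

#' Region-level time series
#'
#' Regions x samples matrix with per-region metadata (name, hemisphere,
#' number of source grid points contributing to the region). Produced either
#' by averaging source grid traces over an atlas region or directly by the
#' simulator, which stands in for a source-imaging inverse solution.
#'
#' @param data numeric matrix, regions x samples.
#' @param sfreq sampling rate in Hz.
#' @param region_meta data.frame with columns `name`, `hemisphere`,
#'   `n_grid_points`.
#' @return An object of class `region_timeseries`.
#' @export
region_timeseries <- function(data, sfreq, region_meta) {
  if (!is.matrix(data)) stop_invalid("data must be a regions x samples matrix")
  if (!is.data.frame(region_meta) || nrow(region_meta) != nrow(data))
    stop_invalid("region_meta must have one row per region")
  stopifnot(all(c("name", "hemisphere", "n_grid_points") %in% names(region_meta)))
  rownames(data) <- region_meta$name
  structure(list(data = data, sfreq = sfreq, region_meta = region_meta),
            class = "region_timeseries")
}

#' @export
print.region_timeseries <- function(x, ...) {
  cat(sprintf("<region_timeseries> %d regions x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$sfreq))
  invisible(x)
}
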