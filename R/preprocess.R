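#' Preprocessing configuration
#'
#' @param notch_freqs powerline frequency and harmonics to notch out
#'   (e.g. `c(50, 100, 150)` or `c(60, 120, 180)`).
#' @param bandpass `c(low, high)` pass band in Hz; default 1-200 Hz.
#' @param bad_channels labels of sensors to exclude (never interpolated).
#' @param ssp named list per artifact kind (`cardiac`, `ocular`) with
#'   `n_components` and `window = c(pre_s, post_s)` around each event.
#' @export
preprocess_config <- function(notch_freqs = c(50, 100, 150),
                              bandpass = c(1, 200),
                              bad_channels = character(0),
                              ssp = list(
                                cardiac = list(n_components = 1,
                                               window = c(0.2, 0.2)),
                                ocular = list(n_components = 1,
                                              window = c(0.3, 0.3)))) {
  if (length(bandpass) != 2 || bandpass[1] <= 0 || bandpass[1] >= bandpass[2])
    stop_invalid("bandpass must satisfy 0 < low < high")
  structure(list(notch_freqs = notch_freqs, bandpass = bandpass,
                 bad_channels = bad_channels, ssp = ssp),
            class = "preprocess_config")
}

#' Notch filter at powerline frequencies
#'
#' Zero-phase narrow band-stop (second-order Butterworth per frequency,
#' stop band `f (1 +/- 1/(2Q))`, applied forward-backward) at each listed
#' frequency. An empty frequency list returns the input unchanged.
#'
#' @param rec a [meg_recording()].
#' @param freqs frequencies in Hz, each below Nyquist.
#' @param q quality factor; the stop-band width is about `f / q` Hz.
#' @export
notch_filter <- function(rec, freqs, q = 30) {
  if (!length(freqs)) return(rec)
  nyq <- rec$sfreq / 2
  if (any(freqs >= nyq))
    stop_invalid("notch frequency >= Nyquist (%g Hz)", nyq)
  data <- rec$data
  for (f0 in freqs) {
    half_bw <- f0 / (2 * q)
    filt <- signal::butter(2, c(f0 - half_bw, f0 + half_bw) / nyq,
                           type = "stop")
    npad <- min(ncol(data) - 1, round(3 * rec$sfreq / (2 * half_bw)))
    data <- filtfilt_rows(filt, data, npad)
    for (nm in names(rec$reference))
      rec$reference[[nm]] <- filtfilt_pad(filt, rec$reference[[nm]], npad)
  }
  rec$data <- data
  rec
}

#' Band-pass filter
#'
#' Zero-phase Butterworth band pass, realized as a cascaded order-4
#' high-pass at `low` and order-4 low-pass at `high`, each applied
#' forward-backward (so no group delay in the pass band). The cascade is
#' numerically stable even for a 1 Hz edge at typical MEG sampling rates.
#'
#' @param rec a [meg_recording()].
#' @param low,high band edges in Hz, `0 < low < high < Nyquist`.
#' @param order filter order per edge (doubled by the two passes).
#' @export
bandpass_filter <- function(rec, low = 1, high = 200, order = 4) {
  nyq <- rec$sfreq / 2
  if (!(low > 0 && low < high && high < nyq))
    stop_invalid("need 0 < low < high < Nyquist (%g Hz); got [%g, %g]",
                 nyq, low, high)
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  npad <- min(ncol(rec$data) - 1, round(3 * rec$sfreq / low))
  rec$data <- filtfilt_rows(lp, filtfilt_rows(hp, rec$data, npad))
  rec
}

#' Detect stereotyped artifact events on a reference channel
#'
#' Band-limits the reference trace in a kind-appropriate range (cardiac:
#' 5-35 Hz to isolate the sharp deflection; ocular: below 5 Hz), z-scores
#' it, and returns the times of local maxima above `threshold`, enforcing a
#' refractory period (the larger peak wins). A flat reference yields an
#' empty result with a warning.
#'
#' @param ref numeric reference trace.
#' @param sfreq sampling rate in Hz.
#' @param kind `"cardiac"` or `"ocular"`.
#' @param threshold z-score threshold.
#' @param refractory_s minimum inter-event interval; defaults to 0.4 s for
#'   cardiac and 0.5 s for ocular.
#' @return numeric vector of event times in seconds.
#' @export
detect_artifact_events <- function(ref, sfreq, kind = c("cardiac", "ocular"),
                                   threshold = 3, refractory_s = NULL) {
  kind <- match.arg(kind)
  if (is.null(refractory_s))
    refractory_s <- if (kind == "cardiac") 0.4 else 0.5
  if (stats::sd(ref) == 0) {
    warning("flat reference channel: no events detected")
    return(numeric(0))
  }
  nyq <- sfreq / 2
  filt <- if (kind == "cardiac")
    signal::butter(2, c(5, min(35, 0.9 * nyq)) / nyq, type = "pass")
  else
    signal::butter(2, min(5, 0.9 * nyq) / nyq, type = "low")
  z <- filtfilt_pad(filt, ref, min(length(ref) - 1, round(3 * sfreq / 5)))
  z <- abs(z - mean(z)) / stats::sd(z)
  n <- length(z)
  is_peak <- z > threshold &
    z >= c(-Inf, z[-n]) & z >= c(z[-1], -Inf)
  cand <- which(is_peak)
  if (!length(cand)) return(numeric(0))
  # greedy refractory suppression, strongest peak first
  ord <- cand[order(z[cand], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  gap <- refractory_s * sfreq
  for (i in ord)
    if (!length(kept) || all(abs(kept - i) >= gap)) kept <- c(kept, i)
  sort(kept) / sfreq
}

#' Compute a signal-space projector from event-locked epochs
#'
#' Epochs the data around the event times, averages the epochs (which
#' cancels activity not phase-locked to the artifact), and takes the
#' leading left singular vectors of the channels x epoch-time average as
#' the artifact spatial subspace.
#'
#' @param rec a [meg_recording()].
#' @param events event times in seconds.
#' @param window `c(pre_s, post_s)` epoch extent around each event.
#' @param n_components number of subspace dimensions (>= 1).
#' @param kind label stored on the projector.
#' @return A `ssp_projector` with orthonormal `basis`
#'   (channels x components) and per-component `explained_fraction` of the
#'   event-locked average energy.
#' @export
compute_ssp <- function(rec, events, window = c(0.2, 0.2), n_components = 1,
                        kind = "artifact") {
  if (n_components < 1) stop_invalid("n_components must be >= 1")
  fs <- rec$sfreq
  pre <- round(window[1] * fs)
  post <- round(window[2] * fs)
  ns <- ncol(rec$data)
  centers <- round(events * fs)
  ok <- centers - pre >= 1 & centers + post <= ns
  if (sum(ok) < 5)
    stop_insufficient("need >= 5 usable epochs, got %d", sum(ok))
  centers <- centers[ok]
  epoch_len <- pre + post + 1L
  avg <- matrix(0, nrow(rec$data), epoch_len)
  for (c0 in centers)
    avg <- avg + rec$data[, (c0 - pre):(c0 + post), drop = FALSE]
  avg <- avg / length(centers)
  avg <- avg - rowMeans(avg)
  sv <- svd(avg, nu = min(n_components, nrow(avg)))
  structure(list(basis = sv$u[, seq_len(n_components), drop = FALSE],
                 kind = kind,
                 explained_fraction = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)],
                 n_epochs = length(centers)),
            class = "ssp_projector")
}

#' Apply a signal-space projector
#'
#' Projects every sample onto the orthogonal complement of the artifact
#' subspace: `x <- (I - B B') x`. Idempotent, and never increases channel
#' variance. An empty basis returns the input unchanged.
#'
#' @param rec a [meg_recording()].
#' @param proj a `ssp_projector` (or list of them, applied in order).
#' @export
apply_projector <- function(rec, proj) {
  if (inherits(proj, "ssp_projector")) proj <- list(proj)
  for (p in proj) {
    if (is.null(p$basis) || ncol(p$basis) == 0) next
    if (nrow(p$basis) != nrow(rec$data))
      stop_invalid("projector has %d channels, recording has %d",
                   nrow(p$basis), nrow(rec$data))
    B <- p$basis
    rec$data <- rec$data - B %*% (crossprod(B, rec$data))
  }
  rec
}

# merge sorted possibly-overlapping intervals
merge_intervals <- function(ivals) {
  if (!nrow(ivals)) return(ivals)
  ivals <- ivals[order(ivals$start), , drop = FALSE]
  out <- ivals[1, , drop = FALSE]
  for (i in seq_len(nrow(ivals))[-1]) {
    j <- nrow(out)
    if (ivals$start[i] <= out$end[j]) out$end[j] <- max(out$end[j], ivals$end[i])
    else out <- rbind(out, ivals[i, , drop = FALSE])
  }
  out
}

#' Split a recording at bad-segment annotations
#'
#' Returns the maximal artifact-free spans as separate recordings.
#' Resulting spans shorter than `min_length_s` (one Welch window by
#' default) are discarded; the discard count is attached as attribute
#' `n_discarded`.
#'
#' @param rec a [meg_recording()] with annotations marking bad spans.
#' @param min_length_s minimum retained segment length in seconds.
#' @return list of [meg_recording()] segments.
#' @export
drop_bad_segments <- function(rec, min_length_s = 4) {
  dur <- duration(rec)
  ann <- rec$annotations
  if (nrow(ann) && (any(ann$start < 0) || any(ann$end > dur + 1e-9)))
    stop_invalid("annotation outside recording [0, %.3f] s", dur)
  bad <- merge_intervals(ann[, c("start", "end"), drop = FALSE])
  bounds <- c(0, as.vector(t(as.matrix(bad))), dur)
  good <- matrix(bounds, ncol = 2, byrow = TRUE)
  keep <- good[, 2] - good[, 1] >= min_length_s - 1e-9
  n_discarded <- sum(!keep & good[, 2] > good[, 1] + 1e-9)
  segs <- lapply(which(keep), function(i) {
    i0 <- floor(good[i, 1] * rec$sfreq) + 1L
    i1 <- floor(good[i, 2] * rec$sfreq)
    out <- rec
    out$data <- rec$data[, i0:i1, drop = FALSE]
    out$reference <- lapply(rec$reference, function(r) r[i0:i1])
    out$annotations <- rec$annotations[0, ]
    out
  })
  attr(segs, "n_discarded") <- n_discarded
  segs
}

#' Run the full preprocessing chain
#'
#' Bad-channel exclusion, powerline notch, band-pass, SSP of cardiac and
#' ocular artifacts (events detected on the reference channels), then
#' bad-segment exclusion. Returns the good segments plus a machine-readable
#' log of what was removed.
#'
#' @param rec a [meg_recording()].
#' @param config a [preprocess_config()].
#' @return list with `segments` (list of [meg_recording()]) and `log`
#'   (dropped channels/segments, per-kind event counts and explained
#'   fractions).
#' @export
preprocess <- function(rec, config = preprocess_config()) {
  log <- list(bad_channels = config$bad_channels)
  rec <- drop_channels(rec, config$bad_channels)
  rec <- notch_filter(rec, config$notch_freqs)
  rec <- bandpass_filter(rec, config$bandpass[1], config$bandpass[2])
  ref_for <- c(cardiac = "ecg", ocular = "eog")
  projs <- list()
  for (kind in names(config$ssp)) {
    refname <- ref_for[[kind]] %||% kind
    if (is.null(rec$reference[[refname]])) next
    cfgk <- config$ssp[[kind]]
    if (cfgk$n_components < 1) next
    ev <- detect_artifact_events(rec$reference[[refname]], rec$sfreq, kind)
    log[[paste0(kind, "_events")]] <- length(ev)
    pr <- tryCatch(
      compute_ssp(rec, ev, cfgk$window, cfgk$n_components, kind),
      megalpha_insufficient_data = function(e) NULL)
    if (is.null(pr)) next
    projs[[kind]] <- pr
    log[[paste0(kind, "_explained")]] <- pr$explained_fraction
  }
  if (length(projs)) rec <- apply_projector(rec, projs)
  segs <- drop_bad_segments(rec)
  log$n_segments <- length(segs)
  log$n_discarded_segments <- attr(segs, "n_discarded")
  list(segments = segs, log = log, projectors = projs)
}
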