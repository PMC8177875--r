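#' Welch PSD configuration
#'
#' Defaults match the analysis definition: 4-second Hamming windows with
#' 50% overlap, giving a frequency resolution of exactly
#' `1 / window_s = 0.25 Hz`, with per-window constant detrending.
#'
#' @param window_s window length in seconds (> 0).
#' @param overlap_fraction fractional overlap in `[0, 1)`.
#' @param taper window family; `"hamming"` or `"hann"`.
#' @param detrend `"constant"` (remove per-window mean) or `"none"`.
#' @export
welch_config <- function(window_s = 4, overlap_fraction = 0.5,
                         taper = c("hamming", "hann"),
                         detrend = c("constant", "none")) {
  if (window_s <= 0) stop_invalid("window_s must be > 0")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop_invalid("overlap_fraction must be in [0, 1)")
  structure(list(window_s = window_s, overlap_fraction = overlap_fraction,
                 taper = match.arg(taper), detrend = match.arg(detrend)),
            class = "welch_config")
}

taper_vector <- function(kind, n) {
  k <- seq_len(n) - 1L
  switch(kind,
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
         hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)))
}

#' Welch power spectral density over good segments
#'
#' Averages modified periodograms over all complete windows of all supplied
#' segments (window-count weighting, so the pooled estimate over segments
#' equals the estimate over their concatenation when windows align). The
#' result is a one-sided density in signal^2/Hz: the rectangle sum
#' `sum(power) * delta_f` approximates the signal variance.
#'
#' @param segments a [meg_recording()], [region_timeseries()], list of
#'   either, or a plain channels x samples matrix (then `sfreq` required).
#' @param cfg a [welch_config()].
#' @param sfreq sampling rate, only for matrix input.
#' @return A `spectral_density` object: `freqs` (Hz), `power`
#'   (signals x freqs), `n_windows`, `signal_meta`.
#' @export
welch_psd <- function(segments, cfg = welch_config(), sfreq = NULL) {
  if (inherits(segments, c("meg_recording", "region_timeseries")))
    segments <- list(segments)
  if (is.matrix(segments)) {
    if (is.null(sfreq)) stop_invalid("sfreq required for matrix input")
    segments <- list(list(data = segments, sfreq = sfreq))
  }
  fs <- segments[[1]]$sfreq
  meta <- segments[[1]]$channel_meta %||% segments[[1]]$region_meta
  for (s in segments) {
    if (abs(s$sfreq - fs) > 1e-9)
      stop_invalid("segments must share one sampling rate")
    if (nrow(s$data) != nrow(segments[[1]]$data))
      stop_invalid("segments must share the channel set")
  }
  nper <- cfg$window_s * fs
  if (abs(nper - round(nper)) > 1e-8)
    stop_invalid("window_s * sfreq must be an integer number of samples")
  nper <- as.integer(round(nper))
  step <- max(1L, as.integer(round(nper * (1 - cfg$overlap_fraction))))
  w <- taper_vector(cfg$taper, nper)
  wnorm <- fs * sum(w^2)
  nfreq <- nper %/% 2L + 1L
  acc <- matrix(0, nrow(segments[[1]]$data), nfreq)
  n_windows <- 0L
  for (s in segments) {
    ns <- ncol(s$data)
    if (ns < nper) next
    starts <- seq(1L, ns - nper + 1L, by = step)
    for (st in starts) {
      seg <- s$data[, st:(st + nper - 1L), drop = FALSE]
      if (cfg$detrend == "constant") seg <- seg - rowMeans(seg)
      X <- stats::mvfft(t(seg * rep(w, each = nrow(seg))))
      P <- (Mod(X[seq_len(nfreq), , drop = FALSE])^2) / wnorm
      P[2:(nfreq - 1L), ] <- 2 * P[2:(nfreq - 1L), ]  # one-sided
      acc <- acc + t(P)
      n_windows <- n_windows + 1L
    }
  }
  if (n_windows == 0L)
    stop_insufficient("no segment is at least one Welch window (%g s) long",
                      cfg$window_s)
  structure(list(freqs = (seq_len(nfreq) - 1L) * (fs / nper),
                 power = acc / n_windows,
                 n_windows = n_windows,
                 signal_meta = meta,
                 delta_f = fs / nper),
            class = "spectral_density")
}

#' @export
print.spectral_density <- function(x, ...) {
  cat(sprintf("<spectral_density> %d signals x %d bins (df = %g Hz, %d windows)\n",
              nrow(x$power), length(x$freqs), x$delta_f, x$n_windows))
  invisible(x)
}

#' Frequency band scheme
#'
#' Named bands: theta 4-7.5, alpha 8-12.5, beta 13-30, low-gamma 30.5-60,
#' high-gamma 60.5-90 Hz (closed intervals over bin centers; at the default
#' 0.25 Hz resolution all edges fall on bin centers and the bands are
#' disjoint). The ratio bands are half-open, `[7, 9)` over `[9, 11)`, so
#' the shared 9 Hz bin is counted exactly once, in the denominator. The
#' alpha-peak search range is 7-13 Hz. DC and Nyquist bins never enter any
#' band.
#'
#' @param bands named list of `c(lo, hi)` closed intervals.
#' @param ratio_low,ratio_high half-open `[lo, hi)` intervals defining the
#'   alpha power ratio.
#' @param peak_search closed interval searched for the alpha peak.
#' @param prominence_factor a signal is flagged `no_clear_peak` when its
#'   maximum power in `peak_search` is below `prominence_factor` times the
#'   median power there.
#' @export
band_scheme <- function(bands = list(theta = c(4, 7.5), alpha = c(8, 12.5),
                                     beta = c(13, 30), low_gamma = c(30.5, 60),
                                     high_gamma = c(60.5, 90)),
                        ratio_low = c(7, 9), ratio_high = c(9, 11),
                        peak_search = c(7, 13), prominence_factor = 1.2) {
  structure(list(bands = bands, ratio_low = ratio_low,
                 ratio_high = ratio_high, peak_search = peak_search,
                 prominence_factor = prominence_factor),
            class = "band_scheme")
}

band_bin_index <- function(psd, band, right_open = FALSE) {
  f <- psd$freqs
  interior <- seq_along(f) > 1L & seq_along(f) < length(f)  # drop DC/Nyquist
  eps <- 1e-9
  sel <- if (right_open)
    f >= band[1] - eps & f < band[2] - eps
  else
    f >= band[1] - eps & f <= band[2] + eps
  which(sel & interior)
}

#' Mean band power
#'
#' Arithmetic mean of the PSD over the bins whose centers fall in `band`
#' (closed by default, right-open for the ratio bands). The mean rather
#' than the sum makes bands of different widths comparable.
#'
#' @param psd a `spectral_density`.
#' @param band `c(lo, hi)` in Hz.
#' @param right_open use `[lo, hi)` instead of `[lo, hi]`.
#' @return named numeric, one value per signal.
#' @export
band_power <- function(psd, band, right_open = FALSE) {
  idx <- band_bin_index(psd, band, right_open)
  if (!length(idx))
    stop_invalid("band [%g, %g] Hz contains no bins at df = %g Hz",
                 band[1], band[2], psd$delta_f)
  rowMeans(psd$power[, idx, drop = FALSE])
}

#' Alpha peak frequency
#'
#' Frequency of the maximal PSD bin within the peak search range (7-13 Hz
#' by default); ties resolve to the lowest frequency. To decide whether a
#' signal has a clear peak at all, the search-range spectrum is first
#' compensated for the aperiodic background (a log-log linear fit over the
#' search range is divided out, so a peakless 1/f slope becomes flat); a
#' signal is flagged `no_clear_peak` when the compensated maximum is below
#' `prominence_factor` times the compensated median. The reported peak
#' location always comes from the raw spectrum.
#'
#' @param psd a `spectral_density`.
#' @param scheme a [band_scheme()].
#' @return data.frame with `alpha_peak_freq` (Hz) and `no_clear_peak`.
#' @export
alpha_peak_frequency <- function(psd, scheme = band_scheme()) {
  idx <- band_bin_index(psd, scheme$peak_search)
  if (length(idx) < 3L)
    stop_invalid("peak search range must contain >= 3 bins")
  sub <- psd$power[, idx, drop = FALSE]
  imax <- apply(sub, 1L, which.max)  # first max = lowest frequency on ties
  # aperiodic compensation: per-signal least-squares line in log-log space
  lf <- log10(psd$freqs[idx])
  X <- cbind(1, lf)
  floorv <- pmax(sub, .Machine$double.xmin)
  L <- log10(floorv)
  B <- solve(crossprod(X), crossprod(X, t(L)))       # 2 x n_signals
  comp <- floorv / t(10^(X %*% B))
  # light spectral smoothing (3-bin moving average) stabilizes the
  # prominence decision against periodogram noise; peak location is not
  # smoothed
  nc <- ncol(comp)
  comp <- (comp[, c(1, 1:(nc - 1)), drop = FALSE] + comp +
           comp[, c(2:nc, nc), drop = FALSE]) / 3
  cmax <- apply(comp, 1L, max)
  cmed <- apply(comp, 1L, stats::median)
  data.frame(alpha_peak_freq = psd$freqs[idx][imax],
             no_clear_peak = cmax < scheme$prominence_factor * cmed)
}

#' Slow-to-fast alpha power ratio
#'
#' Mean power in the low alpha band (7-9 Hz) divided by mean power in the
#' middle alpha band (9-11 Hz). The ratio rises with increased theta-range
#' power, decreased alpha power, or a slowed dominant peak, and is
#' invariant to any overall channel gain.
#'
#' @inheritParams alpha_peak_frequency
#' @return named numeric per signal.
#' @export
alpha_power_ratio <- function(psd, scheme = band_scheme()) {
  num <- band_power(psd, scheme$ratio_low, right_open = TRUE)
  den <- band_power(psd, scheme$ratio_high, right_open = TRUE)
  if (any(den <= 0))
    stop_undefined("zero power in the %g-%g Hz band: ratio undefined",
                   scheme$ratio_high[1], scheme$ratio_high[2])
  num / den
}

#' Extract the seven spectral features
#'
#' Per signal: mean power in the theta, alpha, beta, low-gamma and
#' high-gamma bands, the alpha peak frequency (with a no-clear-peak flag),
#' and the slow-to-fast alpha power ratio.
#'
#' @inheritParams alpha_peak_frequency
#' @return data.frame (class `spectral_features`) with one row per signal:
#'   `signal_id`, the five band powers, `alpha_peak_freq`, `no_clear_peak`,
#'   `alpha_power_ratio`.
#' @export
extract_features <- function(psd, scheme = band_scheme()) {
  bp <- lapply(scheme$bands, function(b) band_power(psd, b))
  names(bp) <- paste0(names(scheme$bands), "_power")
  pk <- alpha_peak_frequency(psd, scheme)
  ids <- psd$signal_meta$label %||% psd$signal_meta$name %||%
    sprintf("S%03d", seq_len(nrow(psd$power)))
  out <- data.frame(signal_id = ids, bp, pk,
                    alpha_power_ratio = alpha_power_ratio(psd, scheme))
  rownames(out) <- NULL
  class(out) <- c("spectral_features", "data.frame")
  out
}

#' Names of the seven spectral features
#' @export
feature_names <- function() {
  c("theta_power", "alpha_power", "beta_power", "low_gamma_power",
    "high_gamma_power", "alpha_peak_freq", "alpha_power_ratio")
}

#' Average features over sensors
#'
#' Arithmetic mean of each feature over all retained signals, as used for
#' whole-head summaries. Signals flagged `no_clear_peak` are excluded from
#' the peak-frequency mean only; the number excluded is attached as an
#' attribute. If every signal is flagged the peak-frequency mean is `NA`.
#'
#' @param features a `spectral_features` data.frame.
#' @return named numeric over [feature_names()], with attribute
#'   `n_peak_excluded`.
#' @export
sensor_average <- function(features) {
  if (!nrow(features)) stop_invalid("no signals to average")
  out <- vapply(feature_names(), function(fn) {
    if (fn == "alpha_peak_freq") {
      ok <- !features$no_clear_peak
      if (!any(ok)) return(NA_real_)
      mean(features$alpha_peak_freq[ok])
    } else mean(features[[fn]])
  }, numeric(1))
  attr(out, "n_peak_excluded") <- sum(features$no_clear_peak)
  out
}

#' Region retention rule
#'
#' Keeps regions backed by strictly more than `min_points` source grid
#' points, mirroring the retention of atlas regions with more than 20
#' source locations.
#'
#' @param region_meta data.frame with an `n_grid_points` column.
#' @param min_points threshold (kept iff `n_grid_points > min_points`).
#' @return the retained rows of `region_meta`.
#' @export
filter_regions <- function(region_meta, min_points = 20) {
  if (is.null(region_meta$n_grid_points))
    stop_invalid("region_meta must carry n_grid_points")
  region_meta[region_meta$n_grid_points > min_points, , drop = FALSE]
}

#' Average source grid traces within regions
#'
#' @param grid_data points x samples matrix of source traces.
#' @param region_map factor/character of length `nrow(grid_data)` mapping
#'   each point to a region.
#' @param sfreq sampling rate in Hz.
#' @param region_meta optional metadata (`name`, `hemisphere`); grid-point
#'   counts are recomputed from the map.
#' @return a [region_timeseries()] whose rows are per-region arithmetic
#'   means across member points; regions with no member points are dropped
#'   with a warning.
#' @export
average_region_timeseries <- function(grid_data, region_map, sfreq,
                                      region_meta = NULL) {
  if (length(region_map) != nrow(grid_data))
    stop_invalid("region_map must map every grid point")
  region_map <- as.factor(region_map)
  counts <- table(region_map)
  empty <- names(counts)[counts == 0]
  if (length(empty))
    warning(sprintf("dropping %d region(s) with no grid points: %s",
                    length(empty), paste(empty, collapse = ", ")))
  keep <- names(counts)[counts > 0]
  data <- t(vapply(keep, function(r)
    colMeans(grid_data[region_map == r, , drop = FALSE]),
    numeric(ncol(grid_data))))
  meta <- data.frame(name = keep,
                     hemisphere = "midline",
                     n_grid_points = as.integer(counts[keep]))
  if (!is.null(region_meta)) {
    m <- match(keep, region_meta$name)
    if (!anyNA(m)) meta$hemisphere <- region_meta$hemisphere[m]
  }
  region_timeseries(data, sfreq, meta)
}
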