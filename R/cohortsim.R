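#' Specification of a narrowband cortical oscillator
#'
#' Oscillators are realized as narrowband-filtered Gaussian noise: a source
#' trace whose power spectral density is Gaussian-shaped around
#' `center_freq` with full width at half maximum `bandwidth`, scaled to RMS
#' `amplitude` and projected onto channels by a nonnegative `topography`
#' weight vector. This produces spectral peaks with realistic width rather
#' than line spectra.
#'
#' @param center_freq peak frequency in Hz (> 0).
#' @param bandwidth spectral full width at half maximum in Hz (> 0).
#' @param amplitude source RMS in signal units (>= 0; 0 disables the
#'   oscillator, used for subjects without a clear alpha peak).
#' @param topography `NULL` for the default posterior-weighted topography,
#'   a numeric vector of per-channel nonnegative weights, or a function
#'   `f(channel_meta)` returning such a vector.
#' @return An `oscillator_spec` object.
#' @export
oscillator_spec <- function(center_freq, bandwidth = 1.5, amplitude = 0.35,
                            topography = NULL) {
  if (center_freq <= 0) stop_invalid("center_freq must be > 0")
  if (bandwidth <= 0) stop_invalid("bandwidth must be > 0")
  if (amplitude < 0) stop_invalid("amplitude must be >= 0")
  if (is.numeric(topography) && !any(topography > 0) && amplitude > 0)
    stop_invalid("at least one topography weight must be > 0")
  structure(list(center_freq = center_freq, bandwidth = bandwidth,
                 amplitude = amplitude, topography = topography),
            class = "oscillator_spec")
}

#' Aperiodic (1/f) background specification
#'
#' The background one-sided PSD is `10^offset / f^exponent` (signal^2/Hz),
#' independent across channels, giving every channel a broadband floor so
#' band powers and ratios are well defined.
#'
#' @param offset log10 power at 1 Hz.
#' @param exponent spectral decay exponent (>= 0); 0 gives white noise.
#' @export
aperiodic_spec <- function(offset = -1, exponent = 1) {
  if (exponent < 0) stop_invalid("aperiodic exponent must be >= 0")
  structure(list(offset = offset, exponent = exponent),
            class = "aperiodic_spec")
}

#' Artifact configuration
#'
#' Stereotyped physiological and environmental artifacts: a cardiac
#' spike-like waveform repeated at a jittered inter-beat interval with a
#' fixed random topography, a slow biphasic ocular blink transient with a
#' frontal topography, and a powerline sinusoid. Clean copies of the
#' cardiac and ocular trains are exposed as reference channels (`ecg`,
#' `eog`) so projection-based removal can be exercised.
#'
#' @param cardiac_rate beats per minute (>= 0; 0 disables).
#' @param cardiac_amp peak amplitude in signal units.
#' @param blink_rate blinks per minute (>= 0).
#' @param blink_amp peak amplitude in signal units.
#' @param line_freq powerline frequency in Hz.
#' @param line_amp per-channel sinusoid amplitude in signal units.
#' @export
artifact_config <- function(cardiac_rate = 60, cardiac_amp = 0.5,
                            blink_rate = 15, blink_amp = 1,
                            line_freq = 50, line_amp = 0.2) {
  if (cardiac_rate < 0 || blink_rate < 0)
    stop_invalid("artifact rates must be >= 0")
  structure(list(cardiac_rate = cardiac_rate, cardiac_amp = cardiac_amp,
                 blink_rate = blink_rate, blink_amp = blink_amp,
                 line_freq = line_freq, line_amp = line_amp),
            class = "artifact_config")
}

#' Per-subject generative specification
#'
#' @param group `"control"` or `"patient"`.
#' @param oscillators list of [oscillator_spec()] objects.
#' @param aperiodic an [aperiodic_spec()].
#' @param artifacts an [artifact_config()], or `NULL` for none.
#' @param covariates named numeric scalars (e.g. `pain_vas_24h`,
#'   `depression_score`).
#' @param seed integer; fixes the subject's realization bit-for-bit.
#' @export
subject_spec <- function(group = c("control", "patient"),
                         oscillators = list(oscillator_spec(10.25)),
                         aperiodic = aperiodic_spec(),
                         artifacts = artifact_config(),
                         covariates = c(), seed = 1L) {
  group <- match.arg(group)
  if (inherits(oscillators, "oscillator_spec")) oscillators <- list(oscillators)
  stopifnot(all(vapply(oscillators, inherits, TRUE, "oscillator_spec")))
  structure(list(group = group, oscillators = oscillators,
                 aperiodic = aperiodic, artifacts = artifacts,
                 covariates = covariates, seed = as.integer(seed)),
            class = "subject_spec")
}

# ---- internal generators ---------------------------------------------------

# Gaussian noise with target one-sided PSD S(f) via frequency-domain shaping.
# White unit-variance noise at fs has one-sided PSD 2/fs, so the shaping
# gain is sqrt(S(f) * fs / 2).
colored_noise <- function(ns, fs, psd_fun) {
  k <- seq_len(ns) - 1L
  fall <- pmin(k, ns - k) * (fs / ns)  # |f| for every FFT bin
  gain <- sqrt(pmax(psd_fun(fall), 0) * fs / 2)
  gain[1] <- 0  # remove DC
  e <- stats::rnorm(ns)
  Re(stats::fft(stats::fft(e) * gain, inverse = TRUE)) / ns
}

aperiodic_trace <- function(ns, fs, ap) {
  f0 <- fs / ns
  colored_noise(ns, fs, function(f) 10^ap$offset / pmax(f, f0)^ap$exponent)
}

oscillator_trace <- function(ns, fs, center, bandwidth) {
  sigma <- bandwidth / (2 * sqrt(2 * log(2)))
  x <- colored_noise(ns, fs, function(f) exp(-(f - center)^2 / (2 * sigma^2)))
  x / stats::sd(x)
}

# Posterior (occipital) Gaussian topography on the 2-D layout; peak weight 1.
alpha_topography <- function(channel_meta, center = c(0, -0.7), width = 0.45) {
  w <- exp(-((channel_meta$x - center[1])^2 +
             (channel_meta$y - center[2])^2) / (2 * width^2))
  w / max(w)
}

resolve_topography <- function(topo, channel_meta) {
  n <- nrow(channel_meta)
  if (is.null(topo)) return(alpha_topography(channel_meta))
  if (is.function(topo)) topo <- topo(channel_meta)
  if (length(topo) == 1L) topo <- rep(topo, n)
  if (length(topo) != n)
    stop_invalid("topography length %d != %d channels", length(topo), n)
  if (any(topo < 0)) stop_invalid("topography weights must be nonnegative")
  topo
}

cardiac_waveform <- function(fs) {
  t <- seq(-0.2, 0.2, by = 1 / fs)
  # narrow R spike flanked by smaller deflections plus a low T-like bump
  w <- exp(-(t / 0.012)^2) - 0.35 * exp(-((t - 0.035) / 0.02)^2) -
    0.25 * exp(-((t + 0.035) / 0.02)^2) + 0.2 * exp(-((t - 0.15) / 0.04)^2)
  w / max(abs(w))
}

blink_waveform <- function(fs) {
  t <- seq(-0.35, 0.35, by = 1 / fs)
  w <- -t * exp(-(t / 0.12)^2)  # biphasic slow transient
  w / max(abs(w))
}

place_events <- function(trace_len, fs, events_s, waveform, amps = 1) {
  out <- numeric(trace_len)
  half <- (length(waveform) - 1L) %/% 2L
  amps <- rep_len(amps, length(events_s))
  for (i in seq_along(events_s)) {
    c0 <- round(events_s[i] * fs)
    idx <- (c0 - half):(c0 - half + length(waveform) - 1L)
    ok <- idx >= 1L & idx <= trace_len
    out[idx[ok]] <- out[idx[ok]] + amps[i] * waveform[ok]
  }
  out
}

# Shared core for channel- and region-level simulation.
simulate_multichannel <- function(spec, duration, fs, meta) {
  ns <- round(duration * fs)
  n_sig <- nrow(meta)
  with_seed(spec$seed, {
    data <- matrix(0, n_sig, ns)
    for (ch in seq_len(n_sig))
      data[ch, ] <- aperiodic_trace(ns, fs, spec$aperiodic)
    for (osc in spec$oscillators) {
      if (osc$amplitude <= 0) next
      topo <- resolve_topography(osc$topography, meta)
      src <- osc$amplitude * oscillator_trace(ns, fs, osc$center_freq,
                                              osc$bandwidth)
      data <- data + outer(topo, src)
    }
    reference <- list()
    art <- spec$artifacts
    if (!is.null(art)) {
      tvec <- seq_len(ns) / fs
      if (art$cardiac_rate > 0 && art$cardiac_amp > 0) {
        ibi <- 60 / art$cardiac_rate
        beats <- cumsum(ibi * (1 + 0.05 * stats::rnorm(ceiling(duration / ibi) + 8L)))
        beats <- beats[beats < duration - 0.2]
        wf <- cardiac_waveform(fs)
        train <- place_events(ns, fs, beats, wf)
        topo_c <- stats::rnorm(n_sig)
        topo_c <- topo_c / sqrt(sum(topo_c^2))
        data <- data + art$cardiac_amp * outer(topo_c, train)
        reference$ecg <- train + 0.02 * stats::rnorm(ns)
        attr(reference$ecg, "events") <- beats
        attr(data, "cardiac_topography") <- topo_c
      }
      if (art$blink_rate > 0 && art$blink_amp > 0) {
        n_blinks <- stats::rpois(1, art$blink_rate * duration / 60)
        blinks <- sort(stats::runif(n_blinks, 0.5, duration - 0.5))
        # enforce a 1 s separation so transients stay distinct
        if (length(blinks) > 1) blinks <- blinks[c(TRUE, diff(blinks) > 1)]
        wf <- blink_waveform(fs)
        train <- place_events(ns, fs, blinks, wf)
        topo_b <- exp(-((meta$x)^2 + (meta$y - 0.8)^2) / (2 * 0.35^2))
        topo_b <- topo_b / max(topo_b)
        data <- data + art$blink_amp * outer(topo_b, train)
        reference$eog <- train + 0.02 * stats::rnorm(ns)
        attr(reference$eog, "events") <- blinks
      }
      if (art$line_amp > 0 && art$line_freq < fs / 2) {
        phase <- stats::runif(1, 0, 2 * pi)
        line <- sin(2 * pi * art$line_freq * tvec + phase)
        amps <- art$line_amp * stats::runif(n_sig, 0.5, 1)
        data <- data + outer(amps, line)
      }
    }
    list(data = data, reference = reference)
  })
}

#' Simulate one subject's resting-state recording
#'
#' Realizes the subject's generative model — aperiodic 1/f background plus
#' narrowband oscillators plus configured artifacts — as a multichannel
#' recording on a circular 2-D sensor layout. Identical `(spec, seed)`
#' yields bit-identical output.
#'
#' @param spec a [subject_spec()].
#' @param duration recording length in seconds (>= 8, i.e. at least two
#'   4-second Welch windows).
#' @param sampling_rate sampling rate in Hz.
#' @param n_channels number of sensors (>= 2).
#' @param channel_meta optional custom layout table; default circular.
#' @return A [meg_recording()] with `ecg`/`eog` reference channels when the
#'   corresponding artifacts are enabled.
#' @export
simulate_subject <- function(spec, duration = 300, sampling_rate = 600,
                             n_channels = 64, channel_meta = NULL) {
  if (duration < 8)
    stop_invalid("duration must be >= 8 s (two Welch windows), got %g", duration)
  if (n_channels < 2) stop_invalid("n_channels must be >= 2")
  meta <- channel_meta %||% default_channel_meta(n_channels)
  sim <- simulate_multichannel(spec, duration, sampling_rate, meta)
  topo_c <- attr(sim$data, "cardiac_topography")
  attr(sim$data, "cardiac_topography") <- NULL
  rec <- meg_recording(sim$data, sampling_rate, channel_meta = meta,
                       reference = sim$reference)
  attr(rec, "spec") <- spec
  if (!is.null(topo_c)) attr(rec, "cardiac_topography") <- topo_c
  rec
}

#' Simulate region-level time series
#'
#' Same generative model as [simulate_subject()], realized directly at the
#' level of atlas-like regions; stands in for source imaging plus
#' within-region averaging of source grid traces. Region metadata carries a
#' hemisphere label and the number of source grid points per region so the
#' region-retention rule can be applied downstream.
#'
#' @inheritParams simulate_subject
#' @param n_regions number of regions (>= 2); ignored when `region_meta`
#'   is given.
#' @param region_meta optional data.frame (`name`, `hemisphere`,
#'   `n_grid_points`, and layout `x`, `y`).
#' @return A [region_timeseries()].
#' @export
simulate_regions <- function(spec, n_regions = 8, duration = 300,
                             sampling_rate = 600, region_meta = NULL) {
  if (is.null(region_meta)) {
    if (n_regions < 2) stop_invalid("n_regions must be >= 2")
    region_meta <- default_region_meta(n_regions)
  }
  if (duration < 8)
    stop_invalid("duration must be >= 8 s (two Welch windows), got %g", duration)
  sim <- simulate_multichannel(spec, duration, sampling_rate, region_meta)
  rts <- region_timeseries(sim$data, sampling_rate, region_meta)
  attr(rts, "spec") <- spec
  rts
}

#' Default homologous-pair region table
#'
#' Builds `n` regions as left/right homologous pairs (`Region01_L`,
#' `Region01_R`, ...; one midline region when `n` is odd), each with
#' `n_grid_points = 100` and symmetric layout positions.
#'
#' @param n number of regions.
#' @export
default_region_meta <- function(n) {
  npair <- n %/% 2
  y <- seq(-0.8, 0.8, length.out = max(npair, 1))
  meta <- data.frame(name = character(0), hemisphere = character(0),
                     x = numeric(0), y = numeric(0))
  for (i in seq_len(npair)) {
    meta <- rbind(meta,
      data.frame(name = sprintf("Region%02d_%s", i, c("L", "R")),
                 hemisphere = c("L", "R"), x = c(-0.5, 0.5), y = y[i]))
  }
  if (n %% 2 == 1)
    meta <- rbind(meta, data.frame(name = "Midline01", hemisphere = "midline",
                                   x = 0, y = 0))
  meta$n_grid_points <- 100L
  meta$pair <- sub("_(L|R)$", "", meta$name)
  meta$pair[meta$hemisphere == "midline"] <- NA
  meta
}

# ---- cohort templates ------------------------------------------------------

#' Group-level generative templates
#'
#' A template is the distribution over [subject_spec()] parameters for one
#' group. The patient template follows the reported group structure:
#' slowed alpha peaks at 8.25 and/or 9.25 Hz assigned by a four-way mixture
#' (8.25 only / 9.25 only / both / no clear peak), against controls with a
#' single peak near 10.25 Hz. Per-subject peak frequency jitters by
#' `peak_sd` and amplitude is lognormal with `sdlog = amplitude_sdlog`.
#'
#' @param peak_freq control-group alpha peak center in Hz.
#' @param peak_sd between-subject SD of the peak frequency in Hz.
#' @param amplitude median oscillator source RMS in signal units.
#' @param amplitude_sdlog lognormal spread of amplitude across subjects.
#' @param bandwidth oscillator FWHM in Hz.
#' @param aperiodic_offset,aperiodic_exponent background parameters
#'   (log10 power at 1 Hz; decay exponent).
#' @param exponent_sd between-subject SD of the exponent.
#' @param artifacts an [artifact_config()] or `NULL`.
#' @param pain_link correlation between a patient's alpha slowing (negative
#'   standardized peak frequency) and the pain VAS covariate; 0 gives a
#'   null for correlation tests.
#' @export
group_template <- function(peak_freq = 10.25, peak_sd = 0.4,
                           amplitude = 0.35, amplitude_sdlog = 0.25,
                           bandwidth = 1.5,
                           aperiodic_offset = -1, aperiodic_exponent = 1,
                           exponent_sd = 0.1,
                           artifacts = artifact_config(),
                           pain_link = 0) {
  structure(list(peak_freq = peak_freq, peak_sd = peak_sd,
                 amplitude = amplitude, amplitude_sdlog = amplitude_sdlog,
                 bandwidth = bandwidth, aperiodic_offset = aperiodic_offset,
                 aperiodic_exponent = aperiodic_exponent,
                 exponent_sd = exponent_sd, artifacts = artifacts,
                 pain_link = pain_link),
            class = "group_template")
}

#' @rdname group_template
#' @export
control_template <- function(...) group_template(peak_freq = 10.25, ...)

#' @rdname group_template
#' @param peak_low,peak_mid the two slowed peak frequencies in Hz.
#' @param ... passed on to [group_template()].
#' @export
patient_template <- function(peak_low = 8.25, peak_mid = 9.25, ...) {
  tpl <- group_template(peak_freq = peak_mid, ...)
  tpl$peak_low <- peak_low
  tpl$peak_mid <- peak_mid
  class(tpl) <- c("patient_template", "group_template")
  tpl
}

#' Cohort specification
#'
#' @param n_control,n_patient group sizes (>= 2 each).
#' @param mixture named proportions over patient peak assignments
#'   `c(low=, mid=, both=, none=)`; must sum to 1. The default reproduces
#'   the reported patient composition 4/21, 11/21, 4/21, 2/21.
#' @param control,patient [group_template()] objects.
#' @param duration recording length (s).
#' @param sampling_rate Hz.
#' @param n_channels sensor count.
#' @param master_seed integer fixing the whole cohort.
#' @export
cohort_spec <- function(n_control = 25, n_patient = 21,
                        mixture = c(low = 4 / 21, mid = 11 / 21,
                                    both = 4 / 21, none = 2 / 21),
                        control = control_template(),
                        patient = patient_template(),
                        duration = 300, sampling_rate = 600,
                        n_channels = 64, master_seed = 1L) {
  if (n_control < 2 || n_patient < 2)
    stop_invalid("group sizes must be >= 2 (got %d, %d)", n_control, n_patient)
  if (!setequal(names(mixture), c("low", "mid", "both", "none")))
    stop_invalid("mixture must have names low, mid, both, none")
  if (abs(sum(mixture) - 1) > 1e-8)
    stop_invalid("mixture proportions must sum to 1 (sum = %g)", sum(mixture))
  structure(list(n_control = n_control, n_patient = n_patient,
                 mixture = mixture[c("low", "mid", "both", "none")],
                 control = control, patient = patient,
                 duration = duration, sampling_rate = sampling_rate,
                 n_channels = n_channels,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# Draw a subject_spec from a group template. `assignment` is one of
# "control", "low", "mid", "both", "none".
draw_subject_spec <- function(tpl, group, assignment, seed) {
  with_seed(seed, {
    amp <- tpl$amplitude * stats::rlnorm(1, 0, tpl$amplitude_sdlog)
    exponent <- max(0, stats::rnorm(1, tpl$aperiodic_exponent, tpl$exponent_sd))
    peaks <- switch(assignment,
      control = tpl$peak_freq + stats::rnorm(1, 0, tpl$peak_sd),
      low     = tpl$peak_low + stats::rnorm(1, 0, tpl$peak_sd),
      mid     = tpl$peak_mid + stats::rnorm(1, 0, tpl$peak_sd),
      both    = c(tpl$peak_low, tpl$peak_mid) + stats::rnorm(2, 0, tpl$peak_sd),
      none    = numeric(0))
    amps <- if (assignment == "both") rep(amp / sqrt(2), 2) else
      rep(amp, length(peaks))
    osc <- if (length(peaks))
      mapply(function(f, a) oscillator_spec(max(f, 1), tpl$bandwidth, a),
             peaks, amps, SIMPLIFY = FALSE)
    else list(oscillator_spec(10, tpl$bandwidth, 0))
    # slowing score drives the optional pain correlation (more slowing ->
    # higher pain when pain_link > 0)
    slow_z <- if (length(peaks)) (10.25 - mean(peaks)) / 1.5 else 1
    rho <- tpl$pain_link
    mix <- function(mu, sdv) {
      z <- rho * slow_z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(1)
      mu + sdv * z
    }
    covs <- if (group == "patient")
      c(pain_vas_24h = min(10, max(0, mix(6.1, 1.8))),
        pain_vas_now = min(10, max(0, mix(5.0, 2.4))),
        depression_score = max(0, stats::rnorm(1, 6, 3)))
    else
      c(pain_vas_24h = 0, pain_vas_now = 0,
        depression_score = max(0, stats::rnorm(1, 3, 2)))
    subject_spec(group = group, oscillators = osc,
                 aperiodic = aperiodic_spec(tpl$aperiodic_offset, exponent),
                 artifacts = tpl$artifacts, covariates = covs, seed = seed)
  })
}

#' Simulate a full cohort
#'
#' Draws per-subject generative parameters from the group templates (patient
#' peak assignments from the mixture), simulates each recording, and returns
#' the recordings with an aligned subject table. `master_seed` fixes
#' everything.
#'
#' @param cohort a [cohort_spec()].
#' @param simulate if `FALSE`, return only the subject table and the drawn
#'   `subject_spec`s without generating time series.
#' @return list with `recordings` (list of [meg_recording()]), `subjects`
#'   (data.frame: subject_id, group, assignment, seed, covariates) and
#'   `specs` (list of [subject_spec()]).
#' @export
simulate_cohort <- function(cohort, simulate = TRUE) {
  n <- cohort$n_control + cohort$n_patient
  seeds <- derive_seeds(cohort$master_seed, n + 1L)
  assign_pat <- with_seed(seeds[n + 1L],
    sample(names(cohort$mixture), cohort$n_patient, replace = TRUE,
           prob = cohort$mixture))
  group <- rep(c("control", "patient"), c(cohort$n_control, cohort$n_patient))
  assignment <- c(rep("control", cohort$n_control), assign_pat)
  specs <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tpl <- if (group[i] == "control") cohort$control else cohort$patient
    specs[[i]] <- draw_subject_spec(tpl, group[i], assignment[i], seeds[i])
    rows[[i]] <- data.frame(subject_id = sprintf("S%03d", i),
                            group = group[i], assignment = assignment[i],
                            seed = seeds[i],
                            t(specs[[i]]$covariates))
  }
  subjects <- do.call(rbind, rows)
  recordings <- if (simulate)
    lapply(specs, simulate_subject,
           duration = cohort$duration, sampling_rate = cohort$sampling_rate,
           n_channels = cohort$n_channels)
  else NULL
  list(recordings = recordings, subjects = subjects, specs = specs)
}
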