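# Shared fixtures, built in code.

# brute-force permutation p for small groups: enumerate every label split
# with an independent t implementation (stats::t.test)
brute_perm_p <- function(a, b) {
  x <- c(a, b); na <- length(a)
  combs <- combn(length(x), na)
  t_obs <- unname(t.test(a, b, var.equal = TRUE)$statistic)
  t_all <- apply(combs, 2, function(idx)
    unname(t.test(x[idx], x[-idx], var.equal = TRUE)$statistic))
  mean(abs(t_all) >= abs(t_obs) - 1e-12)
}

# recording holding pure tones (+ optional white noise), identical channels
tone_recording <- function(freqs, amps = 1, fs = 600, dur = 60, nch = 2,
                           noise_sd = 0, seed = 1) {
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  amps <- rep_len(amps, length(freqs))
  x <- Reduce(`+`, Map(function(f, a) a * sin(2 * pi * f * tt), freqs, amps),
              accumulate = FALSE)
  set.seed(seed)
  data <- matrix(rep(x, each = nch), nch) +
    matrix(rnorm(nch * length(tt), sd = noise_sd), nch)
  meg_recording(data, fs)
}

# quiet subject: aperiodic background only (optionally one oscillator).
# Example tests that assert an exact peak bin use a narrow bandwidth, so
# the spectral peak is sharply resolved against Welch estimator noise.
quiet_spec <- function(seed, peak = NULL, amplitude = 0.5, topography = 1,
                       exponent = 1, bandwidth = 0.3, offset = -1) {
  osc <- if (is.null(peak))
    list(oscillator_spec(10, amplitude = 0))
  else
    list(oscillator_spec(peak, bandwidth = bandwidth, amplitude = amplitude,
                         topography = topography))
  subject_spec("control", oscillators = osc, artifacts = NULL,
               aperiodic = aperiodic_spec(offset, exponent), seed = seed)
}

# hand-built spectral_density on the default 0.25 Hz grid
psd_fixture <- function(power_rows, fs = 600, window_s = 4) {
  nfreq <- window_s * fs / 2 + 1
  if (is.vector(power_rows)) power_rows <- matrix(power_rows, 1)
  stopifnot(ncol(power_rows) == nfreq)
  structure(list(freqs = (seq_len(nfreq) - 1) / window_s,
                 power = power_rows, n_windows = 1L,
                 signal_meta = NULL, delta_f = 1 / window_s),
            class = "spectral_density")
}

# frequency of max PSD within [lo, hi] for one channel
peak_in <- function(psd, ch = 1, lo = 7, hi = 13) {
  sel <- psd$freqs >= lo & psd$freqs <= hi
  psd$freqs[sel][which.max(psd$power[ch, sel])]
}

# small null cohort spec used by statistics tests: both groups drawn from
# the control template, no artifacts (preprocessing is identity for the
# group contrast), short recordings
null_cohort <- function(master_seed, n = 8, duration = 12, n_channels = 4,
                        fs = 300) {
  tpl <- control_template(artifacts = NULL)
  cohort_spec(n_control = n, n_patient = n,
              mixture = c(low = 0, mid = 0, both = 0, none = 1),
              control = tpl,
              patient = tpl,  # "patients" share the control generative model
              duration = duration, sampling_rate = fs,
              n_channels = n_channels, master_seed = master_seed)
}

# but for a true null the patient group must ignore the none-assignment
# (which zeroes the oscillator); build specs directly instead
null_feature_cohort <- function(master_seed, n = 8, duration = 12,
                                n_channels = 4, fs = 300) {
  seeds <- megalpha:::derive_seeds(master_seed, 2 * n)
  tpl <- control_template(artifacts = NULL)
  specs <- lapply(seeds, function(s)
    megalpha:::draw_subject_spec(tpl, "control", "control", s))
  recs <- lapply(specs, simulate_subject, duration = duration,
                 sampling_rate = fs, n_channels = n_channels)
  list(recs = recs, group = rep(c("a", "b"), each = n))
}

# sensor-average alpha power ratio of one recording (no preprocessing)
avg_ratio_of <- function(rec) {
  ft <- extract_features(welch_psd(rec))
  unname(sensor_average(ft)["alpha_power_ratio"])
}
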