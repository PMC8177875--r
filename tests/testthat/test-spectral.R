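test_that("Welch grid and peak align for a 10.25 Hz sinusoid", {
  rec <- tone_recording(10.25, fs = 600, dur = 300, nch = 1)
  psd <- welch_psd(rec)
  expect_identical(psd$delta_f, 0.25)
  expect_equal(diff(psd$freqs)[1], 0.25)
  expect_equal(psd$freqs[which.max(psd$power[1, ])], 10.25)
})

test_that("Welch PSD integrates to the sample variance for white noise", {
  set.seed(3)
  x <- matrix(rnorm(600 * 300, sd = 1.7), 1)
  psd <- welch_psd(x, sfreq = 600)
  expect_lt(abs(sum(psd$power) * psd$delta_f / var(x[1, ]) - 1), 0.05)
})

test_that("pooled-segment PSD is the window-count-weighted mean", {
  set.seed(4)
  s1 <- meg_recording(matrix(rnorm(2 * 6000), 2), 600)
  s2 <- meg_recording(matrix(rnorm(2 * 13200), 2), 600)
  p1 <- welch_psd(s1); p2 <- welch_psd(s2)
  pooled <- welch_psd(list(s1, s2))
  expect_equal(pooled$n_windows, p1$n_windows + p2$n_windows)
  manual <- (p1$power * p1$n_windows + p2$power * p2$n_windows) /
    (p1$n_windows + p2$n_windows)
  expect_equal(pooled$power, manual, tolerance = 1e-12)
})

test_that("Welch contracts: segment length, sampling-rate mismatch", {
  short <- meg_recording(matrix(rnorm(2 * 600), 2), 600)
  expect_error(welch_psd(short), class = "megalpha_insufficient_data")
  a <- meg_recording(matrix(rnorm(2 * 6000), 2), 600)
  b <- meg_recording(matrix(rnorm(2 * 6000), 2), 300)
  expect_error(welch_psd(list(a, b)), class = "megalpha_invalid_argument")
})

test_that("band power is the arithmetic mean over in-band bin centers", {
  nfreq <- 1201
  flat <- psd_fixture(rep(3, nfreq))
  scheme <- band_scheme()
  for (b in scheme$bands) expect_equal(unname(band_power(flat, b)), 3)
  # power 2 on theta bins only
  p <- rep(0, nfreq)
  freqs <- (seq_len(nfreq) - 1) / 4
  p[freqs >= 4 & freqs <= 7.5] <- 2
  stepped <- psd_fixture(p)
  expect_equal(unname(band_power(stepped, c(4, 7.5))), 2)
  expect_equal(unname(band_power(stepped, c(8, 12.5))), 0)
  # theta band at 0.25 Hz resolution spans bins 4.00..7.50: 15 bins
  expect_length(megalpha:::band_bin_index(flat, c(4, 7.5)), 15)
  # ratio bands are disjoint half-open intervals; 9.00 goes to the high band
  ilow <- megalpha:::band_bin_index(flat, c(7, 9), right_open = TRUE)
  ihigh <- megalpha:::band_bin_index(flat, c(9, 11), right_open = TRUE)
  expect_length(intersect(ilow, ihigh), 0)
  expect_true(9 %in% freqs[ihigh] && !(9 %in% freqs[ilow]))
  expect_error(band_power(flat, c(7.01, 7.24)),
               class = "megalpha_invalid_argument")
})

test_that("alpha peak frequency follows the max-bin rule with ties low", {
  nfreq <- 1201
  freqs <- (seq_len(nfreq) - 1) / 4
  base <- rep(1, nfreq)
  single <- base; single[freqs == 9.25] <- 10
  expect_equal(alpha_peak_frequency(psd_fixture(single))$alpha_peak_freq, 9.25)
  # exactly flat spectrum: lowest search bin, flagged
  flat <- alpha_peak_frequency(psd_fixture(base))
  expect_equal(flat$alpha_peak_freq, 7.00)
  expect_true(flat$no_clear_peak)
  # two equal maxima resolve to the lower frequency
  twin <- base; twin[freqs %in% c(8.25, 10.25)] <- 10
  expect_equal(alpha_peak_frequency(psd_fixture(twin))$alpha_peak_freq, 8.25)
})

test_that("alpha power ratio matches its definition and is gain-invariant", {
  nfreq <- 1201
  freqs <- (seq_len(nfreq) - 1) / 4
  flat <- psd_fixture(rep(2, nfreq))
  expect_equal(unname(alpha_power_ratio(flat)), 1.0)
  p <- rep(1, nfreq); p[freqs >= 7 & freqs < 9] <- 2
  expect_equal(unname(alpha_power_ratio(psd_fixture(p))), 2.0)
  # scaling the signal by 10 scales the PSD by 100, ratio unchanged
  r1 <- alpha_power_ratio(psd_fixture(p))
  r2 <- alpha_power_ratio(psd_fixture(100 * p))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("feature extraction recovers simulated oscillators end-to-end", {
  # sharp strong oscillator: exact peak-bin recovery on every channel
  sharp <- simulate_subject(quiet_spec(50, peak = 10.25, amplitude = 1.5),
                            duration = 60, n_channels = 3)
  fts <- extract_features(welch_psd(sharp))
  expect_true(all(fts$alpha_peak_freq == 10.25))
  expect_true(all(!fts$no_clear_peak))
  # realistic-width oscillators: slowed patient raises the alpha ratio
  ctl <- simulate_subject(quiet_spec(51, peak = 10.25, amplitude = 0.5,
                                     bandwidth = 1.5),
                          duration = 60, n_channels = 3)
  ftc <- extract_features(welch_psd(ctl))
  pat <- simulate_subject(quiet_spec(52, peak = 9.25, amplitude = 0.5,
                                     bandwidth = 1.5),
                          duration = 60, n_channels = 3)
  ftp <- extract_features(welch_psd(pat))
  expect_true(all(ftp$alpha_power_ratio > ftc$alpha_power_ratio))
  # zero-oscillator subject: no clear peak anywhere (default-length record)
  none <- simulate_subject(quiet_spec(53, peak = NULL), duration = 300,
                           n_channels = 3)
  ftn <- extract_features(welch_psd(none))
  expect_true(all(ftn$no_clear_peak))
})

test_that("features respond to channel gain as documented", {
  rec <- simulate_subject(quiet_spec(54, peak = 10.25), duration = 30,
                          n_channels = 2)
  scaled <- rec; scaled$data <- 10 * rec$data
  f1 <- extract_features(welch_psd(rec))
  f2 <- extract_features(welch_psd(scaled))
  for (bp in c("theta_power", "alpha_power", "beta_power",
               "low_gamma_power", "high_gamma_power"))
    expect_equal(f2[[bp]], 100 * f1[[bp]], tolerance = 1e-9)
  expect_equal(f2$alpha_power_ratio, f1$alpha_power_ratio, tolerance = 1e-9)
  expect_equal(f2$alpha_peak_freq, f1$alpha_peak_freq)
})

test_that("sensor averaging excludes flagged channels from the peak mean", {
  ft <- data.frame(signal_id = c("a", "b", "c"),
                   theta_power = c(1, 2, 3), alpha_power = c(1, 1, 1),
                   beta_power = c(2, 2, 2), low_gamma_power = c(1, 2, 3),
                   high_gamma_power = c(0.5, 1, 1.5),
                   alpha_peak_freq = c(10, 11, 7),
                   no_clear_peak = c(FALSE, FALSE, TRUE),
                   alpha_power_ratio = c(0.5, 1.5, 1))
  avg <- sensor_average(ft)
  expect_equal(unname(avg["alpha_power_ratio"]), 1.0)
  expect_equal(unname(avg["alpha_peak_freq"]), 10.5)
  expect_equal(attr(avg, "n_peak_excluded"), 1)
  # identical values pass through
  ft1 <- ft[1, ]; expect_equal(unname(sensor_average(ft1)["theta_power"]), 1)
  # all flagged: peak mean undefined, others intact
  ft$no_clear_peak <- TRUE
  avg2 <- sensor_average(ft)
  expect_true(is.na(avg2["alpha_peak_freq"]))
  expect_equal(unname(avg2["theta_power"]), 2)
})

test_that("region retention keeps regions with > 20 grid points", {
  meta <- data.frame(name = c("a", "b", "c"), hemisphere = "L",
                     n_grid_points = c(19, 20, 21))
  expect_equal(filter_regions(meta)$name, "c")
  meta$n_grid_points <- 100
  expect_equal(nrow(filter_regions(meta)), 3)
  # synthetic 99-region atlas with 84 regions above threshold
  set.seed(10)
  sizes <- c(sample(21:400, 84, replace = TRUE),
             sample(1:20, 15, replace = TRUE))
  atlas <- data.frame(name = sprintf("R%02d", 1:99), hemisphere = "L",
                      n_grid_points = sizes)
  expect_equal(nrow(filter_regions(atlas)), 84)
})

test_that("region averaging equals the per-region mean of member traces", {
  set.seed(11)
  grid <- matrix(rnorm(10 * 500), 10)
  map <- rep(c("r1", "r2"), each = 5)
  rts <- average_region_timeseries(grid, map, sfreq = 300)
  expect_equal(rts$data["r1", ], colMeans(grid[1:5, ]), tolerance = 1e-12)
  expect_equal(rts$region_meta$n_grid_points, c(5L, 5L))
  # identical member traces pass through; opposite traces cancel
  same <- matrix(rep(grid[1, ], 3), 3, byrow = TRUE)
  expect_equal(average_region_timeseries(same, rep("r", 3), 300)$data["r", ],
               grid[1, ])
  opp <- rbind(grid[1, ], -grid[1, ])
  expect_equal(max(abs(average_region_timeseries(opp, c("r", "r"), 300)$data)),
               0)
  expect_error(average_region_timeseries(grid, map[1:5], 300),
               class = "megalpha_invalid_argument")
})
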