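test_that("notch removes the target line while sparing the passband", {
  rec <- tone_recording(c(50, 10), amps = c(1, 1), noise_sd = 0.1, dur = 30)
  out <- notch_filter(rec, 50)
  p0 <- welch_psd(rec); p1 <- welch_psd(out)
  i50 <- which(p0$freqs == 50); i10 <- which(p0$freqs == 10)
  expect_gte(10 * log10(p0$power[1, i50] / p1$power[1, i50]), 30)
  expect_lte(abs(10 * log10(p0$power[1, i10] / p1$power[1, i10])), 1)
  # empty notch list is the identity
  expect_identical(notch_filter(rec, numeric(0)), rec)
  expect_error(notch_filter(rec, 400), class = "megalpha_invalid_argument")
})

test_that("bandpass attenuates drift and high frequencies, passes interior", {
  rec <- tone_recording(c(0.2, 10), dur = 60)
  out <- bandpass_filter(rec, 1, 200)
  p0 <- welch_psd(rec); p1 <- welch_psd(out)
  idr <- which.min(abs(p0$freqs - 0.25)); i10 <- which(p0$freqs == 10)
  expect_gte(10 * log10(p0$power[1, idr] / p1$power[1, idr]), 20)
  expect_lte(abs(10 * log10(p0$power[1, i10] / p1$power[1, i10])), 1)
  # a fully band-interior signal passes essentially unchanged and with no
  # group delay; assessed away from the boundary settling zones (edge
  # transients of finite-record zero-phase filtering)
  rec2 <- tone_recording(c(8, 25, 60), amps = c(1, 0.5, 0.3), dur = 30)
  out2 <- bandpass_filter(rec2, 1, 200)
  rms <- sqrt(mean(rec2$data[1, ]^2))
  interior <- seq(3 * 600, ncol(rec2$data) - 3 * 600)
  expect_lt(max(abs(out2$data[1, interior] - rec2$data[1, interior])) / rms,
            0.01)
  expect_error(bandpass_filter(rec, 10, 5),
               class = "megalpha_invalid_argument")
  expect_error(bandpass_filter(rec, 0, 200),
               class = "megalpha_invalid_argument")
})

test_that("filters are linear operators", {
  set.seed(42)
  n <- 6000
  x <- meg_recording(matrix(rnorm(n), 1), 600)
  y <- meg_recording(matrix(rnorm(n), 1), 600)
  comb <- meg_recording(matrix(2 * x$data - 3 * y$data, 1), 600)
  for (f in list(function(r) notch_filter(r, 50),
                 function(r) bandpass_filter(r, 1, 200))) {
    lhs <- f(comb)$data
    rhs <- 2 * f(x)$data - 3 * f(y)$data
    expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-8)
  }
})

test_that("cardiac events are detected at the simulated rate", {
  spec <- subject_spec("control",
                       oscillators = list(oscillator_spec(10, amplitude = 0)),
                       artifacts = artifact_config(cardiac_rate = 60,
                                                   blink_rate = 0,
                                                   line_amp = 0),
                       seed = 21)
  rec <- simulate_subject(spec, duration = 60, n_channels = 4)
  ev <- detect_artifact_events(rec$reference$ecg, rec$sfreq, "cardiac")
  expect_true(abs(length(ev) - 60) <= 2)
  expect_lt(abs(median(diff(ev)) - 1.0), 0.05)
})

test_that("event detection handles flat references and refractoriness", {
  expect_warning(ev <- detect_artifact_events(rep(0, 6000), 600, "cardiac"))
  expect_length(ev, 0)
  # two spikes closer than the refractory period merge into one event
  x <- rnorm(6000, sd = 0.01)
  spike <- dnorm(seq(-0.05, 0.05, by = 1 / 600), sd = 0.012)
  x[3000:(3000 + length(spike) - 1)] <- x[3000:(3000 + length(spike) - 1)] + spike
  x[3090:(3090 + length(spike) - 1)] <- x[3090:(3090 + length(spike) - 1)] + 0.8 * spike
  ev2 <- detect_artifact_events(x, 600, "cardiac", refractory_s = 0.4)
  expect_length(ev2, 1)
})

test_that("SSP recovers a rank-1 artifact topography and removes it", {
  # weak background so the event-locked average is artifact-dominated
  spec <- subject_spec("control",
                       oscillators = list(oscillator_spec(10, amplitude = 0)),
                       aperiodic = aperiodic_spec(-3, 1),
                       artifacts = artifact_config(cardiac_rate = 60,
                                                   cardiac_amp = 2,
                                                   blink_rate = 0,
                                                   line_amp = 0),
                       seed = 31)
  rec <- simulate_subject(spec, duration = 60, n_channels = 8)
  true_topo <- attr(rec, "cardiac_topography")
  ev <- detect_artifact_events(rec$reference$ecg, rec$sfreq, "cardiac")
  proj <- compute_ssp(rec, ev, window = c(0.2, 0.2), n_components = 1)
  expect_gt(abs(sum(proj$basis[, 1] * true_topo)), 0.99)
  expect_equal(sum(proj$basis[, 1]^2), 1, tolerance = 1e-10)
  # event-locked average amplitude drops by >= 90 %
  locked_rms <- function(r) {
    fs <- r$sfreq; pre <- round(0.2 * fs); post <- round(0.2 * fs)
    cs <- round(ev * fs); cs <- cs[cs - pre >= 1 & cs + post <= ncol(r$data)]
    avg <- Reduce(`+`, lapply(cs, function(c0)
      r$data[, (c0 - pre):(c0 + post)])) / length(cs)
    sqrt(mean(avg^2))
  }
  cleaned <- apply_projector(rec, proj)
  expect_lt(locked_rms(cleaned), 0.1 * locked_rms(rec))
  # idempotence within 1e-10 of signal scale
  twice <- apply_projector(cleaned, proj)
  expect_lt(max(abs(twice$data - cleaned$data)),
            1e-10 * sqrt(mean(cleaned$data^2)))
  # projection never increases channel variance
  v0 <- apply(rec$data, 1, var); v1 <- apply(cleaned$data, 1, var)
  expect_true(all(v1 <= v0 + 1e-12))
})

test_that("SSP contracts: component count, epoch count, channel match", {
  rec <- tone_recording(10, dur = 30, nch = 4, noise_sd = 1)
  ev <- seq(1, 25, by = 1)
  expect_error(compute_ssp(rec, ev, n_components = 0),
               class = "megalpha_invalid_argument")
  expect_error(compute_ssp(rec, ev[1:3], n_components = 1),
               class = "megalpha_insufficient_data")
  proj <- compute_ssp(rec, ev, n_components = 1)
  rec2 <- tone_recording(10, dur = 30, nch = 3, noise_sd = 1)
  expect_error(apply_projector(rec2, proj),
               class = "megalpha_invalid_argument")
  # noise-only epochs carry no dominant spatial component
  set.seed(7)
  noise <- meg_recording(matrix(rnorm(8 * 18000), 8), 600)
  projn <- compute_ssp(noise, ev, n_components = 1)
  expect_lt(projn$explained_fraction[1], 0.5)
  # empty basis is the identity
  empty <- structure(list(basis = NULL, kind = "none"),
                     class = "ssp_projector")
  expect_identical(apply_projector(rec, empty)$data, rec$data)
})

test_that("bad-segment exclusion returns maximal good spans", {
  rec <- tone_recording(10, dur = 60, nch = 2, noise_sd = 0.1)
  # no annotations: one full segment
  segs <- drop_bad_segments(rec)
  expect_length(segs, 1)
  expect_equal(ncol(segs[[1]]$data), ncol(rec$data))
  # one bad span 10-20 s -> 10 s and 40 s good spans
  rec$annotations <- data.frame(start = 10, end = 20, kind = "muscle")
  segs2 <- drop_bad_segments(rec)
  expect_equal(vapply(segs2, duration, 0), c(10, 40))
  # a 2 s gap between bad spans is discarded (below one 4 s window)
  rec$annotations <- data.frame(start = c(10, 32), end = c(30, 60),
                                kind = "muscle")
  segs3 <- drop_bad_segments(rec)
  expect_equal(vapply(segs3, duration, 0), 10)
  expect_equal(attr(segs3, "n_discarded"), 1)
  expect_error({
    bad <- rec
    bad$annotations <- data.frame(start = 50, end = 70, kind = "muscle")
    drop_bad_segments(bad)
  }, class = "megalpha_invalid_argument")
})

test_that("preprocess chain preserves metadata and reports a log", {
  spec <- subject_spec("control", seed = 41)
  rec <- simulate_subject(spec, duration = 20, n_channels = 6)
  out <- preprocess(rec, preprocess_config(bad_channels = "CH001"))
  expect_equal(nrow(out$segments[[1]]$data), 5)
  expect_equal(out$segments[[1]]$sfreq, rec$sfreq)
  expect_equal(sum(vapply(out$segments, duration, 0)), duration(rec))
  expect_true(!is.null(out$log$cardiac_events))
})
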