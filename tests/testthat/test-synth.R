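test_that("arousal profile reproduces segment levels exactly without noise", {
  cfg <- session_config(seed = 1, rating_noise_sd = 0,
                        rating_levels = c(segment1 = 10, "break" = 2,
                                          segment2 = 40))
  r <- generate_arousal_profile(cfg)
  tt <- (seq_along(r) - 1) / cfg$fs_rating
  for (i in 1:3) {
    seg <- cfg$segments[i, ]
    expect_equal(mean(r[tt >= seg$start & tt < seg$end]),
                 cfg$rating_levels[[seg$name]])
  }
})

test_that("arousal profile orders break < segment1 < segment2 and stays in range", {
  for (seed in c(1, 7, 23)) {
    cfg <- session_config(seed = seed)
    r <- generate_arousal_profile(cfg)
    expect_true(all(r >= 0 & r <= 50))
    expect_true(is.integer(r))
    tt <- (seq_along(r) - 1) / cfg$fs_rating
    m <- vapply(1:3, function(i)
      mean(r[tt >= cfg$segments$start[i] & tt < cfg$segments$end[i]]),
      numeric(1))
    names(m) <- cfg$segments$name
    expect_lt(m[["break"]], m[["segment1"]])
    expect_lt(m[["segment1"]], m[["segment2"]])
  }
})

test_that("session generation is deterministic in the seed", {
  cfg <- session_config(seed = 5, channels = bhi_channels()[1:6])
  s1 <- generate_session(cfg, ground_truth())
  s2 <- generate_session(cfg, ground_truth())
  expect_identical(s1$eeg, s2$eeg)
  expect_identical(s1$rpeaks, s2$rpeaks)
  expect_identical(s1$rating, s2$rating)
  s3 <- generate_session(session_config(seed = 6,
                                        channels = bhi_channels()[1:6]),
                         ground_truth())
  expect_false(identical(s1$rpeaks, s3$rpeaks))
})

test_that("session invariants hold: dimensions, rating range, R-peak times", {
  cfg <- session_config(seed = 2, channels = bhi_channels()[1:5])
  ses <- generate_session(cfg, ground_truth())
  expect_equal(dim(ses$eeg), c(5, cfg$duration_s * cfg$fs_eeg))
  expect_equal(length(ses$rating), cfg$duration_s * cfg$fs_rating)
  expect_true(all(ses$rating >= 0 & ses$rating <= 50))
  expect_true(all(diff(ses$rpeaks) > 0))
  expect_true(all(ses$rpeaks >= 0 & ses$rpeaks <= cfg$duration_s))
})

test_that("unmodulated heart produces a constant IBI at the configured mean", {
  truth <- ground_truth(hrv_amp = list(LF = c(low = 0, high = 0),
                                       HF = c(low = 0, high = 0)))
  cfg <- session_config(seed = 3, channels = "Cz", ipfm_noise_sd = 0)
  ses <- generate_session(cfg, truth)
  ibi <- diff(ses$rpeaks)
  expect_true(all(abs(ibi - truth$mean_ibi_s) < 1 / cfg$fs_ecg))
  # beat-count conservation
  expect_lt(abs(length(ses$rpeaks) - cfg$duration_s / truth$mean_ibi_s), 2.5)
})

test_that("HF-only modulation concentrates IBI spectral power in 0.15-0.4 Hz", {
  truth <- ground_truth(hrv_amp = list(LF = c(low = 0, high = 0),
                                       HF = c(low = 0.1, high = 0.1)))
  cfg <- session_config(seed = 4, channels = "Cz", ipfm_noise_sd = 0)
  ses <- generate_session(cfg, truth)
  ibi <- rpeaks_to_ibi(ses$rpeaks)
  grid <- seq(5, 275, by = 0.25)
  x <- stats::spline(ibi$times, ibi$values, xout = grid, method = "natural")$y
  sp <- stats::spec.pgram(stats::ts(x, frequency = 4), plot = FALSE,
                          taper = 0, detrend = TRUE)
  peak <- sp$freq[which.max(sp$spec)]
  expect_gt(peak, 0.15)
  expect_lt(peak, 0.4)
})

test_that("injected heartbeat-evoked deflection is recovered exactly without noise", {
  truth <- ground_truth(
    hrv_amp = list(LF = c(low = 0, high = 0), HF = c(low = 0, high = 0)),
    eeg_band_amp = list(alpha = list(default = c(low = 0, high = 0))),
    hep_amplitude = c(low = 0, high = -2), hep_channels = "Fz")
  cfg <- session_config(seed = 6, channels = c("Fz", "Cz"),
                        eeg_noise_sd = 0, amp_fluct_sd = 0, ipfm_noise_sd = 0,
                        band_freqs = c(alpha = 10))
  ses <- generate_session(cfg, truth)
  tl <- label_timeline(ses$rating, cfg$segments, movement = "nomov",
                       participant = "P01")
  ep <- build_epochs(ses, timeline = tl)
  hi <- apply(ep$data[ep$label == "high", , , drop = FALSE], c(2, 3), mean)
  lo <- apply(ep$data[ep$label == "low", , , drop = FALSE], c(2, 3), mean)
  d <- hi - lo
  peak_ms <- ses$template$peak_offset_s * 1000
  peak_col <- which.min(abs(ep$times_ms - peak_ms))
  peak_val <- ses$template$values[which.max(abs(ses$template$values))]
  expect_equal(d[1, peak_col], -2 * peak_val, tolerance = 1e-6)
  expect_equal(max(abs(d[2, ])), 0)  # non-designated channel untouched
})

test_that("fixture files round-trip", {
  ses <- generate_session(session_config(seed = 8,
                                         channels = bhi_channels()[1:3]),
                          ground_truth())
  d <- withr::local_tempdir()
  write_session(ses, d)
  back <- read_session(d)
  expect_identical(back$rpeaks, ses$rpeaks)
  expect_identical(as.integer(back$rating), as.integer(ses$rating))
  for (i in 1:3)
    expect_gt(stats::cor(back$eeg[i, ], ses$eeg[i, ]), 0.999)
  expect_equal(unlist(back$truth$hep_amplitude),
               unlist(as.list(ses$truth$hep_amplitude)),
               ignore_attr = TRUE)
  expect_equal(back$truth$mean_ibi_s, ses$truth$mean_ibi_s)
  expect_equal(back$config$seed, ses$config$seed)
})

test_that("degenerate ground truth is rejected", {
  expect_error(ground_truth(mean_ibi_s = 0), "positive")
  expect_error(ground_truth(hrv_amp = list(LF = c(low = -1, high = 0),
                                           HF = c(low = 0, high = 0))))
  # IPFM positivity guard
  truth <- ground_truth(hrv_amp = list(LF = c(low = 0.6, high = 0.6),
                                       HF = c(low = 0.6, high = 0.6)))
  expect_error(generate_session(session_config(seed = 1, channels = "Cz"),
                                truth), "below 1")
})
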