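# shared fixture builders; everything is generated in code at test time

toy_segments <- function(dur = 280) {
  data.frame(name = c("segment1", "break", "segment2"),
             start = c(0, 153, 183), end = c(153, 183, dur))
}

# one EEG channel carrying a 1-Hz-sampled amplitude envelope on a carrier
carrier_channel <- function(amp_1hz, dur, fs = 250, f_carrier = 10,
                            noise_sd = 0) {
  tt <- seq(0, dur, by = 1 / fs)[-1]
  a_t <- stats::approx(seq_along(amp_1hz) - 1, amp_1hz, xout = tt,
                       rule = 2)$y
  x <- a_t * sin(2 * pi * f_carrier * tt)
  if (noise_sd > 0) x <- x + stats::rnorm(length(tt), 0, noise_sd)
  matrix(x, nrow = 1)
}

# forward-simulate a heart->brain coupled session and estimate the coupling
# back through the full band-power pipeline (one ROI channel)
hb_recovery_ratio <- function(seed, gamma_true = 0.05, rho = 0.9,
                              noise_sd = 0.15, dur = 280) {
  set.seed(seed)
  cl <- pmax(0.02, 0.1 + as.numeric(stats::filter(
    stats::rnorm(dur + 1, 0, 0.015 * sqrt(1 - 0.9^2)), 0.9, "recursive")))
  rp <- forward_simulate_heart(dur, 0.8, c_hf0 = cl,
                               noise = list(sd = 0.02, fs = 4))
  hrv <- hrv_band_power(rp, dur)
  x <- pi * 0.25 * 0.8
  sinc <- sin(x) / x
  sigma <- list(times = hrv$time_s,
                values = hrv$hf_power / sinc^2)  # calibrated driving power
  amp <- forward_simulate_eeg_amplitude(sigma, gamma = gamma_true, rho = rho,
                                        noise_sd = noise_sd, a0 = 40)
  eeg <- carrier_channel(amp$values[match(0:dur, amp$times)], dur,
                         noise_sd = 1)
  bp <- eeg_band_power(eeg, fs = 250, channels = "Pz",
                       segments = toy_segments(dur), bands = "alpha")
  grid <- run_sdg_grid(bp, hrv, mean_ibi_s = attr(hrv, "mean_ibi_s"))
  w <- grid[grid$direction == "heart_to_brain" & grid$hrv_band == "HF" &
              grid$eeg_band == "alpha", ]
  list(ratio = stats::median(w$coupling, na.rm = TRUE) / gamma_true,
       grid = grid, hrv = hrv, bp = bp)
}

# forward-simulate a brain->heart coupled session and estimate back
bh_recovery_ratio <- function(seed, gamma_true = 0.001, dur = 280) {
  set.seed(seed)
  a <- pmax(0, 10 + as.numeric(stats::filter(
    stats::rnorm(dur + 1, 0, 2.5 * sqrt(1 - 0.9^2)), 0.9, "recursive")))
  eeg <- carrier_channel(a, dur, noise_sd = 1)
  c_hf <- 0.04 + gamma_true * a^2 / 2
  rp <- forward_simulate_heart(dur, 0.8, c_hf0 = c_hf,
                               noise = list(sd = 0.02, fs = 4))
  hrv <- hrv_band_power(rp, dur)
  bp <- eeg_band_power(eeg, fs = 250, channels = "Pz",
                       segments = toy_segments(dur), bands = "alpha")
  grid <- run_sdg_grid(bp, hrv, mean_ibi_s = attr(hrv, "mean_ibi_s"))
  w <- grid[grid$direction == "brain_to_heart" & grid$hrv_band == "HF" &
              grid$eeg_band == "alpha", ]
  list(ratio = stats::median(w$coupling, na.rm = TRUE) / gamma_true,
       grid = grid)
}

# shuffle-null 95th percentile for a coupling median: circular shifts of the
# driver break the temporal alignment while preserving both marginals
coupling_shift_null <- function(driver, target, n_shift = 20, ...) {
  n <- length(driver$values)
  meds <- vapply(seq_len(n_shift), function(i) {
    k <- floor(n / (n_shift + 1)) * i
    d <- list(times = driver$times,
              values = driver$values[((seq_len(n) - 1 + k) %% n) + 1])
    f <- estimate_coupling(d, target, ...)
    stats::median(f$values, na.rm = TRUE)
  }, numeric(1))
  stats::quantile(meds, 0.95, names = FALSE)
}
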