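#' Session configuration for the synthetic generator
#'
#' Describes one recording session: a 280-s virtual-rollercoaster protocol
#' with two ride segments (153 s and 97 s) separated by a 30-s break, 30-channel
#' EEG and ECG at 250 Hz and a continuous 0-50 arousal rating dial at 50 Hz.
#' Noise and modulation knobs of the generator live here; the effect sizes
#' live in [ground_truth()].
#'
#' @param duration_s session length (s)
#' @param segments data.frame `name`, `start`, `end`; must tile
#'   `[0, duration_s]` without overlap
#' @param fs_eeg,fs_ecg,fs_rating sampling rates (Hz)
#' @param channels EEG channel labels (10-20 montage)
#' @param seed integer; fully determines the generated session
#' @param rating_levels mean dial level per segment (0-50)
#' @param rating_noise_sd,rating_tau_s sd and correlation time (s) of the
#'   smooth rating fluctuation
#' @param eeg_noise_sd per-channel white EEG noise sd (microvolt)
#' @param amp_fluct_sd,amp_fluct_rho relative sd and 1-Hz persistence of the
#'   shared band-amplitude fluctuation
#' @param ipfm_noise_sd broadband heart-rate modulation noise (dimensionless)
#' @param pink_sd sd of an optional shared 1/f background (microvolt; 0 = off)
#' @param cfa_amplitude optional R-locked cardiac-field artifact amplitude
#'   added to all channels over 0-100 ms post-peak (microvolt; 0 = off)
#' @param band_freqs carrier frequency per EEG band (Hz)
#' @return list of class `session_config`
#' @export
session_config <- function(duration_s = 280,
                           segments = data.frame(
                             name = c("segment1", "break", "segment2"),
                             start = c(0, 153, 183),
                             end = c(153, 183, 280)),
                           fs_eeg = 250, fs_ecg = 250, fs_rating = 50,
                           channels = bhi_channels(), seed = 1,
                           rating_levels = c(segment1 = 22, "break" = 6,
                                             segment2 = 34),
                           rating_noise_sd = 7, rating_tau_s = 8,
                           eeg_noise_sd = 1,
                           amp_fluct_sd = 0.1, amp_fluct_rho = 0.9,
                           ipfm_noise_sd = 0.02,
                           pink_sd = 0, cfa_amplitude = 0,
                           band_freqs = c(delta = 2, theta = 6, alpha = 10,
                                          beta = 20, gamma = 35)) {
  stopifnot(fs_eeg > 0, fs_ecg > 0, fs_rating > 0, duration_s > 0)
  seg <- segments[order(segments$start), , drop = FALSE]
  if (seg$start[1] != 0 || seg$end[nrow(seg)] != duration_s ||
      (nrow(seg) > 1 && any(seg$start[-1] != seg$end[-nrow(seg)])))
    stop("segments must tile [0, duration_s] without gaps or overlap")
  structure(list(duration_s = duration_s, segments = seg, fs_eeg = fs_eeg,
                 fs_ecg = fs_ecg, fs_rating = fs_rating, channels = channels,
                 seed = as.integer(seed), rating_levels = rating_levels,
                 rating_noise_sd = rating_noise_sd, rating_tau_s = rating_tau_s,
                 eeg_noise_sd = eeg_noise_sd, amp_fluct_sd = amp_fluct_sd,
                 amp_fluct_rho = amp_fluct_rho, ipfm_noise_sd = ipfm_noise_sd,
                 pink_sd = pink_sd, cfa_amplitude = cfa_amplitude,
                 band_freqs = band_freqs),
            class = "session_config")
}

#' Ground truth for the synthetic generator
#'
#' The injected effects, encoding the qualitative pattern the pipeline is
#' meant to recover: lower HF- (and LF-) HRV modulation depth, lower
#' parieto-occipital alpha amplitude and a more negative fronto-central
#' heartbeat-evoked deflection under high arousal, plus optional directional
#' couplings with known coefficients. Magnitudes are chosen for comfortable
#' statistical detectability, not physiological realism.
#'
#' @param mean_ibi_s mean interbeat interval (s)
#' @param hrv_amp per-band oscillator modulation depth (dimensionless) for
#'   low/high arousal
#' @param eeg_band_amp per-band amplitude (microvolt) for low/high arousal;
#'   group `default` applies to all channels, group `roi` overrides for the
#'   parieto-occipital ROI
#' @param hep_amplitude heartbeat-evoked template peak amplitude (microvolt)
#'   per arousal condition
#' @param hep_channels channels carrying the heartbeat-evoked potential
#' @param coupling list of directional couplings, each a list with `direction`
#'   (`"heart_to_brain"` or `"brain_to_heart"`), `eeg_band`, `hrv_band` and
#'   coefficient `gamma` (scalar or 1-Hz series)
#' @param rho persistence of a coupled EEG band amplitude (per second)
#' @param amp_noise_sd innovation sd of a coupled EEG band amplitude
#' @return list of class `ground_truth`
#' @export
ground_truth <- function(mean_ibi_s = 0.8,
                         hrv_amp = list(LF = c(low = 0.10, high = 0.06),
                                        HF = c(low = 0.12, high = 0.05)),
                         eeg_band_amp = list(
                           delta = list(default = c(low = 6, high = 6)),
                           theta = list(default = c(low = 5, high = 5)),
                           alpha = list(default = c(low = 4, high = 4),
                                        roi = c(low = 12, high = 7)),
                           beta = list(default = c(low = 3, high = 3)),
                           gamma = list(default = c(low = 1.5, high = 1.5))),
                         hep_amplitude = c(low = 0, high = -2),
                         hep_channels = c("Fz", "F3", "FC1", "FC5", "C3"),
                         coupling = list(),
                         rho = 0.9, amp_noise_sd = 0.15) {
  if (mean_ibi_s <= 0) stop("mean_ibi_s must be positive")
  stopifnot(all(unlist(hrv_amp) >= 0), all(unlist(eeg_band_amp) >= 0))
  structure(list(mean_ibi_s = mean_ibi_s, hrv_amp = hrv_amp,
                 eeg_band_amp = eeg_band_amp, hep_amplitude = hep_amplitude,
                 hep_channels = hep_channels, coupling = coupling,
                 rho = rho, amp_noise_sd = amp_noise_sd),
            class = "ground_truth")
}

#' Generate an emotional-arousal rating trace
#'
#' Piecewise-constant segment levels (break lowest, second rollercoaster
#' highest) plus a smooth AR(1) fluctuation, rounded to the integer dial range
#' 0-50. With `rating_noise_sd = 0` the per-segment means equal the configured
#' levels exactly.
#'
#' @param config [session_config()]
#' @return integer vector of length `duration_s * fs_rating`
#' @export
generate_arousal_profile <- function(config) {
  set.seed(config$seed)
  fs <- config$fs_rating
  n <- round(config$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  level <- numeric(n)
  for (i in seq_len(nrow(config$segments)))
    level[tt >= config$segments$start[i] & tt < config$segments$end[i]] <-
      config$rating_levels[[config$segments$name[i]]]
  if (config$rating_noise_sd > 0) {
    a <- exp(-1 / (fs * config$rating_tau_s))
    innov <- stats::rnorm(n, 0, config$rating_noise_sd * sqrt(1 - a^2))
    level <- level + as.numeric(stats::filter(innov, a, method = "recursive"))
  }
  pmin(pmax(as.integer(round(level)), 0L), 50L)
}

#' Heartbeat-evoked potential template
#'
#' Fixed smooth biphasic deflection spanning 200-450 ms after the R-peak
#' (a windowed sine cycle, 10-ms moving-average smoothed, normalized to unit
#' peak magnitude), placed so that the 250-450 ms cluster-test window covers
#' it.
#'
#' @param fs sampling rate (Hz)
#' @return list: `offsets` (sample offsets from the R-peak), `values`
#'   (unit-peak template), `peak_offset_s` (time of the extremum, s)
#' @export
hep_template <- function(fs = 250) {
  tau <- seq(0.2, 0.45, by = 1 / fs)
  u <- (tau - 0.2) / 0.25
  raw <- sin(2 * pi * u) * 0.5 * (1 - cos(2 * pi * u))
  k <- max(1, round(0.010 * fs))
  sm <- stats::filter(c(rep(0, k), raw, rep(0, k)), rep(1 / k, k),
                      sides = 2)[(k + 1):(k + length(raw))]
  sm <- as.numeric(sm) / max(abs(sm), na.rm = TRUE)
  list(offsets = round(tau * fs), values = sm,
       peak_offset_s = tau[which.max(abs(sm))])
}

# generator-internal arousal condition level per second: tertile split of the
# (uncropped) 1-Hz rating trace mapped to 0 (low) / 0.5 (medium) / 1 (high)
cond_level_1hz <- function(rating, fs_rating) {
  r1 <- ratings_to_1hz(rating, fs = fs_rating)
  lab <- tertile_labels(r1$values, times = r1$times, drop_medium = FALSE)
  list(times = r1$times, level = (as.integer(lab$label) - 1) / 2)
}

cond_interp <- function(amp2, level) amp2[["low"]] +
  (amp2[["high"]] - amp2[["low"]]) * level

#' Generate a coupled ECG/EEG/rating session
#'
#' Forward-simulates one session with known ground truth: R-peaks from the
#' integral pulse frequency modulation generator with condition-dependent
#' LF/HF oscillator amplitudes (plus any injected brain-to-heart coupling),
#' EEG as per-band amplitude-modulated carriers (adaptive Markov recursion for
#' bands with injected heart-to-brain coupling) plus white noise, and a
#' heartbeat-locked biphasic potential on designated channels scaled by the
#' arousal condition of the second containing each R-peak.
#'
#' @param config [session_config()]
#' @param truth [ground_truth()]
#' @return object of class `bhi_session`: list with `eeg` (channel x sample
#'   matrix, microvolt), `channels`, `fs_eeg`, `rpeaks` (times in s),
#'   `break_bounds`, `rating` (integer trace at `fs_rating`), `config`,
#'   `truth`, and generator internals (`cond_level`, `band_amplitude`,
#'   `template`)
#' @export
generate_session <- function(config = session_config(),
                             truth = ground_truth()) {
  stopifnot(inherits(config, "session_config"), inherits(truth, "ground_truth"))
  rating <- generate_arousal_profile(config)  # seeds the RNG
  dur <- config$duration_s
  cl <- cond_level_1hz(rating, config$fs_rating)
  secs <- cl$times

  ## EEG band amplitude series (1 Hz, shared across channels up to gain)
  bands <- names(config$band_freqs)
  roi <- intersect(bhi_roi(), config$channels)
  mean_ibi_ms <- truth$mean_ibi_s * 1000
  hb_coupling <- Filter(function(e) e$direction == "heart_to_brain",
                        truth$coupling)
  bh_coupling <- Filter(function(e) e$direction == "brain_to_heart",
                        truth$coupling)
  # deterministic heart-side band power used to drive coupled EEG bands
  det_hrv_power <- function(hrv_band) {
    cx <- cond_interp(truth$hrv_amp[[hrv_band]], cl$level)
    list(times = secs, values = (cx * mean_ibi_ms / sqrt(2))^2)
  }
  band_amp <- list()     # per band: channel x second matrix of amplitudes
  band_series <- list()  # per band: the shared 1-Hz amplitude series
  for (b in bands) {
    hbc <- Filter(function(e) e$eeg_band == b, hb_coupling)
    if (length(hbc)) {
      a <- forward_simulate_eeg_amplitude(det_hrv_power(hbc[[1]]$hrv_band),
                                          gamma = hbc[[1]]$gamma,
                                          rho = truth$rho,
                                          noise_sd = truth$amp_noise_sd,
                                          a0 = 0)$values
      amp <- matrix(rep(a, each = length(config$channels)),
                    nrow = length(config$channels))
    } else {
      spec_b <- truth$eeg_band_amp[[b]]
      base <- matrix(0, length(config$channels), length(secs))
      for (ch in seq_along(config$channels)) {
        grp <- if (!is.null(spec_b$roi) && config$channels[ch] %in% roi)
          spec_b$roi else spec_b$default
        base[ch, ] <- cond_interp(grp, cl$level)
      }
      fl <- if (config$amp_fluct_sd > 0) {
        a <- config$amp_fluct_rho
        as.numeric(stats::filter(
          stats::rnorm(length(secs), 0, config$amp_fluct_sd * sqrt(1 - a^2)),
          a, method = "recursive"))
      } else numeric(length(secs))
      amp <- base * rep(pmax(1 + fl, 0), each = nrow(base))
      a <- colMeans(amp)
    }
    band_amp[[b]] <- amp
    band_series[[b]] <- list(times = secs, values = a)
  }

  ## Heart: oscillator amplitudes + injected brain-to-heart coupling
  c_series <- list(LF = cond_interp(truth$hrv_amp$LF, cl$level),
                   HF = cond_interp(truth$hrv_amp$HF, cl$level))
  for (e in bh_coupling) {
    p_b <- band_series[[e$eeg_band]]$values^2 / 2
    g <- if (length(e$gamma) == 1) rep(e$gamma, length(secs)) else e$gamma
    c_series[[e$hrv_band]] <- c_series[[e$hrv_band]] + g * p_b
  }
  if (max(abs(c_series$LF) + abs(c_series$HF)) >= 1)
    stop("|C_LF| + |C_HF| must stay below 1 (IPFM rate positivity)")
  phases <- stats::runif(2, 0, 2 * pi)
  rpeaks <- forward_simulate_heart(
    duration_s = dur, mean_ibi_s = truth$mean_ibi_s,
    c_lf0 = c_series$LF, c_hf0 = c_series$HF,
    phase_lf = phases[1], phase_hf = phases[2],
    noise = if (config$ipfm_noise_sd > 0)
      list(sd = config$ipfm_noise_sd, fs = 4) else NULL,
    fs = config$fs_ecg)
  rpeaks <- rpeaks[rpeaks < dur]

  ## EEG assembly at fs_eeg
  fs <- config$fs_eeg
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1) / fs
  nch <- length(config$channels)
  eeg <- matrix(stats::rnorm(nch * n, 0, config$eeg_noise_sd), nch, n)
  if (config$pink_sd > 0) eeg <- eeg +
    rep(pink_noise(n, config$pink_sd), each = nch)
  for (b in bands) {
    f_b <- config$band_freqs[[b]]
    phi <- stats::runif(nch, 0, 2 * pi)
    for (ch in seq_len(nch)) {
      a_t <- stats::approx(secs, band_amp[[b]][ch, ], xout = tt, rule = 2)$y
      eeg[ch, ] <- eeg[ch, ] + a_t * sin(2 * pi * f_b * tt + phi[ch])
    }
  }

  ## heartbeat-evoked potential, scaled by the condition of the peak's second
  tmpl <- hep_template(fs)
  hep_idx <- match(intersect(truth$hep_channels, config$channels),
                   config$channels)
  lvl <- function(tr) {
    s <- pmin(pmax(floor(tr), min(secs)), max(secs))
    cl$level[match(s, secs)]
  }
  scales <- cond_interp(truth$hep_amplitude, lvl(rpeaks))
  for (i in seq_along(rpeaks)) {
    idx <- round(rpeaks[i] * fs) + tmpl$offsets + 1
    ok <- idx >= 1 & idx <= n
    if (any(ok) && length(hep_idx))
      eeg[hep_idx, idx[ok]] <- eeg[hep_idx, idx[ok]] +
        rep(scales[i] * tmpl$values[ok], each = length(hep_idx))
    if (config$cfa_amplitude > 0) {
      cfa_idx <- round(rpeaks[i] * fs) + seq(0, round(0.1 * fs)) + 1
      cfa_ok <- cfa_idx >= 1 & cfa_idx <= n
      pulse <- config$cfa_amplitude *
        sin(pi * seq(0, 1, length.out = sum(cfa_ok)))
      eeg[, cfa_idx[cfa_ok]] <- eeg[, cfa_idx[cfa_ok]] +
        rep(pulse, each = nch)
    }
  }

  brk <- config$segments[config$segments$name == "break", ]
  structure(list(eeg = eeg, channels = config$channels, fs_eeg = fs,
                 rpeaks = rpeaks,
                 break_bounds = if (nrow(brk)) c(brk$start[1], brk$end[1]),
                 rating = rating, config = config, truth = truth,
                 cond_level = cl, band_amplitude = band_series,
                 template = tmpl),
            class = "bhi_session")
}

# shared 1/f background via spectral shaping
pink_noise <- function(n, sd) {
  xf <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  x <- Re(stats::fft(xf / sqrt(f), inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

#' @export
print.bhi_session <- function(x, ...) {
  cat("Synthetic brain-heart session\n")
  cat(sprintf("  %g s, %d EEG channels @ %g Hz, %d R-peaks (mean IBI %.0f ms)\n",
              x$config$duration_s, nrow(x$eeg), x$fs_eeg, length(x$rpeaks),
              1000 * mean(diff(x$rpeaks))))
  cat(sprintf("  rating: %d samples @ %g Hz, range %d-%d\n",
              length(x$rating), x$config$fs_rating, min(x$rating),
              max(x$rating)))
  cat(sprintf("  seed %d; %d injected coupling(s)\n", x$config$seed,
              length(x$truth$coupling)))
  invisible(x)
}
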