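#' Canonical EEG frequency bands
#' @return named list of `c(lo, hi)` edges in Hz: delta 0.3-4, theta 4-8,
#'   alpha 8-13, beta 13-30, gamma 30-45
#' @export
eeg_bands <- function() list(delta = c(0.3, 4), theta = c(4, 8),
                             alpha = c(8, 13), beta = c(13, 30),
                             gamma = c(30, 45))

#' Wavelet frequency grid for a set of EEG bands
#'
#' Log-spaced points per band (about five per octave), always including the
#' exact band edges so that band integration tiles the requested range.
#'
#' @param bands character vector of band names (see [eeg_bands()])
#' @param per_octave grid density (points per octave)
#' @return ascending numeric vector of frequencies (Hz)
#' @export
eeg_freq_grid <- function(bands = names(eeg_bands()), per_octave = 5) {
  defs <- eeg_bands()[bands]
  f <- unlist(lapply(defs, function(b) {
    n <- max(2, ceiling(log2(b[2] / b[1]) * per_octave) + 1)
    exp(seq(log(b[1]), log(b[2]), length.out = n))
  }))
  sort(unique(round(f, 6)))
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-windowed sinc FIR (order ~ 3.3 / normalized low transition width),
#' applied by FFT convolution with group-delay compensation, so the output is
#' zero-phase. Intended to reproduce the standard broadband 0.3-45 Hz EEG
#' filtering step; synthetic sessions are generated in-band already.
#'
#' @param x numeric vector or channel x sample matrix
#' @param fs sampling rate (Hz)
#' @param lo,hi pass-band edges (Hz)
#' @param n_taps filter length (odd); default from the low transition width
#' @return filtered data, same shape as `x`
#' @export
bandpass_eeg <- function(x, fs, lo = 0.3, hi = 45, n_taps = NULL) {
  if (is.null(n_taps)) n_taps <- 2 * round(3.3 / (lo / fs) / 2) + 1
  b <- signal::fir1(n_taps - 1, c(lo, hi) / (fs / 2), type = "pass",
                    window = signal::hamming(n_taps))
  one <- function(v) {
    y <- signal::fftfilt(b, c(v, numeric(n_taps)))
    y[seq_along(v) + (n_taps - 1) / 2]  # symmetric FIR: delay compensation
  }
  if (is.matrix(x)) t(apply(x, 1, one)) else one(x)
}

#' 1-Hz EEG band power per electrode
#'
#' Segment-wise Morlet (7-cycle) wavelet power: each session segment
#' (rollercoaster 1, break, rollercoaster 2) is anti-symmetrically padded,
#' transformed, trimmed and re-concatenated, so that no wavelet support spans
#' a segment transition. The concatenated power is downsampled to 1 Hz (2-s
#' windows, 50% overlap) and integrated per band; `keep_pad_s` seconds of
#' padding are retained at the outer ends only.
#'
#' @param eeg channel x sample matrix (microvolt) or a `bhi_session`
#' @param fs sampling rate (Hz); taken from the session if one is given
#' @param channels channel labels; taken from the session if one is given
#' @param segments segment table (`name`, `start`, `end`); taken from the
#'   session config if one is given
#' @param bands band names to integrate
#' @param keep_pad_s padding retained at the outer ends (s); inner seams use
#'   `min(keep_pad_s, segment length / 2)`
#' @param n_cycles Morlet width
#' @param electrodes optional subset of channels to process
#' @param freqs wavelet frequency grid; default [eeg_freq_grid()] of `bands`
#' @return long data.frame (`time_s`, `electrode`, `band`, `power`) at 1 Hz
#' @export
eeg_band_power <- function(eeg, fs = NULL, channels = NULL, segments = NULL,
                           bands = names(eeg_bands()), keep_pad_s = 35,
                           n_cycles = 7, electrodes = NULL, freqs = NULL) {
  if (inherits(eeg, "bhi_session")) {
    fs <- eeg$fs_eeg
    channels <- eeg$channels
    segments <- eeg$config$segments
    eeg <- eeg$eeg
  }
  stopifnot(is.matrix(eeg), !is.null(fs), !is.null(channels),
            !is.null(segments))
  if (is.null(electrodes)) electrodes <- channels
  miss <- setdiff(electrodes, channels)
  if (length(miss)) stop("unknown electrodes: ", paste(miss, collapse = ", "))
  if (is.null(freqs)) freqs <- eeg_freq_grid(bands)
  defs <- eeg_bands()[bands]
  nseg <- nrow(segments)
  seg_len <- segments$end - segments$start
  pad <- pmin(keep_pad_s, floor(seg_len / 2))
  if (pad[1] < keep_pad_s || pad[nseg] < keep_pad_s)
    stop("outer segments must be at least twice keep_pad_s long")
  out <- vector("list", length(electrodes))
  for (ei in seq_along(electrodes)) {
    ch <- match(electrodes[ei], channels)
    pieces <- vector("list", nseg)
    for (si in seq_len(nseg)) {
      i0 <- round(segments$start[si] * fs) + 1
      i1 <- round(segments$end[si] * fs)
      np <- round(pad[si] * fs)
      p <- morlet_cwt_power(mirror_pad(eeg[ch, i0:i1], np), fs, freqs,
                            n_cycles)
      keep_l <- if (si == 1) 0 else np          # samples trimmed on the left
      keep_r <- if (si == nseg) 0 else np       # and on the right
      pieces[[si]] <- p[(keep_l + 1):(nrow(p) - keep_r), , drop = FALSE]
    }
    power <- do.call(rbind, pieces)
    ds <- downsample_power_1hz(power, fs, t0 = segments$start[1] - keep_pad_s)
    bp <- lapply(defs, function(b) band_integrate(ds$power, freqs, b[1], b[2]))
    out[[ei]] <- data.frame(
      time_s = rep(ds$times, length(bands)),
      electrode = electrodes[ei],
      band = rep(bands, each = length(ds$times)),
      power = unlist(bp, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' ROI-averaged log band power
#'
#' Arithmetic mean of band power across the ROI electrodes at every second,
#' then natural log (mean-then-log, matching averaging before transformation).
#'
#' @param band_power long data.frame from [eeg_band_power()]
#' @param roi electrode labels to average over
#' @param band band name to extract
#' @return data.frame (`time_s`, `log_power`)
#' @export
roi_log_average <- function(band_power, roi = bhi_roi(), band = "alpha") {
  bp <- band_power[band_power$band == band, , drop = FALSE]
  miss <- setdiff(roi, unique(bp$electrode))
  if (length(miss))
    stop("ROI electrodes missing from band power: ",
         paste(miss, collapse = ", "))
  bp <- bp[bp$electrode %in% roi, , drop = FALSE]
  m <- tapply(bp$power, bp$time_s, mean)
  data.frame(time_s = as.numeric(names(m)), log_power = log(as.numeric(m)))
}
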