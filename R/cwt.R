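#' Morlet continuous wavelet power
#'
#' FFT-based complex Morlet transform returning a time x frequency matrix of
#' power spectral density. The analytic wavelet has Gaussian envelope
#' sd `sigma_t = n_cycles / (2 * pi * f)`, i.e. `n_cycles` plays the role of
#' the Morlet centre frequency omega0 under the usual
#' scale ~ omega0 / (2 pi f) approximation, so `n_cycles = 6` reproduces the
#' omega0 = 6 mother wavelet and `n_cycles = 7` the 7-cycle variant.
#'
#' The transform is variance-calibrated: for a (locally) stationary signal the
#' trapezoidal integral of the returned density over frequency approximates
#' the signal variance in that band. A pure sinusoid of amplitude A therefore
#' integrates to A^2/2 across its band, which keeps HRV power in ms^2 and EEG
#' band power in microvolt^2.
#'
#' @param x numeric vector, the (already padded) signal
#' @param fs sampling rate in Hz
#' @param freqs frequencies of interest in Hz (all in (0, fs/2))
#' @param n_cycles Morlet width (cycles; equivalently omega0)
#' @return matrix `length(x)` x `length(freqs)` of power density (x-units^2/Hz)
#' @export
morlet_cwt_power <- function(x, fs, freqs, n_cycles = 6) {
  stopifnot(is.numeric(x), fs > 0, n_cycles > 0)
  if (any(freqs <= 0) || any(freqs >= fs / 2))
    stop("freqs must lie strictly inside (0, Nyquist = ", fs / 2, " Hz)")
  n <- length(x)
  # the analytic wavelet has (numerically) zero DC response, so the mean
  # carries no band power; removing it keeps the FFT zero-extension from
  # injecting a large step edge into low frequencies
  x <- x - mean(x)
  nfft <- stats::nextn(n, c(2, 3, 5))
  xf <- stats::fft(c(x, numeric(nfft - n)))
  # angular frequencies of FFT bins; negative-frequency half is zeroed so the
  # transform is analytic
  k <- 0:(nfft - 1)
  omega <- 2 * pi * ifelse(k <= nfft / 2, k, k - nfft) * fs / nfft
  pos <- omega > 0
  out <- matrix(0, n, length(freqs))
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    sigma_t <- n_cycles / (2 * pi * f)
    g <- 2 * pi^0.25 * sqrt(sigma_t)  # variance calibration (see vignette)
    H <- numeric(nfft)
    H[pos] <- g * exp(-0.5 * sigma_t^2 * (omega[pos] - 2 * pi * f)^2)
    w <- stats::fft(xf * H, inverse = TRUE) / nfft
    out[, j] <- Mod(w[seq_len(n)])^2
  }
  colnames(out) <- format(freqs)
  out
}

#' Anti-symmetric (point-mirrored) padding
#'
#' Pads a series with "inverted" reflections about each edge value:
#' pad(t) = 2 x(edge) - x(reflect(t)). This keeps the padded series and its
#' first derivative continuous at the seam, suppressing wavelet edge
#' artifacts.
#'
#' @param x numeric vector
#' @param n_pad number of samples to add at each end (`< length(x)`)
#' @return numeric vector of length `length(x) + 2 * n_pad`
#' @export
mirror_pad <- function(x, n_pad) {
  n <- length(x)
  if (n_pad < 0) stop("n_pad must be >= 0")
  if (n_pad == 0) return(x)
  if (n_pad >= n) stop("n_pad must be smaller than the series length")
  head_pad <- 2 * x[1] - x[seq(n_pad + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - n_pad)]
  c(head_pad, x, tail_pad)
}

#' Downsample a power time course to 1 Hz
#'
#' Averages within 2-s sliding windows with 50% overlap, i.e. one window
#' centred on every integer second. Only seconds whose full window lies inside
#' the sampled range are returned.
#'
#' @param power time x frequency matrix (or vector) sampled at `fs`
#' @param fs input sampling rate (Hz)
#' @param t0 time of the first sample (s)
#' @param window_s window length (s)
#' @return list with `times` (integer seconds) and `power` (matrix/vector)
#' @export
downsample_power_1hz <- function(power, fs, t0 = 0, window_s = 2) {
  if (is.vector(power)) power <- matrix(power, ncol = 1)
  n <- nrow(power)
  t_end <- t0 + (n - 1) / fs
  half <- window_s / 2
  secs <- seq(ceiling(t0 + half), floor(t_end - half))
  if (!length(secs)) stop("series too short for 2-s windows")
  out <- matrix(0, length(secs), ncol(power))
  for (i in seq_along(secs)) {
    i0 <- round((secs[i] - half - t0) * fs) + 1
    i1 <- round((secs[i] + half - t0) * fs) + 1
    i1 <- min(i1, n)
    out[i, ] <- colMeans(power[i0:i1, , drop = FALSE])
  }
  colnames(out) <- colnames(power)
  list(times = secs, power = out)
}

#' Integrate a TFR over a frequency band
#'
#' Trapezoidal integration over the grid frequencies in the closed band
#' `[lo, hi]`. A point sitting exactly on a shared band edge acts as the right
#' endpoint of the lower band and the left endpoint of the upper band, so
#' adjacent bands tile the spectrum without double-counting any power (edges
#' have zero measure) and band power is additive. Frequency grids built with
#' [hrv_freq_grid()] / [eeg_freq_grid()] contain the band edges exactly.
#'
#' @param power time x frequency matrix
#' @param freqs frequency grid (Hz), ascending
#' @param lo,hi band edges in Hz
#' @return numeric vector: integrated power per time sample (x-units^2)
#' @export
band_integrate <- function(power, freqs, lo, hi) {
  sel <- which(freqs >= lo & freqs <= hi)
  if (length(sel) < 2)
    stop("frequency grid has fewer than 2 points in band [", lo, ", ", hi, ")")
  f <- freqs[sel]
  p <- power[, sel, drop = FALSE]
  w <- diff(f)
  # trapezoid: sum_i (p_i + p_{i+1})/2 * df_i
  as.numeric(p[, -length(sel), drop = FALSE] %*% w / 2 +
             p[, -1, drop = FALSE] %*% w / 2)
}
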