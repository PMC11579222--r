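#' HRV frequency bands
#' @return named list of `c(lo, hi)` band edges in Hz
#' @export
hrv_bands <- function() list(LF = c(0.04, 0.15), HF = c(0.15, 0.40))

#' Default HRV wavelet frequency grid
#'
#' 64 log-spaced frequencies over 0.01-0.5 Hz, augmented with the exact LF/HF
#' band edges so band integration tiles 0.04-0.4 Hz.
#'
#' @return ascending numeric vector of frequencies (Hz)
#' @export
hrv_freq_grid <- function() {
  sort(unique(c(exp(seq(log(0.01), log(0.5), length.out = 64)),
                0.04, 0.15, 0.40)))
}

#' Interbeat intervals from R-peak times
#'
#' `IBI_k = (t_{k+1} - t_k) * 1000` ms, stamped at the terminating beat. When
#' break boundaries are supplied, the first R-peak after the break start and
#' the first after the break end are removed before interval formation, to
#' suppress transition artifacts at the semi-continuity.
#'
#' @param times R-peak times (s), strictly increasing, at least 3
#' @param break_bounds optional `c(start_s, end_s)` of the break
#' @return list of class `ibi_series`: `times` (s, terminating beats) and
#'   `values` (ms)
#' @export
rpeaks_to_ibi <- function(times, break_bounds = NULL) {
  if (length(times) < 3) stop("need at least 3 R-peaks")
  if (any(diff(times) <= 0)) stop("R-peak times must be strictly increasing")
  if (!is.null(break_bounds)) {
    drop <- integer(0)
    for (b in break_bounds) {
      i <- which(times > b)[1]
      if (!is.na(i)) drop <- c(drop, i)
    }
    if (length(drop)) times <- times[-unique(drop)]
  }
  structure(list(times = times[-1], values = diff(times) * 1000),
            class = "ibi_series")
}

#' Resample an IBI series to a padded uniform grid
#'
#' Cubic-spline (natural) interpolation onto a uniform grid over the session,
#' followed by anti-symmetric mirror padding of `pad_s` seconds at each end
#' (see [mirror_pad()]).
#'
#' @param ibi [rpeaks_to_ibi()] result
#' @param fs target rate (Hz)
#' @param pad_s symmetric padding (s) at each end
#' @param t_range session span `c(start_s, end_s)`; defaults to the IBI span
#' @return list of class `uniform_series`: `fs`, `t0` (time of first padded
#'   sample), `values`, `pad_s`
#' @export
ibi_to_padded_uniform <- function(ibi, fs = 4, pad_s = 70, t_range = NULL) {
  if (is.null(t_range)) t_range <- range(ibi$times)
  if (diff(t_range) < pad_s)
    stop("series span shorter than the requested padding")
  grid <- seq(t_range[1], t_range[2], by = 1 / fs)
  sf <- stats::splinefun(ibi$times, ibi$values, method = "natural")
  x <- sf(grid)
  n_pad <- round(pad_s * fs)
  structure(list(fs = fs, t0 = t_range[1] - pad_s,
                 values = mirror_pad(x, n_pad), pad_s = pad_s),
            class = "uniform_series")
}

#' Time-frequency representation of a uniform series
#'
#' Morlet wavelet power followed by downsampling to 1 Hz (2-s windows, 50%
#' overlap, centred on integer seconds).
#'
#' @param series [ibi_to_padded_uniform()] result
#' @param freqs frequency grid (Hz); must stay below the series Nyquist
#' @param n_cycles Morlet width (omega0 = 6 for the HRV analysis)
#' @return list of class `bhi_tfr`: `times` (s, 1 Hz), `freqs`, `power`
#'   (time x frequency), `pad_s`
#' @export
series_to_tfr <- function(series, freqs = hrv_freq_grid(), n_cycles = 6) {
  stopifnot(inherits(series, "uniform_series"))
  if (any(freqs >= series$fs / 2))
    stop("frequency grid exceeds the series Nyquist (", series$fs / 2, " Hz)")
  # cone-of-influence guard: keep only frequencies whose wavelet envelope
  # (sd = n_cycles / (2 pi f)) is covered by at least twice its sd of padding;
  # slower components cannot be estimated anywhere on the record
  ok <- n_cycles / (2 * pi * freqs) <= series$pad_s / 2
  if (!any(ok)) stop("no frequency fits inside the padding")
  freqs <- freqs[ok]
  p <- morlet_cwt_power(series$values, series$fs, freqs, n_cycles)
  ds <- downsample_power_1hz(p, series$fs, t0 = series$t0)
  structure(list(times = ds$times, freqs = freqs, power = ds$power,
                 pad_s = series$pad_s),
            class = "bhi_tfr")
}

#' Band power from a TFR
#'
#' Integrates the TFR over one frequency band and trims the symmetric padding
#' down to `keep_pad_s` seconds per end (the retained padding initializes the
#' coupling model downstream).
#'
#' @param tfr [series_to_tfr()] result
#' @param band `"LF"`, `"HF"`, or a numeric `c(lo, hi)` in Hz
#' @param keep_pad_s padding retained at each end (s)
#' @param session_range `c(start_s, end_s)` of the unpadded session; defaults
#'   to the TFR span minus its padding
#' @return list of class `band_power`: `times` (s, 1 Hz), `values`
#'   (signal-units^2), `band`, `pad_s`
#' @export
tfr_to_band_power <- function(tfr, band = "HF", keep_pad_s = 35,
                              session_range = NULL) {
  stopifnot(inherits(tfr, "bhi_tfr"))
  if (is.character(band)) band <- hrv_bands()[[match.arg(band, c("LF", "HF"))]]
  if (band[1] < min(tfr$freqs) || band[2] > max(tfr$freqs))
    stop("band outside the TFR frequency grid")
  if (keep_pad_s > tfr$pad_s) stop("keep_pad_s exceeds the attached padding")
  v <- band_integrate(tfr$power, tfr$freqs, band[1], band[2])
  if (is.null(session_range))
    session_range <- c(min(tfr$times) + tfr$pad_s, max(tfr$times) - tfr$pad_s)
  keep <- tfr$times >= session_range[1] - keep_pad_s &
    tfr$times <= session_range[2] + keep_pad_s
  structure(list(times = tfr$times[keep], values = v[keep], band = band,
                 pad_s = keep_pad_s),
            class = "band_power")
}

#' 1-Hz LF/HF-HRV power series from R-peaks
#'
#' Full heart-side recipe: interbeat intervals (with break-transition beats
#' removed), 4-Hz cubic-spline resampling, 70-s anti-symmetric padding, Morlet
#' (omega0 = 6) wavelet power, 1-Hz downsampling and LF/HF band integration,
#' keeping 35 s of padding to initialize the coupling model.
#'
#' @param rpeaks R-peak times (s)
#' @param duration_s session length (s)
#' @param break_bounds optional break `c(start_s, end_s)`
#' @param fs resampling rate (Hz)
#' @param pad_s padding added before the wavelet transform (s)
#' @param keep_pad_s padding retained in the output (s)
#' @param freqs wavelet frequency grid (Hz)
#' @param n_cycles Morlet width
#' @return data.frame (`time_s`, `lf_power`, `hf_power`) with attributes
#'   `mean_ibi_s` and `pad_s`
#' @export
hrv_band_power <- function(rpeaks, duration_s,
                           break_bounds = NULL, fs = 4, pad_s = 70,
                           keep_pad_s = 35, freqs = hrv_freq_grid(),
                           n_cycles = 6) {
  ibi <- rpeaks_to_ibi(rpeaks, break_bounds)
  u <- ibi_to_padded_uniform(ibi, fs = fs, pad_s = pad_s,
                             t_range = c(0, duration_s))
  tfr <- series_to_tfr(u, freqs = freqs, n_cycles = n_cycles)
  lf <- tfr_to_band_power(tfr, "LF", keep_pad_s, c(0, duration_s))
  hf <- tfr_to_band_power(tfr, "HF", keep_pad_s, c(0, duration_s))
  out <- data.frame(time_s = lf$times, lf_power = lf$values,
                    hf_power = hf$values)
  attr(out, "mean_ibi_s") <- mean(ibi$values) / 1000
  attr(out, "pad_s") <- keep_pad_s
  out
}
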