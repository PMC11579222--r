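#' SDG model configuration
#'
#' Parameters of the synthetic-data-generation coupling model: the sliding
#' estimation window, the central angular frequencies of the two cardiac
#' oscillators, and the initialization span absorbed by retained padding.
#'
#' @param window_s estimation window length in seconds
#' @param step_s window step in seconds
#' @param omega_s LF oscillator central angular frequency (rad/s)
#' @param omega_p HF oscillator central angular frequency (rad/s)
#' @param init_s seconds consumed to initialize the estimator
#' @return list of class `sdg_config`
#' @export
sdg_config <- function(window_s = 15, step_s = 1,
                       omega_s = 2 * pi * 0.1, omega_p = 2 * pi * 0.25,
                       init_s = 30) {
  stopifnot(window_s > step_s, step_s > 0, init_s >= 0)
  structure(list(window_s = window_s, step_s = step_s,
                 omega_s = omega_s, omega_p = omega_p, init_s = init_s),
            class = "sdg_config")
}

# interpolate a 1-Hz series (times, values) onto an arbitrary time grid,
# holding the edge values beyond the series range
interp_1hz <- function(times, values, t_out) {
  if (length(values) == 1) return(rep(values, length(t_out)))
  stats::approx(times, values, xout = t_out, rule = 2)$y
}

#' Forward heart simulator (integral pulse frequency modulation)
#'
#' Emits R-peaks as the integer crossings of the integrated instantaneous
#' heart rate. The rate is modulated by two sinusoidal oscillators at the LF
#' and HF central frequencies whose amplitudes
#' `C_X(t) = gamma_X(t) * eeg_power(t) + C_X0(t)` carry the brain-to-heart
#' coupling.
#'
#' @param duration_s session length (s)
#' @param mean_ibi_s mean interbeat interval (s)
#' @param c_lf0,c_hf0 baseline oscillator amplitudes; scalar or 1-Hz series
#'   (dimensionless modulation depth, `|C_LF| + |C_HF| < 1`)
#' @param gamma_lf,gamma_hf brain-to-heart coupling coefficient(s); scalar or
#'   1-Hz series
#' @param eeg_power driving EEG band-power series; list with `times`, `values`
#'   (1 Hz), or NULL when both gammas are zero
#' @param cfg [sdg_config()]
#' @param phase_lf,phase_hf oscillator phases (rad)
#' @param noise list(`sd`, `fs`) broadband rate-modulation noise: white noise
#'   of that sd generated at `fs` Hz and linearly interpolated; NULL for none
#' @param fs integration rate (Hz) for the IPFM integral
#' @param t0 start time (s); the session covers `[t0, t0 + duration_s]`
#' @return numeric vector of R-peak times (s), strictly increasing
#' @export
forward_simulate_heart <- function(duration_s, mean_ibi_s,
                                   c_lf0 = 0, c_hf0 = 0,
                                   gamma_lf = 0, gamma_hf = 0,
                                   eeg_power = NULL,
                                   cfg = sdg_config(),
                                   phase_lf = 0, phase_hf = 0,
                                   noise = NULL, fs = 250, t0 = 0) {
  if (mean_ibi_s <= 0) stop("mean_ibi_s must be positive")
  tt <- seq(t0, t0 + duration_s, by = 1 / fs)
  sec <- seq(floor(t0), ceiling(t0 + duration_s))
  as_series <- function(v) if (length(v) == 1) rep(v, length(tt)) else
    interp_1hz(sec[seq_along(v)], v, tt)
  p_b <- if (is.null(eeg_power)) numeric(length(tt)) else
    interp_1hz(eeg_power$times, eeg_power$values, tt)
  c_lf <- as_series(gamma_lf) * p_b + as_series(c_lf0)
  c_hf <- as_series(gamma_hf) * p_b + as_series(c_hf0)
  m <- c_lf * cos(cfg$omega_s * tt + phase_lf) +
       c_hf * cos(cfg$omega_p * tt + phase_hf)
  if (!is.null(noise) && noise$sd > 0) {
    tn <- seq(t0, t0 + duration_s, by = 1 / noise$fs)
    m <- m + stats::approx(tn, stats::rnorm(length(tn), 0, noise$sd),
                           xout = tt, rule = 2)$y
  }
  rate <- (1 + m) / mean_ibi_s
  if (any(rate <= 0))
    stop("instantaneous rate dropped to zero; reduce modulation amplitudes")
  # cumulative trapezoid of the rate; beats at integer crossings
  integral <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2)) / fs
  k_max <- floor(integral[length(integral)])
  if (k_max < 1) return(numeric(0))
  stats::approx(integral, tt, xout = seq_len(k_max), ties = "ordered")$y
}

#' Forward EEG band-amplitude simulator (adaptive Markov process amplitude)
#'
#' One step per second: `a(k+1) = rho * a(k) + gamma(k) * sigma_X(k) + eta(k)`
#' with `sigma_X = sqrt(HRV band power)` and Gaussian innovations, clipped at
#' zero. This is the heart-to-brain half of the coupling model.
#'
#' @param hrv_power list with `times`, `values`: driving 1-Hz HRV band power
#' @param gamma heart-to-brain coupling coefficient(s); scalar or series
#' @param rho amplitude persistence, in (0, 1)
#' @param noise_sd innovation standard deviation
#' @param a0 initial amplitude
#' @return list with `times` and `values` (amplitude series, same clock as
#'   `hrv_power`)
#' @export
forward_simulate_eeg_amplitude <- function(hrv_power, gamma, rho,
                                           noise_sd = 0, a0 = 0) {
  stopifnot(rho > 0, rho < 1)
  n <- length(hrv_power$values)
  sigma <- sqrt(pmax(hrv_power$values, 0))
  g <- if (length(gamma) == 1) rep(gamma, n) else gamma
  a <- numeric(n)
  a[1] <- a0
  eta <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  for (k in seq_len(n - 1))
    a[k + 1] <- max(0, rho * a[k] + g[k] * sigma[k] + eta[k])
  list(times = hrv_power$times, values = a)
}

#' Estimate a time-varying directional coupling coefficient
#'
#' Window-wise ordinary least squares: within every `window_s`-sample window
#' stepped by `step_s`, the target series (optionally led by one sample) is
#' regressed on an intercept, optionally the lagged target (autoregressive
#' nuisance term), and the driver. The coefficient magnitude on the driver is
#' reported as the coupling at the window's final second. Windows ending
#' before `t = 0` serve as initialization (they are absorbed by the retained
#' padding) and are dropped, so the output resumes at the session start.
#'
#' @param driver,target lists with `times` (1-Hz seconds, may start negative
#'   in the retained padding) and `values`, on a shared clock
#' @param cfg [sdg_config()]
#' @param direction label stored with the result
#' @param ar_term include the lagged target as nuisance regressor
#' @param lead regress `target(k + lead)`; 1 for the autoregressive forward
#'   model, 0 for an instantaneous map
#' @return object of class `coupling_fit` with elements `times`, `values`
#'   (coefficient magnitudes), `coef_signed`, `ar_coef`, `direction`, `cfg`
#' @export
estimate_coupling <- function(driver, target, cfg = sdg_config(),
                              direction = "heart_to_brain",
                              ar_term = TRUE, lead = 1) {
  if (length(driver$values) != length(target$values) ||
      any(driver$times != target$times))
    stop("driver and target must share the same 1-Hz clock")
  tt <- target$times
  y_all <- target$values
  x_all <- driver$values
  n <- length(y_all)
  w <- cfg$window_s
  if (n <= w + cfg$init_s)
    stop("series shorter than window_s + init_s")
  ends <- seq(w, n - lead, by = cfg$step_s)
  est <- se <- arc <- rep(NA_real_, length(ends))
  for (i in seq_along(ends)) {
    k <- (ends[i] - w + 1):ends[i]
    y <- y_all[k + lead]
    X <- if (ar_term) cbind(1, y_all[k], x_all[k]) else cbind(1, x_all[k])
    if (anyNA(y) || anyNA(X)) next
    if (stats::sd(x_all[k]) < .Machine$double.eps^0.5) next  # rank-deficient
    fit <- stats::lm.fit(X, y)
    b <- fit$coefficients
    est[i] <- b[length(b)]
    if (ar_term) arc[i] <- b[2]
  }
  keep <- tt[ends] >= 0
  structure(list(times = tt[ends][keep],
                 values = abs(est)[keep],
                 coef_signed = est[keep],
                 ar_coef = arc[keep],
                 direction = direction,
                 ar_term = ar_term, lead = lead, cfg = cfg),
            class = "coupling_fit")
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat("Time-varying coupling (", x$direction, ")\n", sep = "")
  cat(sprintf("  %d windows of %d s (step %d s), %d unresolved\n",
              length(x$values), x$cfg$window_s, x$cfg$step_s,
              sum(is.na(x$values))))
  cat(sprintf("  coupling magnitude: median %.4g [IQR %.4g, %.4g]\n",
              stats::median(x$values, na.rm = TRUE),
              stats::quantile(x$values, 0.25, na.rm = TRUE),
              stats::quantile(x$values, 0.75, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.coupling_fit <- function(object, ...) {
  stats::setNames(object$values, object$times)
}

#' @export
plot.coupling_fit <- function(x, ...) {
  plot(x$times, x$values, type = "l", xlab = "time (s)",
       ylab = "coupling magnitude", main = x$direction, ...)
  invisible(x)
}

# Gaussian smoothing of a 1-Hz series, kernel sd in samples
gauss_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  h <- ceiling(3 * sd_samples)
  k <- exp(-0.5 * ((-h):h / sd_samples)^2)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], h), x, rep(x[n], h))
  stats::filter(xp, k, sides = 2)[(h + 1):(h + n)]
}

#' Estimate the full coupling grid
#'
#' Runs the inverse model for every (direction, EEG band, HRV band, electrode)
#' combination. For heart-to-brain coupling the target is the EEG band
#' amplitude `sqrt(2 * power)` and the driver `sigma_X = sqrt(HRV power)`,
#' regressed with the autoregressive forward structure. For brain-to-heart
#' coupling the target is the cardiac modulation depth
#' `sqrt(2 * HRV power) / (1000 * mean_ibi_s)` and the driver the EEG band
#' power, pre-smoothed to the temporal resolution of the HRV wavelet and fit
#' contemporaneously (the forward map is instantaneous).
#'
#' @param eeg_power long data.frame (`time_s`, `electrode`, `band`, `power`)
#' @param hrv_power data.frame (`time_s`, `lf_power`, `hf_power`)
#' @param mean_ibi_s mean interbeat interval (s), used to convert HRV power to
#'   modulation depth
#' @param cfg [sdg_config()]
#' @param smooth_sd_s Gaussian sd (s) of the brain-to-heart driver
#'   pre-smoothing; internal calibration constant fixed by forward/inverse
#'   self-consistency (it matches the temporal smearing the 1-Hz band-power
#'   estimator imposes on the cardiac modulation envelope)
#' @return long data.frame (`time_s`, `direction`, `eeg_band`, `hrv_band`,
#'   `electrode`, `coupling`)
#' @export
run_sdg_grid <- function(eeg_power, hrv_power, mean_ibi_s,
                         cfg = sdg_config(), smooth_sd_s = 2.5) {
  electrodes <- unique(eeg_power$electrode)
  bands <- unique(eeg_power$band)
  hrv_bands <- c(LF = "lf_power", HF = "hf_power")
  hrv_fc <- c(LF = cfg$omega_s, HF = cfg$omega_p) / (2 * pi)
  out <- vector("list", 2 * length(bands) * 2 * length(electrodes))
  i <- 0
  for (el in electrodes) for (b in bands) {
    sel <- eeg_power$electrode == el & eeg_power$band == b
    p_eeg <- list(times = eeg_power$time_s[sel],
                  values = eeg_power$power[sel])
    for (hb in names(hrv_bands)) {
      common <- intersect(p_eeg$times, hrv_power$time_s)
      ei <- match(common, p_eeg$times)
      hi <- match(common, hrv_power$time_s)
      p_hrv <- hrv_power[[hrv_bands[[hb]]]][hi]
      # interval-averaging of the rate attenuates the measured modulation
      # depth by sinc(pi f_c T); undo it so depths are on the forward scale
      x <- pi * hrv_fc[[hb]] * mean_ibi_s
      sinc <- sin(x) / x
      sigma_x <- sqrt(pmax(p_hrv, 0)) / sinc
      # heart -> brain: AR(1) amplitude recursion
      fit_hb <- estimate_coupling(
        driver = list(times = common, values = sigma_x),
        target = list(times = common,
                      values = sqrt(2 * pmax(p_eeg$values[ei], 0))),
        cfg = cfg, direction = "heart_to_brain", ar_term = TRUE, lead = 1)
      # brain -> heart: instantaneous modulation-depth map
      fit_bh <- estimate_coupling(
        driver = list(times = common,
                      values = gauss_smooth(p_eeg$values[ei], smooth_sd_s)),
        target = list(times = common,
                      values = sqrt(2) * sigma_x / (1000 * mean_ibi_s)),
        cfg = cfg, direction = "brain_to_heart", ar_term = FALSE, lead = 0)
      for (f in list(fit_hb, fit_bh)) {
        i <- i + 1
        out[[i]] <- data.frame(time_s = f$times, direction = f$direction,
                               eeg_band = b, hrv_band = hb, electrode = el,
                               coupling = f$values,
                               stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out[seq_len(i)])
}
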