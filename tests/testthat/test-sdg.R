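test_that("unmodulated IPFM emits beats at exact multiples of the mean IBI", {
  rp <- forward_simulate_heart(80, 0.8)
  expect_equal(length(rp), 100)
  expect_lt(max(abs(rp - 0.8 * seq_along(rp))), 0.004)
  expect_error(forward_simulate_heart(10, 0.5, c_hf0 = 1.2), "rate")
  expect_error(forward_simulate_heart(10, -1), "positive")
})

test_that("constant HF modulation shows up at the HF central frequency", {
  rp <- forward_simulate_heart(280, 0.8, c_hf0 = 0.2)
  ibi <- rpeaks_to_ibi(rp)
  grid <- seq(5, 275, by = 0.25)
  x <- stats::spline(ibi$times, ibi$values, xout = grid,
                     method = "natural")$y
  sp <- stats::spec.pgram(stats::ts(x, frequency = 4), plot = FALSE,
                          taper = 0, detrend = TRUE)
  expect_equal(sp$freq[which.max(sp$spec)], 0.25, tolerance = 0.01)
})

test_that("the brain-to-heart gain is linear in the coupling coefficient", {
  # demodulation oracle: regress the IBI series on the 0.25-Hz quadrature pair
  depth <- vapply(c(0.0005, 0.001), function(g) {
    p_b <- list(times = 0:280, values = rep(50, 281))
    rp <- forward_simulate_heart(280, 0.8, c_hf0 = 0.02, gamma_hf = g,
                                 eeg_power = p_b)
    ibi <- rpeaks_to_ibi(rp)
    grid <- seq(2, 278, by = 0.25)
    x <- stats::spline(ibi$times, ibi$values, xout = grid,
                       method = "natural")$y
    b <- stats::lm(x ~ cos(2 * pi * 0.25 * grid) +
                     sin(2 * pi * 0.25 * grid))$coefficients
    sqrt(sum(b[2:3]^2))
  }, numeric(1))
  # C = 0.02 + g * 50: doubling g moves depth from 0.045T to 0.07T
  expect_equal(depth[2] / depth[1], (0.02 + 0.001 * 50) / (0.02 + 0.0005 * 50),
               tolerance = 0.1)
})

test_that("the adaptive Markov amplitude follows its closed forms", {
  hp <- list(times = 0:99, values = rep(4, 100))
  a <- forward_simulate_eeg_amplitude(hp, gamma = 0, rho = 0.9, a0 = 1)
  expect_equal(a$values, 0.9^(0:99))
  # fixed point a* = c / (1 - rho) with c = gamma * sigma
  a2 <- forward_simulate_eeg_amplitude(hp, gamma = 0.5, rho = 0.8, a0 = 5)
  expect_equal(a2$values[100], 0.5 * 2 / (1 - 0.8), tolerance = 1e-6)
  # stochastic runs: different paths, compatible stationary means
  hp_long <- list(times = 0:1999, values = rep(4, 2000))
  set.seed(1)
  s1 <- forward_simulate_eeg_amplitude(hp_long, 0.5, 0.8, noise_sd = 0.1,
                                       a0 = 5)
  set.seed(2)
  s2 <- forward_simulate_eeg_amplitude(hp_long, 0.5, 0.8, noise_sd = 0.1,
                                       a0 = 5)
  expect_false(identical(s1$values, s2$values))
  se <- 0.1 / sqrt(1 - 0.8^2) / sqrt(2000 / 10)  # ~10-sample correlation
  expect_lt(abs(mean(s1$values) - mean(s2$values)), 6 * se)
  expect_error(forward_simulate_eeg_amplitude(hp, 0.1, rho = 1.2), "rho")
})

test_that("window OLS recovers a linear AR + driver system exactly", {
  set.seed(7)
  n <- 300
  x <- abs(rnorm(n))
  y <- numeric(n)
  y[1] <- 1
  for (k in 1:(n - 1)) y[k + 1] <- 0.7 * y[k] + 0.5 * x[k]
  fit <- estimate_coupling(list(times = 0:(n - 1), values = x),
                           list(times = 0:(n - 1), values = y))
  expect_lt(max(abs(fit$coef_signed - 0.5), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(fit$ar_coef - 0.7), na.rm = TRUE), 1e-6)
  expect_s3_class(fit, "coupling_fit")
  expect_equal(fit$times, 14:(n - 2))
  # a constant driver is rank-deficient: windows flagged missing
  fitc <- estimate_coupling(list(times = 0:(n - 1), values = rep(2, n)),
                            list(times = 0:(n - 1), values = y))
  expect_true(all(is.na(fitc$values)))
})

test_that("independent series give couplings at the shuffle-null level", {
  set.seed(9)
  diffs <- vapply(1:40, function(s) {
    set.seed(s)
    x <- abs(rnorm(500))
    y <- abs(rnorm(500))
    f <- estimate_coupling(list(times = 0:499, values = x),
                           list(times = 0:499, values = y))
    fs <- estimate_coupling(list(times = 0:499, values = sample(x)),
                            list(times = 0:499, values = y))
    median(f$values, na.rm = TRUE) - median(fs$values, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)))
})

test_that("a step change in the coupling is tracked within one window", {
  set.seed(11)
  n <- 400
  x <- abs(rnorm(n)) + 0.5
  g <- ifelse(seq_len(n) - 1 < 200, 0.2, 0.8)
  y <- numeric(n)
  for (k in 1:(n - 1)) y[k + 1] <- 0.5 * y[k] + g[k] * x[k]
  fit <- estimate_coupling(list(times = 0:(n - 1), values = x),
                           list(times = 0:(n - 1), values = y))
  before <- fit$values[fit$times < 195]
  after <- fit$values[fit$times > 200 + 15]
  expect_lt(max(abs(before - 0.2), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(after - 0.8), na.rm = TRUE), 1e-6)
})

test_that("estimates depend only on the data inside each window", {
  set.seed(13)
  x <- abs(rnorm(300))
  y <- abs(rnorm(300)) + 0.3 * x
  f1 <- estimate_coupling(list(times = -35:264, values = x),
                          list(times = -35:264, values = y))
  # replace the warm-up prefix: estimates from 10 s on are unchanged
  x2 <- x; y2 <- y
  x2[1:20] <- rev(x2[1:20]); y2[1:20] <- abs(rnorm(20))
  f2 <- estimate_coupling(list(times = -35:264, values = x2),
                          list(times = -35:264, values = y2))
  sel <- f1$times >= 10
  expect_equal(f1$values[sel], f2$values[sel])
})

test_that("the coupling grid covers all direction x band x HRV combinations", {
  set.seed(15)
  tt <- -30:250
  bp <- expand.grid(time_s = tt, electrode = c("O1", "O2", "Pz"),
                    band = c("alpha", "theta"), stringsAsFactors = FALSE)
  bp$power <- abs(rnorm(nrow(bp))) + 1
  hrv <- data.frame(time_s = tt, lf_power = abs(rnorm(length(tt))) + 1,
                    hf_power = abs(rnorm(length(tt))) + 1)
  grid <- run_sdg_grid(bp, hrv, mean_ibi_s = 0.8)
  combos <- unique(grid[, c("direction", "eeg_band", "hrv_band",
                            "electrode")])
  expect_equal(nrow(combos), 2 * 2 * 2 * 3)
  expect_true(all(grid$coupling >= 0 | is.na(grid$coupling)))
})
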