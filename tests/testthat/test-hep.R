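make_timeline <- function(labels, participant = "P01", movement = "nomov") {
  data.frame(time_s = seq_along(labels) - 1, rating = 0,
             label = factor(labels, levels = c("low", "medium", "high")),
             excluded = labels == "medium", movement = movement,
             participant = participant, stringsAsFactors = FALSE)
}

test_that("epoching maps R-peaks to labelled seconds and baseline-corrects", {
  fs <- 250
  dur <- 60
  eeg <- matrix(7, 2, dur * fs)  # constant voltage
  labels <- rep(c("low", "high", "medium"), each = 20)
  tl <- make_timeline(labels)
  rpeaks <- seq(1.1, dur - 1.1, by = 0.8)
  ep <- build_epochs(eeg, rpeaks, tl, fs = fs, channels = c("A", "B"))
  expect_equal(dim(ep$data)[3], round(1.1 * fs) + 1)
  expect_true(all(ep$data == 0))  # constant voltage vanishes after baseline
  # count oracle: one epoch per R-peak in a low/high second, minus edge drops
  sec <- floor(rpeaks)
  usable <- labels[sec + 1] %in% c("low", "high") &
    rpeaks - 0.3 >= 0 & rpeaks + 0.8 <= dur
  expect_equal(dim(ep$data)[1], sum(usable))
  # no epoch from medium seconds
  expect_false(any(floor(rpeaks)[labels[sec + 1] == "medium"] %in%
                     floor(rpeaks)[ep$label == "medium"]))
  expect_true(all(ep$label %in% c("low", "high")))
})

test_that("baseline correction is idempotent", {
  set.seed(21)
  fs <- 250
  eeg <- matrix(rnorm(2 * 30 * fs), 2)
  tl <- make_timeline(rep("low", 30))
  ep <- build_epochs(eeg, seq(1, 28, by = 0.9), tl, fs = fs,
                     channels = c("A", "B"))
  bl <- which(ep$times_ms >= -125 & ep$times_ms <= -25)
  again <- ep$data
  for (i in seq_len(dim(again)[1]))
    again[i, , ] <- again[i, , ] -
      rowMeans(again[i, , bl, drop = FALSE], dims = 1)
  expect_equal(again, ep$data, tolerance = 1e-12)
})

test_that("condition averaging is exact and excludes incomplete participants", {
  fs <- 250
  dur <- 40
  set.seed(22)
  eeg <- matrix(rnorm(40 * dur * fs, sd = 0.01), 40)
  tl1 <- make_timeline(rep(c("low", "high"), each = dur / 2))
  ep1 <- build_epochs(eeg[1:2, ], seq(1, dur - 1, 0.8), tl1, fs = fs,
                      channels = c("A", "B"))
  tl2 <- make_timeline(rep("low", dur), participant = "P02")
  ep2 <- build_epochs(eeg[3:4, ], seq(1, dur - 1, 0.8), tl2, fs = fs,
                      channels = c("A", "B"))
  expect_warning(avg <- hep_condition_average(list(ep1, ep2)), "P02")
  expect_equal(avg$participants, "P01")
  oracle <- apply(ep1$data[ep1$label == "high", , , drop = FALSE],
                  c(2, 3), mean) -
    apply(ep1$data[ep1$label == "low", , , drop = FALSE], c(2, 3), mean)
  expect_equal(avg$diff[1, , ], oracle)
})

test_that("the difference SE scales as sigma over sqrt(n)", {
  set.seed(23)
  sds <- vapply(c(100, 400), function(n) {
    means <- replicate(80, mean(rnorm(n, sd = 2)))
    sd(means)
  }, numeric(1))
  expect_equal(sds[1] / sds[2], 2, tolerance = 0.2)
})

test_that("identical conditions produce no clusters", {
  ch <- c("Fz", "Cz", "Pz")
  adj <- channel_adjacency(ch)
  D <- array(0, c(8, 3, 5))
  r <- cluster_permutation_test(D, seq(300, 340, 10), ch, adj,
                                window_ms = c(300, 340),
                                n_permutations = 200)
  expect_equal(nrow(r$clusters), 0)
})

test_that("Monte Carlo cluster p agrees with exhaustive sign-flip enumeration", {
  set.seed(24)
  ch <- c("Fz", "Cz", "Pz")
  adj <- channel_adjacency(ch)
  tms <- seq(300, 340, by = 10)
  D <- array(rnorm(6 * 3 * 5, 0.7, 1), c(6, 3, 5))
  ex <- cluster_permutation_test(D, tms, ch, adj, window_ms = c(300, 340),
                                 exhaustive = TRUE)
  expect_equal(ex$n_permutations, 64)
  mc <- cluster_permutation_test(D, tms, ch, adj, window_ms = c(300, 340),
                                 n_permutations = 4000)
  expect_lt(abs(mc$clusters$p_mc[1] - ex$clusters$p_mc[1]), 2 / 64)
})

test_that("an injected spatio-temporal effect is found where it was put", {
  set.seed(25)
  chs <- bhi_channels()
  D <- array(rnorm(20 * 30 * 51), c(20, 30, 51))
  inj_ch <- c("F3", "Fz", "FC1")
  inj_t <- 14:29  # 302-362 ms on a 4-ms grid starting at 250
  D[, match(inj_ch, chs), inj_t] <- D[, match(inj_ch, chs), inj_t] - 1.5
  tms <- seq(250, 450, by = 4)
  r <- cluster_permutation_test(D, tms, chs, channel_adjacency(),
                                n_permutations = 1000)
  top <- r$clusters[1, ]
  expect_lt(top$p_mc, 0.05)
  expect_lt(top$sign, 0)
  got_ch <- strsplit(top$channels, ",")[[1]]
  expect_gte(length(intersect(got_ch, inj_ch)), 2)
  inj_window <- range(tms[inj_t])
  overlap <- min(top$t_end_ms, inj_window[2]) -
    max(top$t_start_ms, inj_window[1])
  expect_gte(overlap, 0.5 * diff(inj_window))
})

test_that("permutation p is invariant to channel relabeling and time shifts", {
  set.seed(26)
  ch <- c("Fz", "Cz", "Pz", "Oz")
  adj <- channel_adjacency(ch)
  tms <- seq(300, 360, by = 10)
  D <- array(rnorm(10 * 4 * 7, 0.4, 1), c(10, 4, 7))
  set.seed(1)
  r1 <- cluster_permutation_test(D, tms, ch, adj, window_ms = c(300, 360),
                                 n_permutations = 500)
  perm <- c(3, 1, 4, 2)
  set.seed(1)
  r2 <- cluster_permutation_test(D[, perm, ], tms, ch[perm],
                                 adj[perm, perm], window_ms = c(300, 360),
                                 n_permutations = 500)
  expect_equal(sort(r2$clusters$mass), sort(r1$clusters$mass))
  expect_equal(sort(r2$clusters$p_mc), sort(r1$clusters$p_mc))
  set.seed(1)
  r3 <- cluster_permutation_test(D, tms + 40, ch, adj,
                                 window_ms = c(340, 400),
                                 n_permutations = 500)
  expect_equal(sort(r3$clusters$mass), sort(r1$clusters$mass))
  expect_equal(sort(r3$clusters$p_mc), sort(r1$clusters$p_mc))
})

test_that("the ECG waveform control matches a Benjamini-Yekutieli oracle", {
  set.seed(27)
  ha <- matrix(rnorm(20 * 15), 20)
  la <- ha
  r0 <- ecg_waveform_control(ha, la)
  expect_true(all(r0$t == 0) && all(r0$p == 1))
  # single timepoint: correction is the identity
  h1 <- matrix(rnorm(20), 20)
  l1 <- matrix(rnorm(20), 20)
  r1 <- ecg_waveform_control(h1, l1)
  expect_equal(r1$p_fdr, r1$p)
  # 15 timepoints vs the direct BY step-up formula, c(m) = sum 1/i
  la2 <- la + matrix(rnorm(20 * 15, 0.2), 20)
  r2 <- ecg_waveform_control(ha, la2)
  m <- 15
  cm <- sum(1 / seq_len(m))
  o <- order(r2$p)
  adj <- cm * m * r2$p[o] / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  oracle <- numeric(m)
  oracle[o] <- pmin(1, adj)
  expect_equal(r2$p_fdr, oracle, tolerance = 1e-12)
  expect_error(ecg_waveform_control(ha[1:2, ], la[1:2, ]), "3 participants")
})
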