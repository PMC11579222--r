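#' Heartbeat-locked EEG epochs
#'
#' One epoch per R-peak falling in a low- or high-arousal labelled second
#' (the label of the second containing the peak assigns the condition;
#' excluded/medium seconds produce no epoch). Epochs span -300 to +800 ms
#' around the peak and are baseline-corrected by subtracting the per-epoch,
#' per-channel mean voltage over [-125, -25] ms. Epochs extending beyond the
#' recording are dropped.
#'
#' @param eeg channel x sample matrix or `bhi_session`
#' @param rpeaks R-peak times (s); taken from the session if one is given
#' @param timeline labelled timeline from [label_timeline()]
#' @param fs,channels sampling rate and labels; taken from the session if
#'   one is given
#' @param tmin,tmax epoch limits (s, relative to the R-peak)
#' @param baseline baseline window (s, relative to the R-peak)
#' @return object of class `epoch_set`: `data` (epoch x channel x time array,
#'   microvolt), `times_ms`, `channels`, `label`, `participant`, `movement`,
#'   `fs`
#' @export
build_epochs <- function(eeg, rpeaks = NULL, timeline, fs = NULL,
                         channels = NULL, tmin = -0.3, tmax = 0.8,
                         baseline = c(-0.125, -0.025)) {
  if (inherits(eeg, "bhi_session")) {
    if (is.null(rpeaks)) rpeaks <- eeg$rpeaks
    fs <- eeg$fs_eeg
    channels <- eeg$channels
    eeg <- eeg$eeg
  }
  stopifnot(is.matrix(eeg), !is.null(fs), !is.null(channels))
  offsets <- round(tmin * fs):round(tmax * fs)
  times_ms <- offsets / fs * 1000
  sec <- floor(rpeaks)
  row <- match(sec, timeline$time_s)
  lab <- as.character(timeline$label[row])
  usable <- !is.na(row) & !timeline$excluded[row] & lab %in% c("low", "high")
  centre <- round(rpeaks * fs) + 1
  inside <- centre + min(offsets) >= 1 & centre + max(offsets) <= ncol(eeg)
  keep <- which(usable & inside)
  if (!length(keep)) stop("no usable epochs")
  n_t <- length(offsets)
  dat <- array(0, c(length(keep), length(channels), n_t))
  bl <- which(times_ms >= baseline[1] * 1000 & times_ms <= baseline[2] * 1000)
  for (i in seq_along(keep)) {
    ep <- eeg[, centre[keep[i]] + offsets, drop = FALSE]
    dat[i, , ] <- ep - rowMeans(ep[, bl, drop = FALSE])
  }
  structure(list(data = dat, times_ms = times_ms, channels = channels,
                 label = lab[keep],
                 participant = timeline$participant[row[keep]],
                 movement = timeline$movement[row[keep]], fs = fs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Heartbeat-locked epochs: %d epochs x %d channels x %d samples\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3]))
  print(table(participant = x$participant, condition = x$label))
  invisible(x)
}

#' Per-participant condition-average HEPs
#'
#' Averages epochs per participant and arousal condition, pooling both
#' movement conditions. Participants missing either condition are flagged and
#' excluded from the contrast arrays.
#'
#' @param epochs one `epoch_set` or a list of them (e.g. one per session)
#' @return list: `high` and `low` (participant x channel x time arrays),
#'   `diff` (high - low), `participants`, `times_ms`, `channels`, `excluded`
#'   (participants missing a condition)
#' @export
hep_condition_average <- function(epochs) {
  if (inherits(epochs, "epoch_set")) epochs <- list(epochs)
  participants <- sort(unique(unlist(lapply(epochs, `[[`, "participant"))))
  times_ms <- epochs[[1]]$times_ms
  channels <- epochs[[1]]$channels
  cell_mean <- function(p, cond) {
    acc <- 0
    n <- 0
    for (e in epochs) {
      sel <- e$participant == p & e$label == cond
      if (any(sel)) {
        acc <- acc + apply(e$data[sel, , , drop = FALSE], c(2, 3), sum)
        n <- n + sum(sel)
      }
    }
    if (n == 0) NULL else acc / n
  }
  hi <- lo <- list()
  excluded <- character(0)
  for (p in participants) {
    h <- cell_mean(p, "high")
    l <- cell_mean(p, "low")
    if (is.null(h) || is.null(l)) {
      excluded <- c(excluded, p)
      next
    }
    hi[[p]] <- h
    lo[[p]] <- l
  }
  if (length(excluded))
    warning("participants missing a condition, excluded: ",
            paste(excluded, collapse = ", "))
  kept <- setdiff(participants, excluded)
  to_arr <- function(lst) {
    a <- array(0, c(length(lst), length(channels), length(times_ms)))
    for (i in seq_along(lst)) a[i, , ] <- lst[[i]]
    a
  }
  high <- to_arr(hi[kept])
  low <- to_arr(lo[kept])
  list(high = high, low = low, diff = high - low, participants = kept,
       times_ms = times_ms, channels = channels, excluded = excluded)
}

# flattened spatio-temporal neighbour list: channels vary fastest; neighbours
# are the same channel at t +/- 1 and adjacent channels at the same t
flat_neighbours <- function(adjacency, n_time) {
  n_ch <- nrow(adjacency)
  nb_ch <- lapply(seq_len(n_ch), function(c) which(adjacency[c, ]))
  nb <- vector("list", n_ch * n_time)
  for (t in seq_len(n_time)) for (c in seq_len(n_ch)) {
    i <- (t - 1) * n_ch + c
    v <- (t - 1) * n_ch + nb_ch[[c]]
    if (t > 1) v <- c(v, i - n_ch)
    if (t < n_time) v <- c(v, i + n_ch)
    nb[[i]] <- v
  }
  nb
}

# connected components of same-sign suprathreshold points; returns a list of
# integer vectors (flat indices)
sign_clusters <- function(tv, thresh, nb) {
  sup <- abs(tv) > thresh
  if (!any(sup)) return(list())
  visited <- !sup
  comps <- list()
  for (s in which(sup)) {
    if (visited[s]) next
    comp <- integer(0)
    queue <- s
    visited[s] <- TRUE
    sgn <- sign(tv[s])
    while (length(queue)) {
      i <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, i)
      for (j in nb[[i]]) {
        if (!visited[j] && sign(tv[j]) == sgn) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
    comps[[length(comps) + 1]] <- comp
  }
  comps
}

#' Spatio-temporal cluster-based permutation test on HEP contrasts
#'
#' Pointwise paired t tests over participants at every (channel, time) point
#' in the test window; suprathreshold points (two-tailed p below
#' `cluster_alpha`) are clustered by spatio-temporal adjacency with matching
#' sign; the cluster mass is the sum of t values. The null distribution of
#' the maximum absolute cluster mass is built from random per-participant sign
#' flips of the condition difference (or from all `2^n` flips when
#' `exhaustive`). Monte Carlo p uses the `+1` small-sample correction; both
#' cluster signs are tested against the same max-|mass| null (two-tailed).
#'
#' @param diffs participant x channel x time array of HA - LA means (e.g.
#'   `hep_condition_average(...)$diff`)
#' @param times_ms epoch time axis (ms)
#' @param channels channel labels
#' @param adjacency logical channel adjacency matrix ([channel_adjacency()])
#' @param window_ms test window (ms after R-peak)
#' @param cluster_alpha two-tailed alpha forming the clustering threshold
#' @param n_permutations random sign-flip draws
#' @param sig_alpha significance level reported for clusters
#' @param exhaustive enumerate all sign flips instead of sampling
#' @return object of class `hep_cluster_test`: `clusters` (data.frame with
#'   channels, time extent, mass, `p_mc`, sorted by |mass|), `observed_t`
#'   (channel x time), `times_ms`, `channels`, `null_max`, parameters
#' @export
cluster_permutation_test <- function(diffs, times_ms, channels, adjacency,
                                     window_ms = c(250, 450),
                                     cluster_alpha = 0.05,
                                     n_permutations = 10000,
                                     sig_alpha = 0.05,
                                     exhaustive = FALSE) {
  n <- dim(diffs)[1]
  if (n < 6) stop("need at least 6 participants")
  if (!isTRUE(all.equal(dimnames(adjacency)[[1]], channels)))
    adjacency <- adjacency[channels, channels]
  deg <- rowSums(adjacency)
  if (any(deg == 0))
    warning("adjacency graph has isolated channels: ",
            paste(channels[deg == 0], collapse = ", "))
  wsel <- which(times_ms >= window_ms[1] & times_ms <= window_ms[2])
  n_ch <- length(channels)
  n_t <- length(wsel)
  # participant x point matrix, channels fastest
  D <- t(apply(diffs[, , wsel, drop = FALSE], 1, function(m) as.vector(m)))
  tcrit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  nb <- flat_neighbours(adjacency, n_t)
  css <- colSums(D^2)
  t_of_signs <- function(S) {  # rows of S are sign vectors
    M <- S %*% D / n
    V <- sweep(-n * M^2, 2, css, "+") / (n - 1)
    M / sqrt(pmax(V, 0) / n)
  }
  t_obs <- as.numeric(t_of_signs(matrix(1, 1, n)))
  t_obs[!is.finite(t_obs)] <- 0  # zero-variance points carry no evidence
  comps <- sign_clusters(t_obs, tcrit, nb)
  masses <- vapply(comps, function(ix) sum(t_obs[ix]), numeric(1))
  S <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
           ncol = n)
  }
  null_max <- numeric(nrow(S))
  chunk <- 2000
  for (i0 in seq(1, nrow(S), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1, nrow(S))
    Tm <- t_of_signs(S[ii, , drop = FALSE])
    Tm[!is.finite(Tm)] <- 0
    for (r in seq_along(ii)) {
      cc <- sign_clusters(Tm[r, ], tcrit, nb)
      null_max[ii[r]] <- if (length(cc))
        max(abs(vapply(cc, function(ix) sum(Tm[r, ix]), numeric(1)))) else 0
    }
  }
  p_mc <- if (exhaustive) {
    vapply(masses, function(m) mean(null_max >= abs(m)), numeric(1))
  } else {
    vapply(masses, function(m)
      (1 + sum(null_max >= abs(m))) / (1 + length(null_max)), numeric(1))
  }
  cl_df <- if (length(comps)) {
    info <- lapply(seq_along(comps), function(i) {
      ix <- comps[[i]] - 1
      ch <- unique(channels[ix %% n_ch + 1])
      tw <- range(times_ms[wsel][ix %/% n_ch + 1])
      data.frame(cluster = i, sign = sign(masses[i]),
                 n_points = length(comps[[i]]),
                 channels = paste(ch, collapse = ","),
                 t_start_ms = tw[1], t_end_ms = tw[2],
                 mass = masses[i], p_mc = p_mc[i],
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, info)
    df[order(-abs(df$mass)), , drop = FALSE]
  } else {
    data.frame(cluster = integer(0), sign = integer(0), n_points = integer(0),
               channels = character(0), t_start_ms = numeric(0),
               t_end_ms = numeric(0), mass = numeric(0), p_mc = numeric(0))
  }
  structure(list(clusters = cl_df,
                 observed_t = matrix(t_obs, n_ch, n_t,
                                     dimnames = list(channels,
                                                     times_ms[wsel])),
                 times_ms = times_ms[wsel], channels = channels,
                 null_max = null_max, n_participants = n,
                 cluster_alpha = cluster_alpha, sig_alpha = sig_alpha,
                 window_ms = window_ms,
                 n_permutations = nrow(S), exhaustive = exhaustive),
            class = "hep_cluster_test")
}

#' @export
print.hep_cluster_test <- function(x, ...) {
  cat(sprintf(
    "Cluster-based permutation test: %d participants, %d x %d points, %s permutations\n",
    x$n_participants, length(x$channels), length(x$times_ms),
    format(x$n_permutations)))
  if (!nrow(x$clusters)) {
    cat("  no suprathreshold clusters\n")
  } else {
    sig <- x$clusters$p_mc < x$sig_alpha
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %d (%s): %s, %g-%g ms, mass %.1f, p = %.4g%s\n",
                  x$clusters$cluster[i],
                  ifelse(x$clusters$sign[i] > 0, "+", "-"),
                  x$clusters$channels[i], x$clusters$t_start_ms[i],
                  x$clusters$t_end_ms[i], x$clusters$mass[i],
                  x$clusters$p_mc[i], ifelse(sig[i], " *", "")))
  }
  invisible(x)
}

#' ECG waveform confound control
#'
#' Pointwise two-tailed paired t tests between per-participant HA and LA mean
#' ECG waveforms at every timepoint of the test window, corrected across
#' timepoints with the Benjamini-Yekutieli false discovery rate.
#'
#' @param ha,la participant x timepoint matrices of condition-mean waveforms
#' @param times_ms optional time axis (ms)
#' @return data.frame (`time_ms`, `t`, `df`, `p`, `p_fdr`, `degenerate`)
#' @export
ecg_waveform_control <- function(ha, la, times_ms = NULL) {
  stopifnot(all(dim(ha) == dim(la)))
  n <- nrow(ha)
  if (n < 3) stop("need at least 3 participants")
  d <- ha - la
  m <- colMeans(d)
  s <- apply(d, 2, stats::sd)
  degen <- s < .Machine$double.eps^0.5
  tv <- ifelse(degen, 0, m / (s / sqrt(n)))
  p <- 2 * stats::pt(-abs(tv), df = n - 1)
  p[degen] <- 1
  data.frame(time_ms = if (is.null(times_ms)) seq_len(ncol(ha)) else times_ms,
             t = tv, df = n - 1, p = p,
             p_fdr = stats::p.adjust(p, method = "BY"),
             degenerate = degen)
}
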