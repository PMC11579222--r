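#' Crop rollercoaster on/offsets from a session timeline
#'
#' Marks the samples falling within `crop_s` seconds of the beginning or end
#' of each rollercoaster segment (the break is never cropped) as excluded, to
#' avoid ride on/offset transients. For the standard 280-s session
#' (153 s + 30 s break + 97 s) with the default 2.5-s crop this retains
#' exactly 270 s.
#'
#' @param times sample times in seconds (any rate; 1-Hz integer seconds for
#'   the analysis timeline, where a sample at `t` stands for `[t, t + 1)`)
#' @param segments data.frame with columns `name`, `start`, `end`; segments
#'   named `"break"` are not cropped
#' @param crop_s seconds removed at each rollercoaster boundary
#' @return list with `keep` (logical per sample), `retained_s` (total retained
#'   duration in seconds) and `cropped` (data.frame of cropped intervals)
#' @export
crop_session <- function(times, segments, crop_s = 2.5) {
  stopifnot(is.data.frame(segments), all(c("name", "start", "end") %in%
                                           names(segments)))
  rc <- segments[segments$name != "break", , drop = FALSE]
  if (any(rc$end - rc$start < 2 * crop_s))
    stop("crop_s exceeds half a segment length")
  ivals <- do.call(rbind, lapply(seq_len(nrow(rc)), function(i)
    rbind(c(rc$start[i], rc$start[i] + crop_s),
          c(rc$end[i] - crop_s, rc$end[i]))))
  keep <- rep(TRUE, length(times))
  for (i in seq_len(nrow(ivals)))
    keep <- keep & !(times >= ivals[i, 1] & times < ivals[i, 2])
  list(keep = keep,
       retained_s = sum(segments$end - segments$start) -
         2 * crop_s * nrow(rc),
       cropped = data.frame(start = ivals[, 1], end = ivals[, 2]))
}

#' Downsample a rating trace to 1 Hz
#'
#' Means of non-overlapping blocks of `fs` samples; a trailing partial block
#' is averaged as-is.
#'
#' @param values rating samples
#' @param fs rating sampling rate (Hz)
#' @param t0 time of the first sample (s)
#' @return list with `times` (integer seconds) and `values` (block means)
#' @export
ratings_to_1hz <- function(values, fs = 50, t0 = 0) {
  if (!length(values)) stop("empty rating trace")
  block <- (seq_along(values) - 1) %/% fs
  means <- as.numeric(tapply(values, block, mean))
  list(times = t0 + seq_along(means) - 1, values = means)
}

#' Per-participant tertile split of arousal ratings
#'
#' Stable sort-and-slice binning: the `floor(n/3)` seconds with the lowest
#' ratings are labelled `low`, the `floor(n/3)` highest `high`, the remainder
#' `medium` (tie ranks resolved by time order, so integer-valued dials still
#' give exactly balanced bins: a 270-s trace yields 90 low + 90 high + 90
#' medium). Medium seconds are marked excluded when `drop_medium`.
#'
#' @param values 1-Hz rating values
#' @param times 1-Hz sample times (s)
#' @param drop_medium mark medium seconds as excluded
#' @return data.frame (`time_s`, `rating`, `label`, `excluded`) with the
#'   empirical tertile boundaries (type-7 quantiles) attached as attribute
#'   `"quantiles"` for reproducibility
#' @export
tertile_labels <- function(values, times = seq_along(values) - 1,
                           drop_medium = TRUE) {
  n <- length(values)
  if (n < 3) stop("need at least 3 samples for a tertile split")
  if (stats::sd(values) == 0)
    stop("degenerate split: all ratings identical")
  k <- n %/% 3
  ord <- order(values)  # stable: ties keep time order
  label <- rep("medium", n)
  label[ord[seq_len(k)]] <- "low"
  label[ord[seq(n - k + 1, n)]] <- "high"
  out <- data.frame(time_s = times, rating = values,
                    label = factor(label, levels = c("low", "medium", "high")),
                    excluded = drop_medium & label == "medium",
                    stringsAsFactors = FALSE)
  attr(out, "quantiles") <- stats::quantile(values, c(1, 2) / 3, type = 7)
  out
}

#' Build the labelled analysis timeline for one session
#'
#' Downsamples the rating trace to 1 Hz, excludes cropped seconds, and applies
#' the tertile split to the retained seconds only (cropped seconds are
#' labelled `excluded`).
#'
#' @param rating 50-Hz (or `fs`-Hz) rating trace
#' @param segments segment table as in [crop_session()]
#' @param fs rating sampling rate (Hz)
#' @param crop_s boundary crop in seconds
#' @param movement movement-condition label stored with the timeline
#' @param participant participant identifier
#' @return data.frame (`time_s`, `rating`, `label`, `excluded`, `movement`,
#'   `participant`)
#' @export
label_timeline <- function(rating, segments, fs = 50, crop_s = 2.5,
                           movement = "nomov", participant = "P01") {
  r1 <- ratings_to_1hz(rating, fs = fs)
  cr <- crop_session(r1$times, segments, crop_s = crop_s)
  lab <- tertile_labels(r1$values[cr$keep], times = r1$times[cr$keep])
  out <- data.frame(time_s = r1$times, rating = r1$values,
                    label = factor(NA, levels = levels(lab$label)),
                    excluded = TRUE, movement = movement,
                    participant = participant, stringsAsFactors = FALSE)
  out$label[cr$keep] <- lab$label
  out$excluded[cr$keep] <- lab$excluded
  attr(out, "quantiles") <- attr(lab, "quantiles")
  out
}
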