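#' Write a multichannel EEG matrix as a BrainVision triplet
#'
#' Minimal BrainVision writer: `.vhdr` header (INI text), `.vmrk` markers
#' (segment boundaries) and `.eeg` binary data (IEEE float32, multiplexed,
#' microvolt resolution 1). Sufficient for lossless-in-practice round trips of
#' synthetic sessions; not a general-purpose exporter.
#'
#' @param eeg channel x sample matrix (microvolt)
#' @param fs sampling rate (Hz)
#' @param channels channel labels
#' @param basename path without extension; the three files are written next
#'   to each other
#' @param markers optional data.frame (`label`, `time_s`) written as markers
#' @return invisibly, the `.vhdr` path
#' @export
write_brainvision <- function(eeg, fs, channels, basename, markers = NULL) {
  stopifnot(is.matrix(eeg), nrow(eeg) == length(channels))
  base <- basename(basename)
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  dat <- paste0(basename, ".eeg")
  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(eeg)),
    paste0("SamplingInterval=", format(1e6 / fs, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_along(channels), channels))
  writeLines(hdr, vhdr, useBytes = TRUE)
  mk <- c("BrainVision Data Exchange Marker File, Version 1.0",
          "[Common Infos]",
          paste0("DataFile=", base, ".eeg"),
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (!is.null(markers) && nrow(markers))
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(markers)) + 1, markers$label,
                        round(markers$time_s * fs) + 1))
  writeLines(mk, vmrk)
  con <- file(dat, "wb")
  on.exit(close(con))
  writeBin(as.numeric(eeg), con, size = 4, endian = "little")
  invisible(vhdr)
}

#' Read a BrainVision triplet written by [write_brainvision()]
#'
#' @param vhdr path to the `.vhdr` header
#' @return list: `eeg` (channel x sample matrix), `fs`, `channels`, `markers`
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, encoding = "UTF-8")
  get <- function(key) {
    v <- grep(paste0("^", key, "="), lines, value = TRUE)[1]
    sub(paste0("^", key, "="), "", v)
  }
  n_ch <- as.integer(get("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get("SamplingInterval"))
  if (get("BinaryFormat") != "IEEE_FLOAT_32" ||
      get("DataOrientation") != "MULTIPLEXED")
    stop("only IEEE_FLOAT_32 multiplexed data are supported")
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  channels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                     `[[`, character(1), 1)
  dat_path <- file.path(dirname(vhdr), get("DataFile"))
  sz <- file.info(dat_path)$size
  con <- file(dat_path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
  eeg <- matrix(x, nrow = n_ch)
  rownames(eeg) <- channels
  mrk_path <- file.path(dirname(vhdr), sub("\\.vhdr$", ".vmrk",
                                           basename(vhdr)))
  markers <- NULL
  if (file.exists(mrk_path)) {
    ml <- grep("^Mk[0-9]+=Stimulus", readLines(mrk_path), value = TRUE)
    if (length(ml)) {
      parts <- strsplit(sub("^Mk[0-9]+=", "", ml), ",")
      markers <- data.frame(
        label = vapply(parts, `[[`, character(1), 2),
        time_s = (vapply(parts, function(p) as.numeric(p[[3]]),
                         numeric(1)) - 1) / fs,
        stringsAsFactors = FALSE)
    }
  }
  list(eeg = eeg, fs = fs, channels = channels, markers = markers)
}

#' Write a session recording to disk
#'
#' EEG as a BrainVision triplet, R-peaks as CSV (`time_s`), ratings as CSV
#' (`time_s`, `rating`), ground truth as JSON and the session configuration
#' as YAML. A round-trip read reproduces the R-peaks and ratings exactly and
#' the EEG within float32 quantization.
#'
#' @param session `bhi_session` from [generate_session()]
#' @param out_dir output directory (created if needed)
#' @param name file stem
#' @return invisibly, a named vector of the written paths
#' @export
write_session <- function(session, out_dir, name = "session") {
  stopifnot(inherits(session, "bhi_session"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(out_dir, name)
  write_brainvision(session$eeg, session$fs_eeg, session$channels, stem,
                    markers = data.frame(label = "R-peak",
                                         time_s = session$rpeaks))
  rp <- paste0(stem, "_rpeaks.csv")
  # full-precision text so the round trip is bit-exact
  writeLines(c("time_s", sprintf("%.17g", session$rpeaks)), rp)
  rt <- paste0(stem, "_rating.csv")
  utils::write.csv(data.frame(
    time_s = (seq_along(session$rating) - 1) / session$config$fs_rating,
    rating = session$rating), rt, row.names = FALSE)
  tj <- paste0(stem, "_truth.json")
  jsonlite::write_json(unclass(session$truth), tj, auto_unbox = TRUE,
                       digits = NA, null = "null")
  cy <- paste0(stem, "_config.yaml")
  cfg <- unclass(session$config)
  cfg$segments <- as.list(cfg$segments)
  yaml::write_yaml(cfg, cy)
  invisible(c(vhdr = paste0(stem, ".vhdr"), rpeaks = rp, rating = rt,
              truth = tj, config = cy))
}

#' Read a session recording written by [write_session()]
#'
#' @param out_dir directory containing the files
#' @param name file stem used when writing
#' @return list with `eeg`, `fs_eeg`, `channels`, `rpeaks`, `rating`,
#'   `truth` (list, or NULL if absent), `config` (list)
#' @export
read_session <- function(out_dir, name = "session") {
  stem <- file.path(out_dir, name)
  bv <- read_brainvision(paste0(stem, ".vhdr"))
  rp <- utils::read.csv(paste0(stem, "_rpeaks.csv"))
  rt <- utils::read.csv(paste0(stem, "_rating.csv"))
  tj <- paste0(stem, "_truth.json")
  truth <- if (file.exists(tj)) jsonlite::read_json(tj, simplifyVector = TRUE)
  cy <- paste0(stem, "_config.yaml")
  config <- if (file.exists(cy)) yaml::read_yaml(cy)
  list(eeg = bv$eeg, fs_eeg = bv$fs, channels = bv$channels,
       rpeaks = rp$time_s, rating = rt$rating, truth = truth,
       config = config)
}
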