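#' Standard 30-channel 10-20 montage
#'
#' Schematic 2D (top view, nose up) coordinates for the 30 scalp electrodes
#' used throughout the package. Units are fractions of the head radius; the
#' ear-to-ear line is y = 0. Coordinates are only used to build the channel
#' neighbourhood graph for spatio-temporal clustering, so schematic positions
#' suffice.
#'
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
bhi_montage <- function() {
  m <- rbind(
    c("Fp1", -0.25,  0.78), c("Fp2",  0.25,  0.78),
    c("F7",  -0.65,  0.47), c("F3",  -0.33,  0.42), c("Fz", 0, 0.40),
    c("F4",   0.33,  0.42), c("F8",   0.65,  0.47),
    c("FC5", -0.57,  0.23), c("FC1", -0.20,  0.20),
    c("FC2",  0.20,  0.20), c("FC6",  0.57,  0.23),
    c("T7",  -0.80,  0.00), c("C3",  -0.40,  0.00), c("Cz", 0, 0.00),
    c("C4",   0.40,  0.00), c("T8",   0.80,  0.00),
    c("TP9", -0.95, -0.25), c("CP5", -0.57, -0.23), c("CP1", -0.20, -0.20),
    c("CP2",  0.20, -0.20), c("CP6",  0.57, -0.23), c("TP10", 0.95, -0.25),
    c("P7",  -0.65, -0.47), c("P3",  -0.33, -0.42), c("Pz", 0, -0.40),
    c("P4",   0.33, -0.42), c("P8",   0.65, -0.47),
    c("O1",  -0.25, -0.78), c("Oz",  0, -0.80), c("O2", 0.25, -0.78)
  )
  data.frame(channel = m[, 1],
             x = as.numeric(m[, 2]),
             y = as.numeric(m[, 3]),
             stringsAsFactors = FALSE)
}

#' Default montage channel labels
#' @return character vector of 30 channel names
#' @export
bhi_channels <- function() bhi_montage()$channel

#' Parieto-occipital region of interest
#'
#' Electrode subset used for the confirmatory alpha-power and alpha/HF-HRV
#' coupling analyses.
#'
#' @return character vector of ROI electrode labels
#' @export
bhi_roi <- function() c("Pz", "P3", "P4", "P7", "P8", "O1", "O2", "Oz")

#' Channel adjacency matrix
#'
#' Neighbourhood graph over scalp electrodes: two channels are neighbours when
#' their schematic 2D distance is below `threshold`. The default threshold
#' gives 4-8 neighbours per channel on the standard 30-channel montage
#' (3 for the peripheral below-ear TP9/TP10).
#'
#' @param channels channel labels (subset of [bhi_channels()])
#' @param threshold Euclidean distance threshold in head-radius units
#' @return logical channel x channel matrix (FALSE on the diagonal)
#' @export
channel_adjacency <- function(channels = bhi_channels(), threshold = 0.52) {
  mon <- bhi_montage()
  miss <- setdiff(channels, mon$channel)
  if (length(miss))
    stop("channels not in montage: ", paste(miss, collapse = ", "))
  idx <- match(channels, mon$channel)
  xy <- as.matrix(mon[idx, c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  adj <- d > 0 & d < threshold
  dimnames(adj) <- list(channels, channels)
  adj
}
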