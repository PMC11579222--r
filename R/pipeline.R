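#' Pipeline run configuration
#'
#' One configuration object for a full multi-participant analysis run:
#' simulate -> HRV -> EEG power -> binning -> HEP -> coupling -> statistics.
#' Per-session seeds are derived deterministically from the master seed and
#' the participant/movement index, so a run is reproducible bit-for-bit.
#'
#' @param n_participants number of synthetic participants
#' @param movements movement conditions simulated per participant
#' @param session [session_config()] template (its seed is overridden
#'   per session)
#' @param truth [ground_truth()] shared by all sessions
#' @param sdg [sdg_config()]
#' @param roi ROI electrodes for the confirmatory alpha analyses
#' @param eeg_bands EEG bands computed by the power stage (`"alpha"` suffices
#'   for the confirmatory analyses; all five for exploratory maps)
#' @param eeg_electrodes electrodes processed by the power stage
#' @param stages named logical vector toggling `hrv`, `eegpower`, `bin`,
#'   `hep`, `sdg`, `stats`
#' @param window_ms,cluster_alpha,n_permutations cluster-test parameters
#' @param seed master seed
#' @return list of class `run_config`
#' @export
run_config <- function(n_participants = 20,
                       movements = c("nomov", "mov"),
                       session = session_config(),
                       truth = ground_truth(),
                       sdg = sdg_config(),
                       roi = bhi_roi(),
                       eeg_bands = "alpha",
                       eeg_electrodes = bhi_roi(),
                       stages = c(hrv = TRUE, eegpower = TRUE, bin = TRUE,
                                  hep = TRUE, sdg = TRUE, stats = TRUE),
                       window_ms = c(250, 450), cluster_alpha = 0.05,
                       n_permutations = 10000, seed = 1) {
  stopifnot(n_participants >= 1)
  structure(list(n_participants = n_participants, movements = movements,
                 session = session, truth = truth, sdg = sdg, roi = roi,
                 eeg_bands = eeg_bands, eeg_electrodes = eeg_electrodes,
                 stages = stages, window_ms = window_ms,
                 cluster_alpha = cluster_alpha,
                 n_permutations = n_permutations, seed = as.integer(seed)),
            class = "run_config")
}

session_seed <- function(master, i_participant, i_movement) {
  as.integer((master + 7919L * i_participant + 104729L * i_movement) %%
               .Machine$integer.max)
}

#' Run the full analysis pipeline on synthetic participants
#'
#' Executes the enabled stages in dependency order for every participant and
#' movement condition, assembles the per-second sample table, fits the
#' condition-level mixed models (log HRV, ROI log alpha power, IBI, log
#' ROI-average couplings) and runs the HEP cluster-based permutation test
#' pooled over movement conditions. Artifacts (1-Hz series, labels, cluster
#' report, manifest) are written as TSV/JSON under `out_dir`.
#'
#' @param config [run_config()]
#' @param out_dir output directory; `NULL` skips file output
#' @return object of class `bhi_run`: `samples` (long per-second table),
#'   `lmm` (named list of [fit_arousal_lmm()] results), `hep`
#'   ([cluster_permutation_test()] result or NULL), `coupling` (long
#'   data.frame of ROI couplings), `manifest`
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  st <- config$stages
  need <- function(stage, dep) {
    if (isTRUE(st[[stage]]) && !isTRUE(st[[dep]]))
      stop("stage '", stage, "' needs stage '", dep, "' enabled")
  }
  need("stats", "bin"); need("hep", "bin"); need("sdg", "hrv")
  need("sdg", "eegpower")
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ses_cfg <- config$session
  dur <- ses_cfg$duration_s
  brk <- ses_cfg$segments[ses_cfg$segments$name == "break", ]
  break_bounds <- if (nrow(brk)) c(brk$start[1], brk$end[1])
  electrodes <- unique(c(config$eeg_electrodes,
                         intersect(config$truth$hep_channels,
                                   ses_cfg$channels)))
  samples <- list()
  epoch_sets <- list()
  couplings <- list()
  files <- character(0)
  for (i in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", i)
    for (j in seq_along(config$movements)) {
      mov <- config$movements[j]
      cfg_ij <- config$session
      cfg_ij$seed <- session_seed(config$seed, i, j)
      ses <- generate_session(cfg_ij, config$truth)
      tl <- if (isTRUE(st[["bin"]]))
        label_timeline(ses$rating, cfg_ij$segments, fs = cfg_ij$fs_rating,
                       movement = mov, participant = pid)
      metrics <- list()
      hrv <- NULL
      if (isTRUE(st[["hrv"]])) {
        hrv <- hrv_band_power(ses$rpeaks, dur, break_bounds = break_bounds)
        ibi <- rpeaks_to_ibi(ses$rpeaks, break_bounds)
        metrics$ibi <- data.frame(
          time_s = hrv$time_s,
          value = stats::approx(ibi$times, ibi$values, xout = hrv$time_s,
                                rule = 2)$y)
        metrics$lf_hrv <- data.frame(time_s = hrv$time_s,
                                     value = hrv$lf_power)
        metrics$hf_hrv <- data.frame(time_s = hrv$time_s,
                                     value = hrv$hf_power)
      }
      bp <- NULL
      if (isTRUE(st[["eegpower"]])) {
        bp <- eeg_band_power(ses, bands = config$eeg_bands,
                             electrodes = electrodes)
        if ("alpha" %in% config$eeg_bands)
          metrics$log_alpha_roi <- roi_log_average(bp, roi = config$roi)
      }
      if (isTRUE(st[["sdg"]])) {
        grid <- run_sdg_grid(bp[bp$electrode %in% config$roi, , drop = FALSE],
                             hrv, mean_ibi_s = attr(hrv, "mean_ibi_s"),
                             cfg = config$sdg)
        conf <- grid[grid$eeg_band == "alpha" & grid$hrv_band == "HF", ]
        for (dr in unique(conf$direction)) {
          w <- conf[conf$direction == dr, ]
          m <- tapply(w$coupling, w$time_s, mean)
          metrics[[paste0("coupling_", dr)]] <-
            data.frame(time_s = as.numeric(names(m)),
                       value = as.numeric(m))
        }
        grid$participant <- pid
        grid$movement <- mov
        couplings[[paste(pid, mov)]] <- grid
      }
      if (isTRUE(st[["hep"]])) {
        epoch_sets[[paste(pid, mov)]] <- build_epochs(ses, timeline = tl)
      }
      if (isTRUE(st[["bin"]]) && length(metrics)) {
        samples[[paste(pid, mov)]] <- collect_samples(tl, metrics)
      }
      if (!is.null(out_dir) && !is.null(hrv)) {
        f <- file.path(out_dir, sprintf("%s_%s_hrv.tsv", pid, mov))
        utils::write.table(hrv, f, sep = "\t", row.names = FALSE,
                           quote = FALSE)
        files <- c(files, f)
      }
    }
  }
  samples <- if (length(samples)) do.call(rbind, samples)
  coupling <- if (length(couplings)) do.call(rbind, couplings)
  lmm <- list()
  if (isTRUE(st[["stats"]]) && !is.null(samples)) {
    log_metrics <- c("lf_hrv", "hf_hrv", "coupling_heart_to_brain",
                     "coupling_brain_to_heart")
    for (m in unique(samples$metric)) {
      tab <- samples[samples$metric == m, , drop = FALSE]
      if (m %in% log_metrics) tab$value <- pmax(tab$value, 1e-300)
      lmm[[m]] <- fit_arousal_lmm(tab, log_transform = m %in% log_metrics)
    }
  }
  hep <- NULL
  if (isTRUE(st[["hep"]]) && length(epoch_sets)) {
    avg <- hep_condition_average(epoch_sets)
    set.seed(session_seed(config$seed, 0L, 0L))
    hep <- cluster_permutation_test(
      avg$diff, avg$times_ms, avg$channels,
      channel_adjacency(avg$channels),
      window_ms = config$window_ms, cluster_alpha = config$cluster_alpha,
      n_permutations = config$n_permutations)
  }
  if (!is.null(out_dir)) {
    if (!is.null(samples)) {
      f <- file.path(out_dir, "samples.tsv")
      utils::write.table(samples, f, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      files <- c(files, f)
    }
    if (!is.null(hep)) {
      f <- file.path(out_dir, "hep_clusters.json")
      jsonlite::write_json(hep$clusters, f, digits = NA)
      files <- c(files, f)
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("bhi")),
    seed = config$seed,
    n_participants = config$n_participants,
    movements = config$movements,
    stages = as.list(st),
    eeg_bands = config$eeg_bands,
    n_permutations = config$n_permutations,
    files = if (length(files))
      as.list(stats::setNames(as.character(tools::md5sum(files)),
                              basename(files))) else list())
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(samples = samples, lmm = lmm, hep = hep,
                 coupling = coupling, manifest = manifest, config = config),
            class = "bhi_run")
}

#' @export
print.bhi_run <- function(x, ...) {
  cat("Brain-heart pipeline run:", x$config$n_participants,
      "participants x", length(x$config$movements),
      "movement condition(s), seed", x$config$seed, "\n")
  for (m in names(x$lmm)) {
    an <- x$lmm[[m]]$anova
    ar <- an[an$term == "arousal", ]
    if (nrow(ar))
      cat(sprintf("  %s: arousal F(%.0f, %.1f) = %.2f, p = %.4g\n", m,
                  ar$NumDF, ar$DenDF, ar$`F value`, ar$`Pr(>F)`))
  }
  if (!is.null(x$hep)) {
    cat("  HEP cluster test:\n")
    print(x$hep)
  }
  invisible(x)
}
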