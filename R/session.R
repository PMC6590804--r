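#' Generate a synthetic EEG session
#'
#' Forward model for one recording session: band-limited 1/f background on
#' every channel, plus, after each stimulus, the additive oscillatory bursts
#' prescribed by `bursts` (amplitude selected by the hold's condition label,
#' Hann-tapered, random phase per event so the response is induced rather
#' than phase-locked), plus ledger-tracked artifacts. The recording is
#' produced already referenced to the linked mastoids.
#'
#' @param design a [build_design()] result.
#' @param bursts list of [burst_spec()] (default: the main-scenario set).
#' @param noise a [noise_model()].
#' @param artifacts an [artifact_spec()], or `NULL` for a clean session.
#' @param seed integer seed for noise, phases and artifact placement.
#' @param rate sampling rate in Hz (512).
#' @param amplitude_scale scalar multiplier applied to every burst amplitude
#'   (used for per-subject gain variation).
#' @return An `eeg_recording`: list with `samples` (time x channel matrix,
#'   uV), `rate`, `channels`, `eog_channels`, `events` (data frame
#'   `sample`, `time_s`, `position`), `reference`, `ledger` (ground-truth
#'   artifact table) and `scenario`.
#' @export
generate_session <- function(design, bursts = main_scenario_bursts(),
                             noise = noise_model(), artifacts = artifact_spec(),
                             seed = 1L, rate = 512, amplitude_scale = 1) {
  stopifnot(inherits(design, "session_design"))
  pools <- electrode_pools()
  for (b in bursts) {
    if (!b$target_pool %in% names(pools))
      stop("burst target pool not in montage: ", b$target_pool)
    if (!all(levels(design$position) %in% names(b$amplitude_by_condition)))
      stop("burst amplitude map missing conditions for band ", b$band_name)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  channels <- c(pps_channels(), pps_eog_channels())
  hold_dur <- attr(design, "hold_duration")
  n <- nrow(design) * hold_dur * rate
  # EOG channels carry an attenuated copy of the frontal background level
  gain <- stats::setNames(rep(0.5, 2), pps_eog_channels())
  gain <- c(noise$per_channel_gain, gain[setdiff(names(gain), names(noise$per_channel_gain))])
  nz <- noise
  nz$per_channel_gain <- gain
  samples <- make_noise(n, channels, rate, nz)

  ev_sample <- round(design$stimulus_s * rate) + 1L
  events <- data.frame(sample = ev_sample,
                       time_s = (ev_sample - 1L) / rate,
                       position = design$position)

  for (b in bursts) {
    chans <- pools[[b$target_pool]]
    i0 <- round(b$window[1] * rate)
    i1 <- round(b$window[2] * rate)
    k <- seq(i0, i1)
    env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = length(k))))
    tt <- k / rate
    amp <- amplitude_scale * b$amplitude_by_condition[as.character(events$position)]
    for (e in seq_len(nrow(events))) {
      if (amp[e] == 0) next
      phase <- stats::runif(1, 0, 2 * pi)
      wave <- amp[e] * env * sin(2 * pi * b$center_freq * tt + phase)
      idx <- events$sample[e] + k
      keep <- idx >= 1L & idx <= n
      samples[idx[keep], chans] <- samples[idx[keep], chans] + wave[keep]
    }
  }

  ledger <- data.frame(trial = integer(0), kind = character(0))
  if (!is.null(artifacts)) {
    ledger <- draw_artifact_ledger(nrow(events), artifacts)
    for (i in seq_len(nrow(ledger)))
      samples <- inject_artifact(samples, rate, events$sample[ledger$trial[i]],
                                 ledger$kind[i], artifacts, channels)
  }

  structure(list(samples = samples, rate = rate,
                 channels = pps_channels(), eog_channels = pps_eog_channels(),
                 events = events, reference = "linked-mastoids",
                 ledger = ledger, scenario = attr(design, "scenario")),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels (+%d EOG) x %.0f s @ %g Hz, %d events, %d ledgered artifacts\n",
              x$scenario, length(x$channels), length(x$eog_channels),
              nrow(x$samples) / x$rate, x$rate, nrow(x$events), nrow(x$ledger)))
  invisible(x)
}

#' Write / read a recording as plain text
#'
#' Interchange format: a gzip-free CSV of the sample matrix (one column per
#' channel, uV) plus a sidecar events CSV with columns
#' `sample_index`, `time_s`, `condition_label`, and a small JSON header for
#' rate/reference/scenario.
#'
#' @param rec an `eeg_recording`.
#' @param path directory to write into (created if needed).
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns the `eeg_recording` (the artifact ledger is not part of the
#'   interchange format and comes back empty).
#' @export
write_recording <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(rec$samples),
                   file.path(path, "samples.csv"), row.names = FALSE)
  ev <- data.frame(sample_index = rec$events$sample,
                   time_s = rec$events$time_s,
                   condition_label = as.character(rec$events$position))
  utils::write.csv(ev, file.path(path, "events.csv"), row.names = FALSE)
  hdr <- list(rate = rec$rate, reference = rec$reference,
              scenario = rec$scenario, channels = rec$channels,
              eog_channels = rec$eog_channels)
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE, pretty = TRUE),
             file.path(path, "header.json"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  hdr <- jsonlite::fromJSON(file.path(path, "header.json"))
  samples <- as.matrix(utils::read.csv(file.path(path, "samples.csv")))
  ev <- utils::read.csv(file.path(path, "events.csv"))
  labels <- unique(ev$condition_label)
  structure(list(samples = samples, rate = hdr$rate,
                 channels = hdr$channels, eog_channels = hdr$eog_channels,
                 events = data.frame(sample = ev$sample_index,
                                     time_s = ev$time_s,
                                     position = factor(ev$condition_label,
                                                       levels = sort(labels))),
                 reference = hdr$reference,
                 ledger = data.frame(trial = integer(0), kind = character(0)),
                 scenario = hdr$scenario),
            class = "eeg_recording")
}
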