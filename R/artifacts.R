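#' Artifact injection model
#'
#' Controls how many trials are contaminated and by what. Three kinds are
#' injected, each engineered to trip exactly one of the rejection rules:
#'
#' * `blink` — a 300 ms half-sine deflection, strongest on Fp1/Fp2 (above the
#'   +-60 uV frontopolar rule), projected at reduced gain onto the other
#'   frontal channels and strongly onto the EOG channels.
#' * `eog` — a slow 500 ms eye-movement deflection confined to the EOG
#'   channels (above the +-30 uV EOG rule, frontal projection kept small).
#' * `post_stim_amplitude` — a 100 ms broadband transient on one posterior
#'   channel inside the 0-800 ms post-stimulus window (above +-60 uV there).
#'
#' Contaminated trials are sampled without replacement and disjointly across
#' kinds; every injection is recorded in the session's ground-truth ledger.
#' Default probabilities (0.10/0.04/0.03) make roughly one in six trials
#' artifactual, in line with typical awake-EEG yields (about 125 clean trials
#' out of 150).
#'
#' @param blink_prob,eog_prob,broadband_prob per-trial contamination
#'   probabilities; must sum to < 1.
#' @param blink_amplitude,eog_amplitude,broadband_amplitude peak amplitudes (uV).
#' @return An `artifact_spec` list.
#' @export
artifact_spec <- function(blink_prob = 0.10, blink_amplitude = 120,
                          eog_prob = 0.04, eog_amplitude = 60,
                          broadband_prob = 0.03, broadband_amplitude = 100) {
  stopifnot(blink_prob >= 0, eog_prob >= 0, broadband_prob >= 0,
            blink_prob + eog_prob + broadband_prob < 1,
            blink_amplitude >= 0, eog_amplitude >= 0, broadband_amplitude >= 0)
  structure(list(blink_prob = blink_prob, blink_amplitude = blink_amplitude,
                 eog_prob = eog_prob, eog_amplitude = eog_amplitude,
                 broadband_prob = broadband_prob,
                 broadband_amplitude = broadband_amplitude),
            class = "artifact_spec")
}

# Draw contaminated trials (disjoint across kinds) for n_trials trials.
# Returns the ground-truth ledger: data.frame(trial, kind). Uses the current
# RNG stream.
draw_artifact_ledger <- function(n_trials, spec) {
  kinds <- c("blink", "eog", "post_stim_amplitude")
  probs <- c(spec$blink_prob, spec$eog_prob, spec$broadband_prob)
  avail <- seq_len(n_trials)
  trial <- integer(0)
  kind <- character(0)
  for (k in seq_along(kinds)) {
    n_k <- stats::rbinom(1, length(avail), probs[k] / (1 - sum(probs[seq_len(k - 1L)])))
    if (n_k > 0) {
      pick <- sort(sample(avail, n_k))
      trial <- c(trial, pick)
      kind <- c(kind, rep(kinds[k], n_k))
      avail <- setdiff(avail, pick)
    }
  }
  o <- order(trial)
  data.frame(trial = trial[o], kind = kind[o], stringsAsFactors = FALSE)
}

# Additive artifact waveforms, written into `samples` (time x channels)
# around the event at sample `ev`. Gains per channel group are fixed
# morphology, amplitudes come from the artifact_spec.
inject_artifact <- function(samples, rate, ev, kind, spec, channels) {
  n <- nrow(samples)
  add_wave <- function(chan, at, wave, gain) {
    idx <- at + seq_along(wave) - 1L
    keep <- idx >= 1L & idx <= n
    for (ch in chan)
      samples[idx[keep], ch] <<- samples[idx[keep], ch] + gain * wave[keep]
  }
  if (kind == "blink") {
    dur <- round(0.3 * rate)
    wave <- spec$blink_amplitude * sin(pi * seq_len(dur) / dur)
    at <- ev + round(stats::runif(1, -4, 3) * rate)     # anywhere in the epoch
    add_wave(c("Fp1", "Fp2"), at, wave, 1)
    add_wave(intersect(c("F3", "F4", "Fz", "F7", "F8"), colnames(samples)), at, wave, 0.35)
    add_wave(intersect(pps_eog_channels(), colnames(samples)), at, wave, 1.2)
  } else if (kind == "eog") {
    dur <- round(0.5 * rate)
    wave <- spec$eog_amplitude * sin(pi * seq_len(dur) / dur)
    at <- ev + round(stats::runif(1, -4, 3) * rate)
    add_wave(intersect(pps_eog_channels(), colnames(samples)), at, wave, 1)
    add_wave(c("Fp1", "Fp2"), at, wave, 0.15)           # below the blink rule
  } else if (kind == "post_stim_amplitude") {
    dur <- round(0.1 * rate)
    # tapered 25 Hz transient: in-band, so it survives the 0.3-45 Hz filter
    wave <- spec$broadband_amplitude * sin(pi * seq_len(dur) / dur) *
      sin(2 * pi * 25 * seq_len(dur) / rate + stats::runif(1, 0, 2 * pi))
    at <- ev + round(stats::runif(1, 0.1, 0.6) * rate)  # inside 0-800 ms
    ch <- sample(c("P3", "P4", "Pz", "O1", "O2", "T5", "T6"), 1)
    add_wave(ch, at, wave, 1)
  } else stop("unknown artifact kind: ", kind)
  samples
}
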