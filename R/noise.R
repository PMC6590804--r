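#' Background-EEG noise model
#'
#' The resting EEG background is modelled as a band-limited Gaussian process
#' with a 1/f^exponent power spectrum, the canonical shape of scalp EEG.
#' The process is synthesized in the frequency domain (white spectrum shaped
#' by f^(-exponent/2), zero outside `band`) and scaled to the requested rms.
#'
#' The default rms of 6 uV describes a desynchronised awake adult background;
#' it leaves the stimulus-locked bursts ample headroom under the +-60 uV
#' artifact-rejection thresholds while keeping burst-to-background power
#' ratios in the range that produces clear ERSPs.
#'
#' @param exponent spectral exponent in \[0, 2\] (1 = pink noise).
#' @param rms per-channel root-mean-square amplitude in uV (> 0).
#' @param band `c(low, high)` Hz support of the background spectrum.
#' @param per_channel_gain optional named numeric of per-channel multipliers.
#' @return A `noise_model` list.
#' @export
noise_model <- function(exponent = 1, rms = 6, band = c(0.3, 45),
                        per_channel_gain = NULL) {
  stopifnot(rms > 0, exponent >= 0, exponent <= 2, band[1] > 0,
            band[1] < band[2])
  structure(list(exponent = exponent, rms = rms, band = band,
                 per_channel_gain = per_channel_gain),
            class = "noise_model")
}

# n x n_channels matrix of independent noise traces (uses the current RNG
# stream; callers seed)
make_noise <- function(n, channels, rate, model) {
  nch <- length(channels)
  stopifnot(n %% 2 == 0)
  if (model$rms == 0) return(matrix(0, n, nch, dimnames = list(NULL, channels)))
  freqs <- seq(0, rate / 2, by = rate / n)          # rfft bin frequencies
  shape <- rep(0, length(freqs))
  inband <- freqs >= model$band[1] & freqs <= model$band[2]
  shape[inband] <- freqs[inband]^(-model$exponent / 2)
  nr <- length(freqs)
  spec <- matrix(complex(real = stats::rnorm(nr * nch),
                         imaginary = stats::rnorm(nr * nch)), nr, nch) * shape
  spec[1, ] <- 0
  out <- fft_c2r_cols(spec, as.integer(n)) / n
  out <- sweep(out, 2, apply(out, 2, stats::sd) / model$rms, "/")
  gains <- rep(1, nch)
  if (!is.null(model$per_channel_gain)) {
    hit <- match(names(model$per_channel_gain), channels)
    gains[hit[!is.na(hit)]] <- unlist(model$per_channel_gain)[!is.na(hit)]
  }
  out <- sweep(out, 2, gains, "*")
  colnames(out) <- channels
  out
}
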