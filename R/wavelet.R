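#' Complex Morlet wavelet kernel
#'
#' Gaussian-windowed complex sinusoid with a fixed number of cycles
#' (`sigma_t = cycles / (2*pi*f)`), truncated at +-3.5 sigma. The envelope is
#' normalised to sum to 2, so the squared magnitude of the convolution with a
#' real sinusoid of amplitude A is A^2 at the wavelet's centre frequency
#' (the amplitude-squared-envelope convention; the negative-frequency term is
#' negligible at >= 3 cycles).
#'
#' @param freq centre frequency (Hz).
#' @param rate sampling rate (Hz).
#' @param cycles number of cycles (>= 3).
#' @return complex vector of odd length, centred on its midpoint.
#' @export
morlet_kernel <- function(freq, rate, cycles = 7) {
  stopifnot(freq > 0, freq < rate / 2, cycles >= 3)
  sigma_t <- cycles / (2 * pi * freq)
  half <- ceiling(3.5 * sigma_t * rate)
  tt <- (-half:half) / rate
  env <- exp(-tt^2 / (2 * sigma_t^2))
  env <- 2 * env / sum(env)
  env * exp(2i * pi * freq * tt)
}

#' Time-frequency energy via Morlet wavelet convolution
#'
#' Decomposes every trial and scalp channel into spectral energy (squared
#' magnitude of the complex wavelet coefficients) on a frequency grid,
#' averaged into coarse time bins. Epochs are mirror-padded by the longest
#' wavelet half-length before convolution so the epoch edges — including the
#' pre-stimulus baseline at the leading edge — remain usable; the outer 2 s
#' of the epoch are additionally flagged as edge regions. Because the data
#' are band-limited well below 64 Hz, the series is decimated by `decim`
#' before convolution (simple subsampling is alias-free here), which bounds
#' the cost without affecting energies in the analysis bands.
#'
#' @param epochs an `eeg_epochs` (rejected trials should be dropped first,
#'   see [keep_trials()]).
#' @param freqs frequency grid in Hz (default 3.5-30 in 0.5 Hz steps).
#' @param cycles wavelet cycles (default 7).
#' @param decim integer decimation factor of the 512 Hz series (default 4,
#'   i.e. analysis at 128 Hz).
#' @param time_bin width of the output time bins in seconds (default 0.05).
#' @return A `tf_energy`: list with `energy` (trial x channel x freq x bin
#'   array, uV^2), `freqs`, `times` (bin centres, s), `edge` (logical flag
#'   per bin), `condition`, `rate`.
#' @export
wavelet_energy <- function(epochs, freqs = seq(3.5, 30, by = 0.5), cycles = 7,
                           decim = 4L, time_bin = 0.05) {
  stopifnot(inherits(epochs, "eeg_epochs"), cycles >= 3)
  rate <- epochs$rate / decim
  if (any(freqs <= 0) || any(freqs >= rate / 2))
    stop("frequencies must lie in (0, rate/2) after decimation")
  idx <- seq(1L, length(epochs$times), by = decim)
  times <- epochs$times[idx]
  chans <- epochs$channels                       # scalp only; EOG excluded
  x <- epochs$data[, chans, idx, drop = FALSE]
  ntrial <- dim(x)[1]; nch <- dim(x)[2]; ntime <- dim(x)[3]

  kernels <- lapply(freqs, morlet_kernel, rate = rate, cycles = cycles)
  maxlen <- max(lengths(kernels))
  pad <- (maxlen - 1L) %/% 2L                    # one wavelet half-length
  npad <- ntime + 2L * pad
  nfft <- stats::nextn(npad + maxlen, c(2, 3, 5))

  # kernel spectra for correlation: Conj(fft(wrapped kernel))/nfft
  K <- vapply(kernels, function(k) {
    h <- (length(k) - 1L) %/% 2L
    kw <- complex(length.out = nfft)
    kw[1:(h + 1L)] <- k[(h + 1L):length(k)]
    kw[(nfft - h + 1L):nfft] <- k[1:h]
    Conj(stats::fft(kw)) / nfft
  }, complex(nfft))

  # columns = trial-channel series, channel fastest; mirror-padded
  X <- matrix(0, npad, ntrial * nch)
  mi <- c(rev(seq_len(pad) + 1L), seq_len(ntime), ntime - seq_len(pad))
  for (i in seq_len(ntrial))
    X[, (i - 1L) * nch + seq_len(nch)] <- t(x[i, , mi])

  bins <- floor((times - times[1]) / time_bin) + 1L
  nbins <- max(bins)
  e <- wavelet_energy_fft(X, K, pad, as.integer(bins), as.integer(nbins))
  # nbins x (channel-fastest col) x freq -> trial x channel x freq x bin
  dim(e) <- c(nbins, nch, ntrial, length(freqs))
  e <- aperm(e, c(3, 2, 4, 1))
  dimnames(e) <- list(NULL, chans, NULL, NULL)

  centers <- times[1] + (seq_len(nbins) - 0.5) * time_bin
  structure(list(energy = e, freqs = freqs,
                 times = centers,
                 edge = centers < min(epochs$times) + 2 | centers > max(epochs$times) - 2,
                 condition = epochs$condition, rate = epochs$rate),
            class = "tf_energy")
}

#' @export
print.tf_energy <- function(x, ...) {
  d <- dim(x$energy)
  cat(sprintf("<tf_energy> %d trials x %d channels x %d freqs (%.1f-%.1f Hz) x %d time bins\n",
              d[1], d[2], d[3], min(x$freqs), max(x$freqs), d[4]))
  invisible(x)
}
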