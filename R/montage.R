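#' Scalp montage and electrode pools
#'
#' The simulated cap is the standard 21-electrode 10-20 layout used by most
#' clinical EEG systems, plus two periocular EOG channels used only for
#' artifact screening. Analyses never operate on single electrodes: energy is
#' averaged over four anatomically defined pools before any statistics.
#'
#' @return `pps_channels()`: character vector of the 21 scalp channel labels.
#' @export
pps_channels <- function() {
  c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "Oz", "O2")
}

#' @rdname pps_channels
#' @return `pps_eog_channels()`: the two EOG channel labels.
#' @export
pps_eog_channels <- function() c("EOG1", "EOG2")

#' @rdname pps_channels
#' @return `electrode_pools()`: named list of channel pools (frontal,
#'   centroparietal, temporal, occipital).
#' @export
electrode_pools <- function() {
  list(
    frontal        = c("Fp1", "F3", "F7", "Fz", "Fp2", "F4", "F8"),
    centroparietal = c("C3", "P3", "Cz", "C4", "P4", "Pz"),
    temporal       = c("T3", "T5", "T4", "T6"),
    occipital      = c("O1", "O2")
  )
}

#' Canonical frequency bands
#'
#' Theta 3.5-8 Hz, alpha 8-12 Hz, beta 12-30 Hz. Frequency bins that fall on a
#' shared edge (8, 12 Hz) are assigned to the lower band so the partition is
#' disjoint.
#'
#' @return Named list of `c(low, high)` band limits in Hz.
#' @export
band_set <- function() {
  list(theta = c(3.5, 8), alpha = c(8, 12), beta = c(12, 30))
}

#' Assign frequency bins to bands
#'
#' @param freqs numeric vector of frequencies (Hz).
#' @param bands band list as from [band_set()].
#' @return factor of band names (NA for bins outside all bands), levels in
#'   band order.
#' @export
band_of <- function(freqs, bands = band_set()) {
  nm <- names(bands)
  out <- rep(NA_character_, length(freqs))
  # shared edges belong to the lower band: assign from lowest band upward,
  # using half-open (low, high] except the first band which includes its floor
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    sel <- if (i == 1L) freqs >= b[1] & freqs <= b[2] else freqs > b[1] & freqs <= b[2]
    out[sel & is.na(out)] <- nm[i]
  }
  factor(out, levels = nm)
}
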