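#' Specify an event-locked oscillatory burst
#'
#' A burst is an additive, Hann-tapered sinusoid injected on every channel of
#' one electrode pool in a fixed post-stimulus window, with an amplitude that
#' may depend on the condition label. Bursts carry a random phase per event,
#' so they perturb spectral power without being phase-locked — the signature
#' an ERSP analysis is designed to pick up.
#'
#' @param band_name band label (informational, e.g. "theta").
#' @param center_freq oscillation frequency in Hz.
#' @param window `c(start, end)` seconds post-stimulus; must lie in \[0, 6\].
#' @param target_pool electrode pool name (see [electrode_pools()]).
#' @param amplitude_by_condition named numeric, peak amplitude in uV per
#'   condition label; all non-negative.
#' @param taper envelope shape; only `"hann"` is implemented.
#' @return A `burst_spec` list.
#' @export
burst_spec <- function(band_name, center_freq, window, target_pool,
                       amplitude_by_condition, taper = "hann") {
  stopifnot(length(window) == 2, window[1] >= 0, window[2] <= 6,
            window[1] < window[2], center_freq > 0,
            all(amplitude_by_condition >= 0),
            !is.null(names(amplitude_by_condition)))
  taper <- match.arg(taper, "hann")
  structure(list(band_name = band_name, center_freq = center_freq,
                 window = window, target_pool = target_pool,
                 amplitude_by_condition = amplitude_by_condition,
                 taper = taper),
            class = "burst_spec")
}

#' Default burst sets for the two scenarios
#'
#' The main scenario carries the study's effect structure: a frontal theta
#' burst at 100-700 ms and a frontal beta burst at 700-1500 ms, both growing
#' with hand-to-face proximity (p2 > p1 > p0), and a centroparietal alpha
#' response at 100-2800 ms whose amplitude is independent of position. The
#' control scenario retains only the alpha response, identical across the
#' three arm angles, so no position-dependent spectral effect exists there.
#'
#' Default amplitudes (in uV, against the 6 uV rms background) are
#' calibrated so that the group-level statistics of a simulated cohort have
#' the order of magnitude the study design is built around: post-stimulus
#' energy changes of one to a few log units inside the burst window,
#' strongly position-ordered for theta/beta, while staying comfortably
#' below the +-60 uV artifact-rejection thresholds even for high-gain
#' subjects. The brief theta/beta bursts need larger peak amplitudes than
#' the long alpha response because their energy is diluted over the 6 s
#' post-stimulus analysis window (and, for beta, over the wide 12-30 Hz
#' band).
#'
#' @param theta_amp,beta_amp,alpha_amp named amplitude maps (uV).
#' @return list of [burst_spec()] objects.
#' @export
main_scenario_bursts <- function(theta_amp = c(p0 = 2.5, p1 = 6, p2 = 10),
                                 beta_amp = c(p0 = 2, p1 = 10, p2 = 18),
                                 alpha_amp = c(p0 = 3, p1 = 3, p2 = 3)) {
  list(
    burst_spec("theta", 5.5, c(0.1, 0.7), "frontal", theta_amp),
    burst_spec("beta", 20, c(0.7, 1.5), "frontal", beta_amp),
    burst_spec("alpha", 10, c(0.1, 2.8), "centroparietal", alpha_amp)
  )
}

#' @rdname main_scenario_bursts
#' @export
control_scenario_bursts <- function(alpha_amp = c(a0 = 3, a45 = 3, a90 = 3)) {
  list(burst_spec("alpha", 10, c(0.1, 2.8), "centroparietal", alpha_amp))
}

#' @export
print.burst_spec <- function(x, ...) {
  cat(sprintf("<burst_spec> %s %.1f Hz on %s, window [%.2f, %.2f]s, amp {%s}\n",
              x$band_name, x$center_freq, x$target_pool,
              x$window[1], x$window[2],
              paste(names(x$amplitude_by_condition),
                    x$amplitude_by_condition, sep = "=", collapse = ", ")))
  invisible(x)
}
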