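# shared fixture builders and independent oracles

test_rate <- 512

# minimal eeg_recording wrapper around a bare signal matrix
make_recording <- function(samples, rate = test_rate,
                           events = data.frame(sample = integer(0),
                                               time_s = numeric(0),
                                               position = factor(character(0))),
                           eog = character(0)) {
  structure(list(samples = samples, rate = rate,
                 channels = setdiff(colnames(samples), eog),
                 eog_channels = eog, events = events,
                 reference = "linked-mastoids",
                 ledger = data.frame(trial = integer(0), kind = character(0)),
                 scenario = "main"),
            class = "eeg_recording")
}

# single/multi-trial eeg_epochs on the standard [-6, 6) s window.
# signals: list of channel-named matrices (time x channel), one per trial
make_epochs <- function(signals, conditions = rep("p0", length(signals)),
                        rate = test_rate, eog = character(0)) {
  times <- seq(-6, 6 - 1 / rate, by = 1 / rate)
  chans <- colnames(signals[[1]])
  data <- array(NA_real_, dim = c(length(signals), length(chans), length(times)),
                dimnames = list(NULL, chans, NULL))
  for (i in seq_along(signals)) data[i, , ] <- t(signals[[i]])
  structure(list(data = data, times = times, rate = rate,
                 channels = setdiff(chans, eog), eog_channels = eog,
                 condition = factor(conditions),
                 rejected = rep(FALSE, length(signals)),
                 rejection_reason = factor(rep("none", length(signals)),
                                           levels = c("blink", "eog", "post_stim_amplitude", "none")),
                 ledger = data.frame(trial = integer(0), kind = character(0))),
            class = "eeg_epochs")
}

# band_energy object built directly from per-trial time courses
# courses: trial x time matrix used for every pool/band cell
make_band_energy <- function(courses, conditions = rep("p0", nrow(courses)),
                             corrected = TRUE,
                             pools = c("frontal", "centroparietal"),
                             bands = c("theta", "alpha")) {
  nb <- 240
  stopifnot(ncol(courses) == nb)
  vals <- array(NA_real_, dim = c(nrow(courses), length(pools), length(bands), nb),
                dimnames = list(NULL, pools, bands, NULL))
  for (p in seq_along(pools)) for (b in seq_along(bands)) vals[, p, b, ] <- courses
  centers <- -6 + (seq_len(nb) - 0.5) * 0.05
  structure(list(values = vals, times = centers,
                 edge = centers < -4 | centers > 4,
                 condition = factor(conditions),
                 baseline_corrected = corrected,
                 baseline_window = if (corrected) c(-6, -4) else NULL),
            class = "band_energy")
}

# analytic-signal envelope via FFT (independent of the wavelet path)
hilbert_env <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  Mod(stats::fft(X * h, inverse = TRUE)) / n
}

# hand-written Benjamini-Hochberg step-up (oracle for fdr_adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# within-subject two-way ANOVA oracle via stats::aov error strata
aov_oracle <- function(df, dv) {
  df$subject <- factor(df$subject)
  df$A <- factor(df$A); df$B <- factor(df$B)
  fml <- stats::as.formula(paste(dv, "~ A * B + Error(subject/(A*B))"))
  fit <- summary(stats::aov(fml, data = df))
  get_row <- function(stratum, label) {
    tab <- fit[[paste0("Error: ", stratum)]][[1]]
    i <- grep(label, trimws(rownames(tab)), fixed = TRUE)
    c(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  rbind(A = get_row("subject:A", "A"),
        B = get_row("subject:B", "B"),
        AB = get_row("subject:A:B", "A:B"))
}

# exhaustive sign-flip permutation p for a paired difference vector
perm_exact_p <- function(d) {
  n <- length(d)
  t_of <- function(x) mean(x) / sqrt(stats::var(x) / length(x))
  t_obs <- t_of(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  t_all <- apply(signs, 1, function(s) t_of(s * d))
  mean(abs(t_all) >= abs(t_obs) - 1e-12)
}
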