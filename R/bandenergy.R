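#' Pool channels and frequency bands
#'
#' For each electrode pool and frequency band, averages the linear wavelet
#' energy over the pool's member channels and over the frequency bins inside
#' the band, then takes the natural log per trial. Frequency bins on a shared
#' band edge belong to the lower band ([band_of()]). Energies are floored at
#' `floor` uV^2 before the log for numerical safety.
#'
#' @param tf a `tf_energy` from [wavelet_energy()].
#' @param pools electrode pools ([electrode_pools()]).
#' @param bands band definitions ([band_set()]).
#' @param floor energy floor in uV^2 applied before the log.
#' @return A `band_energy`: list with `values` (trial x pool x band x time
#'   array of log energy), `times`, `edge`, `condition`,
#'   `baseline_corrected = FALSE`.
#' @export
pool_and_band <- function(tf, pools = electrode_pools(), bands = band_set(),
                          floor = 1e-12) {
  stopifnot(inherits(tf, "tf_energy"))
  chans <- dimnames(tf$energy)[[2]]
  for (p in names(pools))
    if (!all(pools[[p]] %in% chans))
      stop("pool channels missing from decomposition: ",
           paste(setdiff(pools[[p]], chans), collapse = ", "))
  assign_band <- band_of(tf$freqs, bands)
  d <- dim(tf$energy)
  vals <- array(NA_real_,
                dim = c(d[1], length(pools), length(bands), d[4]),
                dimnames = list(NULL, names(pools), names(bands), NULL))
  for (pi in seq_along(pools)) {
    ch_idx <- match(pools[[pi]], chans)
    for (bi in seq_along(bands)) {
      fsel <- which(assign_band == names(bands)[bi])
      acc <- matrix(0, d[1], d[4])
      for (ci in ch_idx) for (fi in fsel)
        acc <- acc + matrix(tf$energy[, ci, fi, ], d[1], d[4])
      vals[, pi, bi, ] <- log(pmax(acc / (length(ch_idx) * length(fsel)), floor))
    }
  }
  structure(list(values = vals, times = tf$times, edge = tf$edge,
                 condition = tf$condition, baseline_corrected = FALSE),
            class = "band_energy")
}

#' Baseline-correct log band energy
#'
#' Subtracts, per (trial, pool, band), the mean log energy over the
#' pre-stimulus reference window (default \[-6, -4\] s), so corrected values
#' are log energy ratios relative to that quiet baseline.
#'
#' @param be a `band_energy`.
#' @param window `c(start, end)` seconds; must lie inside the epoch.
#' @return The corrected `band_energy` (`baseline_corrected = TRUE`,
#'   `baseline_window` recorded).
#' @export
baseline_correct <- function(be, window = c(-6, -4)) {
  stopifnot(inherits(be, "band_energy"))
  sel <- be$times >= window[1] & be$times < window[2]
  if (!any(sel)) stop("baseline window outside the epoch")
  base <- apply(be$values[, , , sel, drop = FALSE], c(1, 2, 3), mean)
  be$values <- sweep(be$values, c(1, 2, 3), base)
  be$baseline_corrected <- TRUE
  be$baseline_window <- window
  be
}

#' Event-related spectral perturbation (trial-average)
#'
#' Averages baseline-corrected log band energy over trials within each
#' condition: the ERSP time course per pool, band and condition.
#'
#' @param be a baseline-corrected `band_energy`.
#' @param conditions condition label per trial (defaults to those carried by
#'   `be`).
#' @return An `ersp_result`: list with `ersp` (pool x band x condition x time
#'   array), `counts` (trials per condition), `times`.
#' @export
compute_ersp <- function(be, conditions = be$condition) {
  stopifnot(inherits(be, "band_energy"))
  if (!isTRUE(be$baseline_corrected))
    stop("ERSP requires baseline-corrected band energy")
  conditions <- as.factor(conditions)
  counts <- table(conditions)
  if (any(counts == 0))
    stop("condition with zero kept trials: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  d <- dim(be$values)
  out <- array(NA_real_, dim = c(d[2], d[3], nlevels(conditions), d[4]),
               dimnames = list(dimnames(be$values)[[2]],
                               dimnames(be$values)[[3]],
                               levels(conditions), NULL))
  for (ci in seq_len(nlevels(conditions))) {
    sel <- conditions == levels(conditions)[ci]
    out[, , ci, ] <- apply(be$values[sel, , , , drop = FALSE], c(2, 3, 4), mean)
  }
  structure(list(ersp = out, counts = c(counts), times = be$times),
            class = "ersp_result")
}

#' Pre- vs post-stimulus mean energy per unit of analysis
#'
#' Summarises each trial's log band energy into its mean over the
#' pre-stimulus (\[-4, 0\) s) and post-stimulus (\[0, 6\) s) windows, per
#' pool and band — the inputs of the pre/post paired comparison.
#'
#' @param be a `band_energy` (corrected or not; the pre/post difference is
#'   invariant to the per-trial baseline shift).
#' @param pre,post window limits in seconds.
#' @return data frame: `trial`, `condition`, `pool`, `band`, `pre`, `post`.
#' @export
pre_post_summary <- function(be, pre = c(-4, 0), post = c(0, 6)) {
  stopifnot(inherits(be, "band_energy"))
  pre_sel <- be$times >= pre[1] & be$times < pre[2]
  post_sel <- be$times >= post[1] & be$times < post[2]
  pre_m <- apply(be$values[, , , pre_sel, drop = FALSE], c(1, 2, 3), mean)
  post_m <- apply(be$values[, , , post_sel, drop = FALSE], c(1, 2, 3), mean)
  d <- dim(pre_m)
  grid <- expand.grid(trial = seq_len(d[1]),
                      pool = dimnames(be$values)[[2]],
                      band = dimnames(be$values)[[3]],
                      stringsAsFactors = FALSE)
  grid$condition <- as.character(be$condition)[grid$trial]
  grid$pre <- as.vector(pre_m)
  grid$post <- as.vector(post_m)
  grid[, c("trial", "condition", "pool", "band", "pre", "post")]
}

#' Paired pre/post t-test per pool and band
#'
#' Paired t-test of mean pre-stimulus vs mean post-stimulus log energy,
#' computed on the supplied units of analysis (trials within a session, or
#' subject means at group level). The statistic is computed on pre - post,
#' so a negative t indicates a post-stimulus energy increase.
#'
#' @param summary data frame as from [pre_post_summary()] (one row per unit
#'   x pool x band; column `unit` or `trial` identifies the unit).
#' @return data frame: `pool`, `band`, `n`, `t`, `df`, `p`, `degenerate`.
#' @export
pre_post_test <- function(summary) {
  key <- interaction(summary$pool, summary$band, sep = ":")
  out <- do.call(rbind, lapply(split(seq_len(nrow(summary)), key), function(ii) {
    d <- summary$pre[ii] - summary$post[ii]
    n <- length(d)
    if (n < 2) stop("paired pre/post test needs >= 2 units")
    if (stats::sd(d) == 0) {
      return(data.frame(pool = summary$pool[ii[1]], band = summary$band[ii[1]],
                        n = n, t = 0, df = n - 1, p = 1, degenerate = TRUE))
    }
    tt <- stats::t.test(summary$pre[ii], summary$post[ii], paired = TRUE)
    data.frame(pool = summary$pool[ii[1]], band = summary$band[ii[1]], n = n,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, degenerate = FALSE)
  }))
  rownames(out) <- NULL
  out
}
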