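#' Second-degree polynomial trend of a post-stimulus energy course
#'
#' Least-squares fit of `y(t) = b0 + b1*(t - 3) + b2*(t - 3)^2` on the
#' post-stimulus window \[0, 6\] s. Time is centred at 3 s, so the intercept
#' `b0` is literally the fitted baseline-corrected energy at 3 s
#' post-stimulus, `b1` the linear tendency (log-energy per second), and `b2`
#' the curvature: positive for a U-shape, negative for an inverted U.
#'
#' @param values numeric vector (one course) or matrix (time in rows, one
#'   course per column) of baseline-corrected log energy.
#' @param times time axis in seconds; must contain at least 3 distinct
#'   points and cover the post-stimulus window.
#' @param center centre of the time basis (s).
#' @return For a vector input, named numeric `c(intercept, slope,
#'   quadratic)`; for a matrix, a 3 x ncol coefficient matrix.
#' @export
fit_trend <- function(values, times, center = 3) {
  if (length(unique(times)) < 3)
    stop("trend fit needs at least 3 distinct time points")
  u <- times - center
  X <- cbind(intercept = 1, slope = u, quadratic = u^2)
  co <- qr.coef(qr(X), as.matrix(values))
  rownames(co) <- c("intercept", "slope", "quadratic")
  if (is.null(dim(values))) co[, 1] else co
}

#' Per-trial trend features for every pool and band
#'
#' Applies [fit_trend()] to the baseline-corrected post-stimulus (\[0, 6\] s)
#' energy course of every trial, pool and band.
#'
#' @param be a baseline-corrected `band_energy`.
#' @param window fit window in seconds post-stimulus.
#' @return data frame: `trial`, `condition`, `pool`, `band`, `intercept`,
#'   `slope`, `quadratic` — one row per (trial, pool, band).
#' @export
feature_table <- function(be, window = c(0, 6)) {
  stopifnot(inherits(be, "band_energy"))
  if (!isTRUE(be$baseline_corrected))
    stop("trend features require baseline-corrected band energy")
  sel <- be$times >= window[1] & be$times < window[2]
  tt <- be$times[sel]
  d <- dim(be$values)
  pools <- dimnames(be$values)[[2]]
  bands <- dimnames(be$values)[[3]]
  out <- vector("list", d[2] * d[3])
  k <- 0L
  for (bi in seq_len(d[3])) {
    for (pi in seq_len(d[2])) {
      y <- t(be$values[, pi, bi, sel, drop = TRUE])   # time x trial
      if (d[1] == 1L) y <- matrix(be$values[1, pi, bi, sel], ncol = 1)
      co <- fit_trend(y, tt)
      k <- k + 1L
      out[[k]] <- data.frame(trial = seq_len(d[1]),
                             condition = as.character(be$condition),
                             pool = pools[pi], band = bands[bi],
                             intercept = co[1, ], slope = co[2, ],
                             quadratic = co[3, ])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
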