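rate <- 512
times <- seq(-6, 6 - 1 / rate, by = 1 / rate)

test_that("wavelet energy is maximal at the oscillation frequency and scales quadratically", {
  x <- cbind(A = 2 * sin(2 * pi * 10 * times))
  tf <- wavelet_energy(make_epochs(list(x)))
  en <- apply(tf$energy[1, 1, , ], 1, mean)
  expect_lte(abs(tf$freqs[which.max(en)] - 10), 0.5)
  # amplitude-squared convention: unit response at the centre frequency
  expect_equal(unname(en[tf$freqs == 10]), 4, tolerance = 0.05)
  tf2 <- wavelet_energy(make_epochs(list(2 * x)))
  expect_equal(mean(tf2$energy) / mean(tf$energy), 4, tolerance = 1e-10)
})

test_that("wavelet frequencies above Nyquist (after decimation) are refused", {
  ep <- make_epochs(list(cbind(A = rnorm(length(times)))))
  expect_error(wavelet_energy(ep, freqs = c(10, 70)), "Nyquist|rate")
  expect_error(wavelet_energy(ep, cycles = 2))
})

test_that("band energy of a stationary narrowband signal matches a Hilbert-envelope oracle", {
  set.seed(7)
  # 10 Hz with slowly drifting amplitude, plus weak broadband noise
  amp <- 3 + sin(2 * pi * 0.05 * times)
  x <- amp * sin(2 * pi * 10 * times) + rnorm(length(times), sd = 0.1)
  tf <- wavelet_energy(make_epochs(list(cbind(Cz = x))))
  wav <- mean(tf$energy[1, 1, tf$freqs == 10, !tf$edge])
  env <- hilbert_env(x)
  oracle <- mean(env[abs(times) < 4]^2)
  expect_equal(wav, oracle, tolerance = 0.1)
})

test_that("white-noise energy is flat across frequency after 1/f normalisation", {
  set.seed(8)
  en <- rowMeans(replicate(15, {
    tf <- wavelet_energy(make_epochs(list(cbind(A = rnorm(length(times))))))
    apply(tf$energy[1, 1, , ], 1, mean)
  }))
  nf <- en / seq(3.5, 30, 0.5)
  expect_equal(nf[which(seq(3.5, 30, 0.5) == 6)],
               nf[which(seq(3.5, 30, 0.5) == 20)], tolerance = 0.1)
})

test_that("pooling averages member channels and band bins before the log", {
  freqs <- seq(3.5, 30, 0.5)
  pools <- electrode_pools()
  nch <- length(pps_channels())
  e <- array(2, dim = c(1, nch, length(freqs), 240),
             dimnames = list(NULL, pps_channels(), NULL, NULL))
  tf <- structure(list(energy = e, freqs = freqs,
                       times = -6 + (1:240 - 0.5) * 0.05,
                       edge = rep(FALSE, 240), condition = factor("p0"),
                       rate = 512), class = "tf_energy")
  be <- pool_and_band(tf)
  expect_true(all(abs(be$values - log(2)) < 1e-12))
  # one frontal channel carrying all theta energy: mean = e / 7
  e2 <- array(0, dim = dim(e), dimnames = dimnames(e))
  e2[1, "Fz", band_of(freqs) == "theta", ] <- 7 * exp(1)
  tf$energy <- e2
  be2 <- pool_and_band(tf, floor = 1e-300)
  expect_equal(unname(be2$values[1, "frontal", "theta", 1]), 1)
  # shared band edges belong to the lower band
  bo <- band_of(freqs)
  expect_equal(as.character(bo[freqs == 8]), "theta")
  expect_equal(as.character(bo[freqs == 12]), "alpha")
  expect_equal(as.character(bo[freqs == 12.5]), "beta")
})

test_that("pooled linear energy lies within the member-channel range", {
  set.seed(9)
  sig <- lapply(1:2, function(i)
    matrix(rnorm(length(times) * 21, sd = 5), ncol = 21,
           dimnames = list(NULL, pps_channels())))
  tf <- wavelet_energy(make_epochs(sig, conditions = c("p0", "p1")))
  be <- pool_and_band(tf)
  pools <- electrode_pools()
  bo <- band_of(tf$freqs)
  for (p in names(pools)) for (b in levels(bo)) {
    pooled <- exp(be$values[1, p, b, 17])
    member <- sapply(pools[[p]], function(ch)
      mean(tf$energy[1, ch, bo == b, 17]))
    expect_gte(pooled, min(member) - 1e-12)
    expect_lte(pooled, max(member) + 1e-12)
  }
})

test_that("baseline correction zeroes the reference window and ignores offsets", {
  set.seed(10)
  courses <- matrix(rnorm(3 * 240), 3)
  be <- make_band_energy(courses, corrected = FALSE)
  bc <- baseline_correct(be)
  base_mean <- apply(bc$values[, , , bc$times < -4, drop = FALSE],
                     c(1, 2, 3), mean)
  expect_true(all(abs(base_mean) < 1e-12))
  # adding a constant per trial leaves the corrected course unchanged
  be2 <- make_band_energy(courses + 5, corrected = FALSE)
  bc2 <- baseline_correct(be2)
  expect_equal(bc$values, bc2$values)
  expect_error(baseline_correct(be, c(-20, -10)), "outside")
})

test_that("ERSP is the per-condition trial mean and is duplication-invariant", {
  set.seed(11)
  courses <- matrix(rnorm(4 * 240), 4)
  be <- make_band_energy(courses, conditions = c("p0", "p1", "p0", "p1"))
  er <- compute_ersp(be)
  expect_equal(unname(er$counts), c(2, 2))
  expect_equal(er$ersp["frontal", "theta", "p0", ],
               colMeans(courses[c(1, 3), ]))
  dup <- make_band_energy(courses[rep(1:4, 2), ],
                          conditions = rep(c("p0", "p1", "p0", "p1"), 2))
  expect_equal(compute_ersp(dup)$ersp, er$ersp)
  # all-zero input, zero output
  z <- make_band_energy(matrix(0, 2, 240), conditions = c("p0", "p1"))
  expect_true(all(compute_ersp(z)$ersp == 0))
  # refuses uncorrected input and empty conditions
  expect_error(compute_ersp(make_band_energy(courses, corrected = FALSE)),
               "baseline")
  expect_error(compute_ersp(be, factor(c("p0", "p1", "p0", "p1"),
                                       levels = c("p0", "p1", "p2"))),
               "zero kept")
})

test_that("ERSP of a merged trial set is the weighted mean of subset ERSPs", {
  set.seed(12)
  c1 <- matrix(rnorm(2 * 240), 2)
  c2 <- matrix(rnorm(3 * 240), 3)
  e1 <- compute_ersp(make_band_energy(c1))$ersp
  e2 <- compute_ersp(make_band_energy(c2))$ersp
  em <- compute_ersp(make_band_energy(rbind(c1, c2)))$ersp
  expect_equal(em, (2 * e1 + 3 * e2) / 5)
})

test_that("pre/post comparison is signed so that increases give negative t", {
  courses <- matrix(0, 3, 240)
  be <- make_band_energy(courses)
  s <- pre_post_summary(be)
  r <- pre_post_test(s)
  expect_true(all(r$t == 0) && all(r$p == 1) && all(r$degenerate))
  # uniform post-stimulus increase -> negative t
  up <- courses; up[, 121:240] <- rep(c(1, 1.2, 0.9), 120)
  s2 <- pre_post_summary(make_band_energy(up))
  r2 <- pre_post_test(s2)
  expect_true(all(r2$t < 0))
  expect_true(all(r2$p < 0.05))
})
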