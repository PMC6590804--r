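test_that("band-pass keeps in-band components and removes drift", {
  n <- 512 * 60
  tt <- (1:n) / 512
  x <- cbind(ten = sin(2 * pi * 10 * tt), drift = sin(2 * pi * 0.05 * tt),
             edge = sin(2 * pi * 0.15 * tt), hi = sin(2 * pi * 90 * tt))
  rec <- bandpass(make_recording(x))
  mid <- (512 * 15):(512 * 45)
  gain <- function(ch) stats::sd(rec$samples[mid, ch]) / stats::sd(x[mid, ch])
  expect_gt(gain("ten"), 0.95)            # in-band preserved within 5%
  expect_lt(gain("drift"), 0.10)          # 0.05 Hz reduced >= 90%
  expect_lt(gain("edge"), 10^(-20 / 20))  # >= 20 dB one octave below 0.3
  expect_lt(gain("hi"), 10^(-20 / 20))    # >= 20 dB one octave above 45
})

test_that("band-pass is zero-phase (no stimulus-latency shift)", {
  n <- 512 * 30
  tt <- (1:n) / 512
  x <- cbind(s = sin(2 * pi * 10 * tt))
  rec <- bandpass(make_recording(x))
  mid <- (512 * 10):(512 * 20)
  # zero phase <=> filtered output is a pure rescaling of the input in-band
  expect_gt(stats::cor(rec$samples[mid, 1], x[mid, 1]), 0.99999)
})

test_that("invalid filter bands are refused", {
  rec <- make_recording(cbind(a = rnorm(1024)))
  expect_error(bandpass(rec, 45, 0.3))
  expect_error(bandpass(rec, 0.3, 300))
})

test_that("segmentation yields one 6144-sample epoch per valid event", {
  d <- build_design("main", 3, seed = 13)
  rec <- generate_session(d, artifacts = NULL, seed = 14)
  ep <- segment(rec)
  expect_equal(dim(ep$data), c(9, 23, 6144))
  expect_equal(as.character(ep$condition), as.character(d$position))
  expect_equal(range(ep$times), c(-6, 6 - 1 / 512))
  # event too close to the recording edge is skipped with a warning
  rec$events$sample[1] <- 3 * 512
  expect_warning(ep2 <- segment(rec), "margin")
  expect_equal(dim(ep2$data)[1], 8)
})

test_that("rejection rules flag the right trials for the right reasons", {
  rate <- 512
  base <- function() matrix(0, 6144, 4,
                            dimnames = list(NULL, c("Fp1", "O1", "Cz", "EOG1")))
  blink <- base(); blink[3000:3100, "Fp1"] <- 70
  eogm <- base(); eogm[1000:1200, "EOG1"] <- 35
  post <- base(); post[3073 + seq_len(100), "O1"] <- 70   # inside [0, 800] ms
  late <- base(); late[5000:5100, "O1"] <- 70             # outside the window
  ok <- base(); ok[2000:2100, "Fp1"] <- 59; ok[2000:2100, "EOG1"] <- 29
  both <- base(); both[3000:3100, "Fp1"] <- 70; both[3000:3100, "EOG1"] <- 40
  ep <- make_epochs(list(blink, eogm, post, late, ok, both), eog = "EOG1",
                    conditions = rep("p0", 6))
  ep <- reject(ep)
  expect_equal(as.character(ep$rejection_reason),
               c("blink", "eog", "post_stim_amplitude", "none", "none", "blink"))
  expect_equal(ep$rejected, c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  # idempotence and count conservation
  ep2 <- reject(ep)
  expect_identical(ep2$rejection_reason, ep$rejection_reason)
  expect_equal(sum(ep$rejected) + sum(!ep$rejected), 6)
})

test_that("thresholds are read relative to the pre-stimulus mean", {
  base <- matrix(50, 6144, 2, dimnames = list(NULL, c("Fp1", "Cz")))
  # constant 50 uV offset everywhere: deviation from own baseline is zero
  ep <- reject(make_epochs(list(base)))
  expect_false(ep$rejected[1])
  # 55 uV excursion on top of the offset crosses the 60 uV rule only if
  # measured absolutely; relative to baseline it stays below
  shifted <- base; shifted[3200:3300, "Fp1"] <- 105
  ep2 <- reject(make_epochs(list(shifted)))
  expect_false(ep2$rejected[1])
  shifted[3200:3300, "Fp1"] <- 115   # 65 uV above the 50 uV baseline
  ep3 <- reject(make_epochs(list(shifted)))
  expect_true(ep3$rejected[1])
})

test_that("ledger-injected artifacts are rejected with matching reasons", {
  d <- build_design("main", 8, seed = 31)
  spec <- artifact_spec(blink_prob = 0.15, eog_prob = 0.1, broadband_prob = 0.1)
  rec <- bandpass(generate_session(d, artifacts = spec, seed = 32))
  ep <- reject(segment(rec))
  led <- ep$ledger[order(ep$ledger$trial), ]
  expect_gt(nrow(led), 0)
  expect_setequal(which(ep$rejected), led$trial)
  expect_equal(as.character(ep$rejection_reason[led$trial]),
               ifelse(led$kind == "post_stim_amplitude",
                      "post_stim_amplitude", led$kind))
})

test_that("artifact-free sessions keep the design's condition balance", {
  d <- build_design("main", 5, seed = 41)
  rec <- bandpass(generate_session(d, artifacts = NULL, seed = 42))
  ep <- reject(segment(rec))
  expect_equal(sum(ep$rejected), 0)
  expect_true(all(table(keep_trials(ep)$condition) == 5))
  md <- trial_metadata(ep)
  expect_equal(nrow(md), 15)
  expect_true(all(md$reason == "none"))
})
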