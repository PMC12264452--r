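sine_epochs <- function(f0, fs = 250, dur = 1, amp = 1, n_trials = 2,
                        t0 = -0.2) {
  times <- t0 + (seq_len(round(dur * fs) + 1) - 1) / fs
  x <- array(rep(amp * sin(2 * pi * f0 * times), n_trials),
             dim = c(1, length(times), n_trials))
  eeg_epochs(x, fs, t0, "FCz")
}

test_that("a pure 10 Hz sinusoid concentrates its power in the alpha band", {
  tfr <- tfr_hanning(sine_epochs(10), freqs = seq(3, 40, by = 0.5))
  bands <- eeg_bands()[1:4, ]   # bands within the reduced grid
  means <- vapply(bands$band, function(b)
    mean(band_average(tfr, b, c(0.1, 0.5))), numeric(1))
  expect_identical(names(which.max(means)), "alpha")
})

test_that("frequency localization is within one step for 5/10/20/40 Hz", {
  freqs <- seq(3, 60, by = 0.5)
  for (f0 in c(5, 10, 20, 40)) {
    tfr <- tfr_hanning(sine_epochs(f0, fs = 250), freqs = freqs)
    spec <- apply(tfr$power[1, , , drop = FALSE], 2, mean, na.rm = TRUE)
    expect_lte(abs(freqs[which.max(spec)] - f0), 0.5)
  }
})

test_that("power scales quadratically with amplitude", {
  t1 <- tfr_hanning(sine_epochs(10, amp = 1), freqs = seq(5, 20, 0.5))
  t2 <- tfr_hanning(sine_epochs(10, amp = 2), freqs = seq(5, 20, 0.5))
  ok <- !is.na(t1$power)
  expect_equal(t2$power[ok], 4 * t1$power[ok], tolerance = 1e-8)
})

test_that("broadband power scales linearly with white-noise variance", {
  set.seed(10)
  n <- 500
  mk <- function(sd_x) {
    x <- array(rnorm(n * 6, sd = sd_x), dim = c(1, n, 6))
    tf <- tfr_hanning(eeg_epochs(x, 250, 0, "a"), freqs = seq(5, 100, 5))
    mean(tf$power, na.rm = TRUE)
  }
  p1 <- mean(replicate(4, mk(1)))
  p2 <- mean(replicate(4, mk(2)))
  expect_equal(p2 / p1, 4, tolerance = 0.3)
})

test_that("white noise is spectrally flat across mid bands at fixed window", {
  # a fixed-length window gives every bin the same noise bandwidth;
  # adaptive windows trade that for uniform cycle counts
  set.seed(11)
  x <- array(rnorm(500 * 40), dim = c(1, 500, 40))
  tf <- tfr_hanning(eeg_epochs(x, 250, 0, "a"), freqs = seq(20, 40, 0.5),
                    fixed_window_s = 0.2)
  p_lo <- mean(band_average(tf, c(20, 30), c(0.4, 1.6)))
  p_hi <- mean(band_average(tf, c(30, 40), c(0.4, 1.6)))
  expect_equal(p_lo / p_hi, 1, tolerance = 0.2)
})

test_that("dB baselining satisfies the log identities", {
  # constant power: synthetic TFR via a constant-amplitude sinusoid
  tfr <- tfr_hanning(sine_epochs(10, dur = 1.2, t0 = -0.4),
                     freqs = seq(8, 12, 0.5))
  db <- baseline_db(tfr, baseline = c(-0.3, -0.1))
  # stationary signal: power equals its baseline mean -> ~0 dB
  expect_lt(max(abs(db$power[1, , db$times > 0.2 & db$times < 0.6])), 0.2)

  # exact identities on a hand-built TFR object
  raw <- tfr
  raw$power[] <- 1
  raw$power[1, , raw$times > 0.3] <- 10
  db2 <- baseline_db(raw, baseline = c(-0.3, -0.1))
  expect_equal(unique(db2$power[1, 1, db2$times > 0.3 & db2$valid[1, ]]), 10)
  raw$power[1, , raw$times > 0.3] <- 0.5
  db3 <- baseline_db(raw, baseline = c(-0.3, -0.1))
  expect_equal(unique(db3$power[1, 1, db3$times > 0.3 & db3$valid[1, ]]),
               10 * log10(0.5))
  expect_equal(10 * log10(0.5), -3.0103, tolerance = 1e-4)

  zero <- tfr; zero$power[] <- 0
  expect_error(baseline_db(zero, c(-0.3, -0.1)), "non-positive baseline")
  expect_error(baseline_db(db, c(-0.3, -0.1)), "already")
})

test_that("band membership is half-open with a closed top edge", {
  freqs <- seq(3, 80, 0.5)
  sel_alpha <- cerebwm:::band_bins(freqs, 8, 13)
  sel_theta <- cerebwm:::band_bins(freqs, 4, 8)
  expect_true(sel_alpha[freqs == 8])
  expect_false(sel_theta[freqs == 8])
  expect_false(sel_alpha[freqs == 13])
  sel_gamma <- cerebwm:::band_bins(freqs, 30, 80)
  expect_true(sel_gamma[freqs == 80])
  # no bin in two bands
  b <- eeg_bands()
  counts <- rowSums(vapply(seq_len(nrow(b)), function(i)
    cerebwm:::band_bins(freqs, b$low[i], b$high[i]), logical(length(freqs))))
  expect_lte(max(counts), 1)
})

test_that("band averaging respects constants and construction ordering", {
  tfr <- tfr_hanning(sine_epochs(10), freqs = seq(4, 20, 0.5))
  flat <- tfr; flat$power[] <- 2; flat$baseline_mode <- "dB"
  expect_true(all(band_average(flat, "alpha", c(0.1, 0.3)) == 2))
  expect_gte(mean(band_average(tfr, "alpha", c(0.1, 0.5))),
             mean(band_average(tfr, "theta", c(0.1, 0.5))))
  expect_error(band_average(tfr, "alpha", c(5, 6)), "empty|no valid")
  expect_error(band_average(tfr, "nogamma"), "unknown band")
})

test_that("edge bins are flagged invalid, never silently zero-padded", {
  tfr <- tfr_hanning(sine_epochs(10), freqs = c(5, 10))
  # 4 cycles at 5 Hz = 0.8 s window on a 1 s epoch: most bins invalid
  expect_true(any(!tfr$valid[1, ]))
  expect_true(all(is.na(tfr$power[1, 1, !tfr$valid[1, ]])))
  expect_true(all(!is.na(tfr$power[1, 1, tfr$valid[1, ]])))
})

test_that("impossible requests raise informative errors", {
  ep <- sine_epochs(10)
  expect_error(tfr_hanning(ep, freqs = c(3, 130)), "Nyquist")
  expect_error(tfr_hanning(ep, freqs = 3, fixed_window_s = 0.1),
               "below the spectral resolution")
  short <- sine_epochs(10, dur = 0.3)
  expect_error(tfr_hanning(short, freqs = 5), "shorter than the longest")
})
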