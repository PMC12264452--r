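make_epochs <- function(data, fs = 250, t0 = -0.2,
                        channels = paste0("ch", seq_len(dim(data)[1]))) {
  eeg_epochs(data, fs = fs, t0 = t0, channels = channels)
}

test_that("averaging removes the baseline and is idempotent over identical trials", {
  # constant signal cancels entirely
  const <- array(5, dim = c(2, 251, 4))
  erp <- average_erp(make_epochs(const))
  expect_true(all(abs(erp$data) < 1e-12))

  # n identical trials equal one trial
  set.seed(1)
  one <- matrix(rnorm(2 * 251), 2, 251)
  rep4 <- array(rep(one, 4), dim = c(2, 251, 4))
  e1 <- average_erp(make_epochs(array(one, dim = c(2, 251, 1))))
  e4 <- average_erp(make_epochs(rep4))
  expect_equal(e4$data, e1$data)

  # baseline interval mean is zero after correction
  set.seed(2)
  noisy <- array(rnorm(2 * 251 * 8, mean = 3), dim = c(2, 251, 8))
  eb <- average_erp(make_epochs(noisy))
  bidx <- eb$times >= -0.2 & eb$times <= 0
  expect_lt(max(abs(rowMeans(eb$data[, bidx]))), 1e-9)

  expect_error(average_erp(make_epochs(const), baseline = c(-1, 0)),
               "outside the epoch")
})

test_that("averaging is linear over concatenated trial sets", {
  set.seed(3)
  a <- array(rnorm(2 * 251 * 5), dim = c(2, 251, 5))
  b <- array(rnorm(2 * 251 * 3), dim = c(2, 251, 3))
  eab <- average_erp(make_epochs(array(c(a, b), dim = c(2, 251, 8))))
  ea <- average_erp(make_epochs(a))
  eb <- average_erp(make_epochs(b))
  expect_equal(eab$data, (5 * ea$data + 3 * eb$data) / 8, tolerance = 1e-12)
})

test_that("noise-only averages shrink with the trial count", {
  set.seed(4)
  amp_at <- function(n) {
    x <- array(rnorm(251 * n), dim = c(1, 251, n))
    mean(abs(average_erp(make_epochs(x))$data))
  }
  many <- mean(replicate(10, amp_at(64)))
  few <- mean(replicate(10, amp_at(4)))
  expect_lt(many, few / 2)   # expected ratio 1/4
})

test_that("component amplitude is the windowed mean against an analytic oracle", {
  fs <- 1000
  times <- seq(-0.2, 0.8, by = 1 / fs)
  # flat 5 uV inside the window
  flat <- matrix(0, 1, length(times))
  flat[1, times >= 0.13 & times <= 0.19] <- 5
  erp <- structure(list(data = flat, times = times, channels = "FCz",
                        n_trials = 1), class = "erp_waveform")
  expect_equal(component_amplitude(erp, "P150", "FCz"), 5)

  # Gaussian bump: window mean equals the closed-form Gaussian integral
  mu <- 0.160; sig <- 0.015; amp <- 4
  g <- amp * exp(-(times - mu)^2 / (2 * sig^2))
  erp_g <- structure(list(data = matrix(g, 1), times = times,
                          channels = "FCz", n_trials = 1),
                     class = "erp_waveform")
  got <- component_amplitude(erp_g, c(130, 190), "FCz")
  a <- 0.130; b <- 0.190
  expected <- amp * sig * sqrt(2 * pi) *
    (pnorm((b - mu) / sig) - pnorm((a - mu) / sig)) / (b - a)
  # discrete sample mean vs continuous integral: agreement to ~2%
  expect_equal(got, expected, tolerance = 0.02)

  # invariance to signal wholly outside the window
  erp_g2 <- erp_g
  erp_g2$data[1, times < 0.1] <- erp_g2$data[1, times < 0.1] + 100
  expect_equal(component_amplitude(erp_g2, c(130, 190), "FCz"), got)

  expect_error(component_amplitude(erp_g, "P150", character(0)), "empty")
  expect_error(component_amplitude(erp_g, "P150", "Oz"), "unknown channel")
  expect_error(component_amplitude(erp_g, c(900, 950), "FCz"), "no samples")
})

test_that("difference waves subtract pointwise and commute with amplitudes", {
  cfg <- small_cfg(n_trials = 10)
  set.seed(6)
  pre <- average_erp(generate_epochs(cfg, "rTMS5", "pre", "task"))
  set.seed(7)
  post <- average_erp(generate_epochs(cfg, "rTMS5", "post", "task"))
  dw <- difference_wave(post, pre)
  expect_equal(dw$data, post$data - pre$data)
  expect_equal(component_amplitude(dw, "P150"),
               component_amplitude(post, "P150") -
                 component_amplitude(pre, "P150"))
  zero <- difference_wave(pre, pre)
  expect_true(all(zero$data == 0))
  short <- pre; short$times <- pre$times + 0.004
  expect_error(difference_wave(post, short), "share channel and time axes")
})

test_that("preprocessing drops exactly the artifactual trials", {
  cfg <- small_cfg(n_trials = 6)
  set.seed(8)
  ep <- generate_epochs(cfg, "sham", "pre", "task")
  clean <- preprocess_epochs(ep)
  expect_equal(attr(clean, "n_dropped"), 0)

  spiked <- ep
  spiked$data[1, 100, 3] <- 500
  pp <- preprocess_epochs(spiked, band = NULL)
  expect_equal(attr(pp, "n_dropped"), 1)
  expect_equal(dim(pp$data)[3], 5)

  all_bad <- ep
  all_bad$data <- all_bad$data + 1000
  expect_error(preprocess_epochs(all_bad, band = NULL), "all trials rejected")
})

test_that("double filtering narrows the passband", {
  set.seed(9)
  fs <- 250
  x <- array(rnorm(1 * 500 * 4), dim = c(1, 500, 4))
  ep <- eeg_epochs(x, fs, 0, "ch1")
  once <- preprocess_epochs(ep, band = c(2, 30), reject_uv = Inf)
  twice <- preprocess_epochs(once, band = c(2, 30), reject_uv = Inf)
  psd_at <- function(e, f) {
    v <- e$data[1, , 1]
    sp <- Mod(fft(v))^2
    fr <- seq(0, fs, length.out = length(v) + 1)[seq_along(v)]
    mean(sp[fr >= f - 1 & fr <= f + 1])
  }
  # attenuation beyond the edge grows with the second pass
  expect_lt(psd_at(twice, 40) / psd_at(twice, 15),
            psd_at(once, 40) / psd_at(once, 15))
})
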