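# Filtering, referencing, epoching, baseline, averaging.

make_rec <- function(x, fs = 1000) {
  continuous_recording(matrix(x, nrow = 1), fs, reference = "Fz")
}

test_that("band-pass passes 10 Hz untouched, kills DC, notches 50 Hz", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  fit_amp <- function(y, f) {
    b <- qr.solve(cbind(sin(2 * pi * f * t), cos(2 * pi * f * t)), y)
    list(amp = sqrt(sum(b^2)), phase_deg = atan2(b[2], b[1]) * 180 / pi)
  }
  # 10 Hz sinusoid: < 1% attenuation, < 0.5 degree phase (FFT/regression oracle)
  y10 <- drop(bandpass_notch(make_rec(sin(2 * pi * 10 * t), fs))$data)
  r10 <- fit_amp(y10, 10)
  expect_gt(r10$amp, 0.99)
  expect_lt(abs(r10$phase_deg), 0.5)
  # 50 Hz with notch: >= 20 dB down
  y50 <- drop(bandpass_notch(make_rec(sin(2 * pi * 50 * t), fs))$data)
  expect_lt(20 * log10(fit_amp(y50, 50)$amp), -20)
  # DC is outside the passband
  ydc <- drop(bandpass_notch(make_rec(rep(1, length(t)), fs))$data)
  mid <- seq(fs, length(t) - fs)
  expect_lt(max(abs(ydc[mid])), 1e-2)
  # band above Nyquist rejected
  expect_error(
    bandpass_notch(make_rec(t, fs = 100), filter_spec(band = c(0.5, 70))),
    "Nyquist"
  )
})

test_that("filtering is linear (superposition on random signals)", {
  withr::local_seed(21)
  fs <- 500
  a <- rnorm(1000)
  b <- rnorm(1000)
  spec <- filter_spec(notch_hz = NULL)
  fa <- drop(bandpass_notch(make_rec(a, fs), spec)$data)
  fb <- drop(bandpass_notch(make_rec(b, fs), spec)$data)
  fab <- drop(bandpass_notch(make_rec(a + 2 * b, fs), spec)$data)
  expect_equal(fab, fa + 2 * fb, tolerance = 1e-6)
})

test_that("average reference zeroes the channel mean and is idempotent", {
  ev <- evoked_series(matrix(c(2, 0, -2, 0, 5, 5, 5, 5), nrow = 4),
    time = c(0, 1), n_trials = 1
  )
  out <- to_average_reference(ev)
  expect_equal(out$data[, 1], c(2, 0, -2, 0)) # already zero-mean: unchanged
  expect_equal(out$data[, 2], rep(0, 4)) # constant map annihilated
  withr::local_seed(5)
  e <- random_epochs()
  once <- to_average_reference(e)
  twice <- to_average_reference(once)
  expect_equal(twice$data, once$data, tolerance = 1e-12)
  expect_true(all(abs(apply(once$data, c(1, 3), mean)) < 1e-9))
  one_ch <- evoked_series(matrix(1, 1, 2), time = c(0, 1), n_trials = 1)
  expect_error(to_average_reference(one_ch), "single channel")
})

test_that("difference channels subtract per sample", {
  m <- test_montage()
  ev <- evoked_series(matrix(rnorm(nrow(m) * 5), nrow(m)), time = 0:4,
    n_trials = 1, montage = m
  )
  d <- difference_channel(ev, "Cz", "Fz")
  expect_equal(d$value, ev$data[m$label == "Cz", ] - ev$data[m$label == "Fz", ])
  expect_equal(difference_channel(ev, "Cz", "Cz")$value, rep(0, 5))
  expect_error(difference_channel(ev, "Cz", "Nope"), "Nope")
})

test_that("segmentation uses the canonical window arithmetic", {
  fs <- 5000
  x <- matrix(seq_len(2 * 20000), nrow = 2)
  rec <- continuous_recording(x, fs,
    events = tibble::tibble(sample = c(10000L, 100L), code = c("S  1", "S  1"))
  )
  expect_message(
    ep <- segment_epochs(rec, t_min_ms = -100, t_max_ms = 600),
    "dropped 1"
  )
  # epoch spans event - 500 .. event + 3000 samples at 5000 Hz
  expect_identical(dim(ep$data), c(1L, 2L, 3501L))
  expect_equal(ep$data[1, , ], x[, 9500:13000])
  expect_equal(range(ep$time), c(-100, 600))
  expect_true(0 %in% ep$time)
  # cardinality: one epoch per fitting event
  rec2 <- continuous_recording(x, fs,
    events = tibble::tibble(sample = seq(1000L, 15000L, by = 40L), code = "S  1")
  )
  ep2 <- segment_epochs(rec2)
  expect_equal(dim(ep2$data)[1], nrow(rec2$events))
})

test_that("artifact rejection matches a brute-force scan and honors overrides", {
  e <- random_epochs(n_trials = 3)
  e$data[] <- 0
  e$data[1, 1, 5] <- 99
  e$data[2, 3, 7] <- -101
  out <- reject_artifacts(e, threshold_uv = 100)
  expect_equal(out$kept, c(TRUE, FALSE, TRUE))
  withr::local_seed(33)
  e2 <- random_epochs(n_trials = 40)
  e2$data <- e2$data * 60
  out2 <- reject_artifacts(e2, threshold_uv = 100)
  brute <- vapply(seq_len(40), function(i) all(abs(e2$data[i, , ]) <= 100), TRUE)
  expect_identical(out2$kept, brute)
  out3 <- reject_artifacts(e2, threshold_uv = 100, reject = 1, keep = 2)
  expect_false(out3$kept[1])
  expect_true(out3$kept[2])
})

test_that("baseline correction zeroes the window mean; linear drift leaves the closed form", {
  e <- random_epochs(n_trials = 2)
  e$data[] <- 7
  out <- baseline_correct(e)
  expect_true(all(abs(out$data) < 1e-12))
  withr::local_seed(2)
  e2 <- random_epochs(n_trials = 3)
  out2 <- baseline_correct(e2, window_ms = c(-53, -3))
  idx <- which(e2$time >= -53 & e2$time <= -3)
  expect_true(all(abs(apply(out2$data[, , idx], c(1, 2), mean)) < 1e-10))
  # drift a*t -> residual a*(t - mean(window t))
  a <- 0.3
  ev <- evoked_series(matrix(a * e2$time, nrow = 2, ncol = length(e2$time), byrow = TRUE),
    time = e2$time, n_trials = 1
  )
  evb <- baseline_correct(ev, window_ms = c(-53, -3))
  expect_equal(evb$data[1, ], a * (e2$time - mean(e2$time[idx])), tolerance = 1e-10)
})

test_that("averaging and split halves follow kept-trial parity", {
  withr::local_seed(9)
  e <- random_epochs(n_trials = 4)
  x <- e$data[1, , ]
  for (i in 2:4) e$data[i, , ] <- x # identical trials
  ev <- average_epochs(e)
  sh <- split_half_averages(e)
  expect_equal(ev$data, x, ignore_attr = TRUE)
  expect_equal(sh$odd$data, sh$even$data)
  expect_equal(sh$odd$data, x, ignore_attr = TRUE)
  # {x, -x} averages to zero
  e2 <- random_epochs(n_trials = 2)
  e2$data[2, , ] <- -e2$data[1, , ]
  expect_true(all(abs(average_epochs(e2)$data) < 1e-12))
  # mean matches manual mean over kept trials
  e3 <- random_epochs(n_trials = 5)
  e3$kept <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  manual <- apply(e3$data[c(1, 3, 4), , ], c(2, 3), mean)
  expect_equal(average_epochs(e3)$data, manual, ignore_attr = TRUE)
  expect_equal(average_epochs(e3)$n_trials, 3L)
  e3$kept <- rep(FALSE, 5)
  expect_error(average_epochs(e3), "no kept trials")
})

test_that("linear preprocessing commutes with trial averaging", {
  withr::local_seed(14)
  e <- random_epochs(n_trials = 6)
  # average reference
  a1 <- average_epochs(to_average_reference(e))$data
  a2 <- to_average_reference(average_epochs(e))$data
  expect_equal(a1, a2, tolerance = 1e-8)
  # baseline correction
  b1 <- average_epochs(baseline_correct(e))$data
  b2 <- baseline_correct(average_epochs(e))$data
  expect_equal(b1, b2, tolerance = 1e-8)
})

test_that("pipeline stages are deterministic for identical inputs", {
  withr::local_seed(4)
  e <- random_epochs(n_trials = 4)
  r1 <- average_epochs(baseline_correct(to_average_reference(e)))
  r2 <- average_epochs(baseline_correct(to_average_reference(e)))
  expect_identical(r1$data, r2$data)
})
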