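# Component marking, stability gating, responder rate, time windows.

gauss_trace <- function(time, peaks) {
  # peaks: list of c(latency, amplitude, sd)
  Reduce(`+`, lapply(peaks, function(p) p[2] * exp(-(time - p[1])^2 / (2 * p[3]^2))))
}

test_that("windowed extrema land on programmed peaks", {
  time <- seq(-100, 600, by = 2)
  tr <- gauss_trace(time, list(c(60, 1, 8), c(115, -2, 10), c(250, 2, 20)))
  mk <- detect_markers(tr, time)
  expect_equal(mk$latency_ms, c(60, 115, 250), tolerance = 2) # within one sample
  expect_equal(mk$amplitude_uv, c(1, -2, 2), tolerance = 0.05)
  p2p <- attr(mk, "peak_to_peak")
  expect_equal(unname(p2p["P1N1"]), mk$amplitude_uv[1] - mk$amplitude_uv[2])
  expect_gt(p2p["P1N1"], 0)
  expect_lt(mk$amplitude_uv[mk$component == "N1"],
    mk$amplitude_uv[mk$component == "P1"])
})

test_that("flat traces tie-break to the window start; windows must be covered", {
  time <- seq(-100, 600, by = 2)
  mk <- detect_markers(rep(0, length(time)), time)
  expect_equal(mk$amplitude_uv, c(0, 0, 0))
  expect_equal(mk$latency_ms, c(40, 80, 186)) # first sample inside each window
  expect_error(
    detect_markers(rep(0, 5), c(0, 1, 2, 3, 4)),
    "outside the trace"
  )
})

test_that("stability gate behaves on identical, inverted and null traces", {
  time <- seq(-100, 600, by = 2)
  tr <- gauss_trace(time, list(c(115, -2, 10)))
  expect_equal(stability(tr, tr, time)$r, 1)
  expect_true(stability(tr, tr, time)$stable)
  st <- stability(tr, -tr, time)
  expect_equal(st$r, -1)
  expect_false(st$stable)
})

test_that("null stability rate matches the analytic correlation null", {
  # white-noise pairs over a 12-sample window: P(r >= 0.5) from the exact
  # t transform of the null correlation distribution
  n <- 12
  t0 <- 0.5 * sqrt(n - 2) / sqrt(1 - 0.25)
  p_true <- stats::pt(t0, df = n - 2, lower.tail = FALSE)
  withr::local_seed(17)
  time <- seq_len(n)
  hits <- sum(vapply(seq_len(1000), function(i) {
    stability(rnorm(n), rnorm(n), time, window_ms = c(1, n))$stable
  }, TRUE))
  se <- sqrt(1000 * p_true * (1 - p_true))
  expect_lt(abs(hits - 1000 * p_true), 4 * se)
})

test_that("responder rate counts stable, fully marked recordings", {
  expect_equal(responder_rate(data.frame(stable = c(TRUE, TRUE, TRUE, FALSE))), 75)
  expect_error(responder_rate(data.frame(stable = logical())), "no recordings")
  withr::local_seed(23)
  flags <- data.frame(stable = runif(200) > 0.4, marked = runif(200) > 0.1)
  expect_equal(
    responder_rate(flags),
    100 * mean(flags$stable & flags$marked)
  )
  lst <- list(list(stable = TRUE), list(stable = FALSE, marked = TRUE))
  expect_equal(responder_rate(lst), 50)
})

test_that("mean +/- 2 SD windows match hand arithmetic and degenerate rules", {
  w <- windows_mean2sd(c(90, 110))
  expect_equal(unname(w), c(100 - 2 * sqrt(200), 100 + 2 * sqrt(200)), tolerance = 1e-9)
  expect_equal(unname(w), c(71.7, 128.3), tolerance = 0.02)
  expect_warning(wd <- windows_mean2sd(c(100, 100, 100), dt_ms = 2), "degenerate")
  expect_equal(unname(wd), c(98, 102))
  # grid rounding is outward
  wg <- windows_mean2sd(c(90, 110), dt_ms = 4)
  expect_lte(wg[1], 71.7)
  expect_gte(wg[2], 128.3)
  expect_equal(unname(wg[1]) %% 4, 0)
})

test_that("2 SD windows cover ~95% of normally jittered latencies", {
  withr::local_seed(29)
  lat <- rnorm(200, 115, 7)
  w <- windows_mean2sd(lat)
  expect_equal(unname(w[1]), 101, tolerance = 3)
  expect_equal(unname(w[2]), 129, tolerance = 3)
  expect_gte(mean(lat >= w[1] & lat <= w[2]), 0.93)
})

test_that("GFP windows bracket two-bump curves; inflection nests inside minima", {
  time <- seq(-100, 600, by = 2)
  g <- gauss_trace(time, list(c(115, 2, 18), c(260, 1.6, 30))) + 0.05
  wm <- windows_from_gfp(g, time, mode = "minima")
  wi <- windows_from_gfp(g, time, mode = "inflection")
  expect_equal(wm$component, c("N1", "P2"))
  # windows contain the bumps, centers within +/- 5 ms
  expect_equal(wm$peak_ms, c(115, 260), tolerance = 5)
  expect_true(wm$start_ms[1] < 115 && wm$end_ms[1] > 115)
  expect_true(wm$start_ms[2] < 260 && wm$end_ms[2] > 260)
  # inflection windows strictly nested inside the minima windows
  expect_true(all(wi$start_ms >= wm$start_ms))
  expect_true(all(wi$end_ms <= wm$end_ms))
  expect_true(all(wi$end_ms - wi$start_ms < wm$end_ms - wm$start_ms))
  # analytic check: Gaussian inflections sit one SD from the peak
  expect_equal(wi$start_ms[1], 115 - 18, tolerance = 4)
  expect_equal(wi$end_ms[1], 115 + 18, tolerance = 4)
})

test_that("monotone GFP curves raise a detection failure naming the findings", {
  time <- seq(0, 600, by = 2)
  expect_error(
    windows_from_gfp(seq_along(time) * 0.01, time),
    "detection failed"
  )
})
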