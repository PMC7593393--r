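# Synthetic SEP generator: construction rules, determinism, recovery.

small_cfg <- function(...) {
  generator_config(
    montage = standard_montage("10-20-20"), n_subjects = 3,
    frequencies = c("0.5 Hz", "1.1 Hz", "1.6 Hz"), trials = 4,
    sampling_rate = 125, epoch_window_ms = c(-100, 400), ...
  )
}

test_that("default components encode the programmed SEP morphology", {
  comps <- make_component_defaults()
  names(comps) <- vapply(comps, `[[`, "", "name")
  m <- standard_montage("10-10-64")
  # N1: negativity over the centro-parietal midline, frontal positivity
  n1 <- component_pattern(comps$N1, m)
  expect_lt(n1[m$label == "Cz"], 0)
  expect_lt(n1[m$label == "CPz"], 0)
  expect_gt(n1[m$label == "Fp1"], 0)
  expect_gt(n1[m$label == "Fp2"], 0)
  # P2: central positivity with surrounding negativity
  p2 <- component_pattern(comps$P2, m)
  expect_gt(p2[m$label == "Cz"], 0)
  expect_lt(p2[m$label == "T7"], 0)
  # every pattern is average-reference compatible
  for (cp in comps) {
    expect_lt(abs(mean(component_pattern(cp, m))), 1e-9)
  }
  # condition multipliers decrease with stimulation frequency
  for (cp in comps) {
    mlt <- cp$condition_multipliers
    expect_true(all(diff(mlt) < 0))
    expect_equal(names(mlt), c("0.5 Hz", "1.1 Hz", "1.6 Hz"))
  }
  # programmed latencies: P1 before N1 before P2
  expect_lt(comps$P1$latency_ms, comps$N1$latency_ms)
  expect_lt(comps$N1$latency_ms, comps$P2$latency_ms)
})

test_that("the generator is deterministic given the seed", {
  cfg <- small_cfg()
  a <- simulate_sep(cfg, seed = 5)
  b <- simulate_sep(cfg, seed = 5)
  expect_identical(a$epochs[[1]]$data, b$epochs[[1]]$data)
  expect_identical(a$truth, b$truth)
  c <- simulate_sep(cfg, seed = 6)
  expect_false(identical(a$epochs[[1]]$data, c$epochs[[1]]$data))
})

test_that("noise-free grand-average GFP is ordered by the frequency multipliers", {
  cfg <- small_cfg(noise_sd = 0)
  ds <- simulate_sep(cfg, seed = 9)
  g <- vapply(cfg$frequencies, function(f) {
    ga <- grand_average(ds, frequency = f)
    gfp(ga)[which.min(abs(ga$time - 115))]
  }, 0)
  expect_true(g[["0.5 Hz"]] > g[["1.1 Hz"]])
  expect_true(g[["1.1 Hz"]] > g[["1.6 Hz"]])
})

test_that("the trial mean converges to the programmed signal (3 SE channel-wise)", {
  cfg <- generator_config(
    montage = standard_montage("10-20-20"), n_subjects = 1,
    frequencies = "0.5 Hz", trials = 10000, sampling_rate = 100,
    epoch_window_ms = c(-100, 200), noise_sd = 1
  )
  comps <- make_component_defaults("0.5 Hz")
  ds <- simulate_sep(cfg, comps, seed = 10)
  e <- ds$epochs[[1]]
  emp <- apply(e$data, c(2, 3), mean)
  # reconstruct the programmed expectation from the serialized ground truth
  truth <- ds$truth
  signal <- matrix(0, 20, length(e$time))
  for (i in seq_len(nrow(truth))) {
    cp <- comps[[which(vapply(comps, `[[`, "", "name") == truth$component[i])]]
    signal <- signal + truth$amplitude[i] *
      component_pattern(cp, cfg$montage) %o%
        component_profile(cp, e$time, latency_ms = truth$latency_ms[i])
  }
  se <- 1 / sqrt(10000) # per-channel noise SD / sqrt(trials)
  frac_in <- mean(abs(emp - signal) <= 3 * se)
  expect_gte(frac_in, 0.99)
  expect_lt(max(abs(emp - signal)), 5 * se)
})

test_that("null datasets carry no condition signal; noise-only has no topography", {
  cfg <- small_cfg(noise_sd = 0)
  ds <- null_dataset(cfg, seed = 3)
  g1 <- grand_average(ds, frequency = "0.5 Hz")
  g2 <- grand_average(ds, frequency = "1.6 Hz")
  expect_equal(g1$data, g2$data, tolerance = 1e-12)
  dn <- null_dataset(small_cfg(), components = NULL, seed = 4)
  ev <- average_epochs(dn$epochs[[1]])
  expect_lt(max(abs(ev$data)), 3) # pure noise, no microvolt-scale structure
  expect_identical(
    null_dataset(cfg, seed = 11)$epochs[[2]]$data,
    null_dataset(cfg, seed = 11)$epochs[[2]]$data
  )
})

test_that("evoked N1 latency is recovered within 3 ms at n = 20", {
  cfg <- generator_config(
    montage = standard_montage("10-20-20"), n_subjects = 20,
    frequencies = "0.5 Hz", trials = 40, sampling_rate = 250,
    epoch_window_ms = c(-100, 300), noise_sd = 1
  )
  ds <- simulate_sep(cfg, make_component_defaults("0.5 Hz"), seed = 12)
  ga <- grand_average(ds, average_reference = FALSE)
  tr <- difference_channel(ga, "Cz", "Fz")
  win <- tr$time_ms >= 80 & tr$time_ms <= 170
  peak <- tr$time_ms[win][which.min(tr$value[win])]
  expect_lt(abs(peak - 115), 3 + 1e-9)
})

test_that("evoked_stack produces average-referenced design-ready arrays", {
  cfg <- small_cfg()
  ds <- simulate_sep(cfg, seed = 21)
  stk <- evoked_stack(ds)
  expect_identical(dim(stk$maps), c(3L, 3L, 20L, length(stk$time)))
  expect_true(all(abs(apply(stk$maps, c(1, 2, 4), mean)) < 1e-9))
  expect_equal(stk$design$within, cfg$frequencies)
})
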