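# GFP identities, randomization tests, oracle equivalence, t-maps.

test_that("GFP obeys its defining identities", {
  expect_equal(gfp(c(1, -1)), 1)
  expect_equal(gfp(rep(4.2, 8)), 0)
  expect_equal(gfp(c(3, -1, -1, -1)), sqrt(3), tolerance = 1e-12)
  expect_equal(gfp(c(3, -1, -1, -1)), 1.7321, tolerance = 1e-4)
  # equality with an independent SD computation on random maps
  withr::local_seed(31)
  for (i in 1:25) {
    v <- rnorm(sample(4:64, 1))
    expect_equal(gfp(v), sqrt(sum((v - mean(v))^2) / length(v)), tolerance = 1e-12)
  }
  # invariance to adding a constant to all channels
  v <- rnorm(16)
  expect_equal(gfp(v + 100), gfp(v), tolerance = 1e-9)
  expect_error(gfp(3), "at least 2")
})

test_that("map normalization yields unit GFP and rejects flat maps", {
  expect_equal(normalize_map(c(2, -2)), c(1, -1))
  withr::local_seed(37)
  for (i in 1:10) {
    v <- rnorm(12)
    expect_equal(gfp(normalize_map(v)), 1, tolerance = 1e-12)
  }
  expect_error(normalize_map(rep(1, 5)), "near-zero GFP")
})

test_that("randomized TANOVA equals exhaustive enumeration on a 4-subject toy", {
  withr::local_seed(41)
  maps <- random_maps(n = 4, L = 2, K = 6, T = 1)
  oracle <- oracle_tanova_2cond(maps[, , , 1])
  res <- tanova(maps, design_spec(within = c("A", "B")), exact = TRUE)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_equal(res$effect, oracle$obs, tolerance = 1e-12)
  # and a second draw, to make sure it is not a coincidence of one dataset
  maps2 <- random_maps(n = 4, L = 2, K = 6, T = 1)
  expect_equal(
    tanova(maps2, design_spec(within = c("A", "B")), exact = TRUE)$p,
    oracle_tanova_2cond(maps2[, , , 1])$p,
    tolerance = 1e-12
  )
})

test_that("identical maps across conditions give zero effect and p = 1", {
  one <- matrix(rnorm(8 * 2), 8, 2)
  maps <- array(0, c(5, 2, 8, 2))
  for (s in 1:5) for (c in 1:2) maps[s, c, , ] <- one - rowMeans(one)[row(one) * 0 + 1] * 0
  maps <- sweep(maps, c(1, 2, 4), apply(maps, c(1, 2, 4), mean))
  res <- tanova(maps, design_spec(within = c("A", "B")), n_perm = 199, seed = 5)
  expect_true(all(res$effect < 1e-12))
  expect_true(all(res$p == 1))
})

test_that("orthogonal noise-free condition patterns give the smallest possible p", {
  # every permutation that actually mixes the two patterns lowers the
  # dissimilarity; only the identity and the global swap tie with the observed
  K <- 10
  a <- normalize_map(sin(seq_len(K)))
  b <- normalize_map(cos(seq_len(K) * 2))
  b <- normalize_map(b - a * sum(a * b) / sum(a * a)) # orthogonalize
  maps <- array(0, c(10, 2, K, 1))
  for (s in 1:10) {
    maps[s, 1, , 1] <- a
    maps[s, 2, , 1] <- b
  }
  res <- tanova(maps, design_spec(within = c("A", "B")), n_perm = 1999, seed = 7)
  expect_lte(res$p, 0.005)
  # the observed effect dominates every non-tied permutation
  expect_gt(res$effect, 0)
})

test_that("GFP test and TANOVA dissociate strength from topography", {
  withr::local_seed(43)
  K <- 12
  template <- normalize_map(rnorm(K))
  maps <- array(0, c(10, 2, K, 1))
  for (s in 1:10) {
    amp <- exp(rnorm(1, 0, 0.2))
    maps[s, 1, , 1] <- template * amp
    maps[s, 2, , 1] <- template * amp * 0.5
  }
  d <- design_spec(within = c("A", "B"))
  expect_lte(gfp_test(maps, d, n_perm = 999, seed = 3)$p, 0.05)
  expect_equal(tanova(maps, d, n_perm = 999, seed = 3)$p, 1) # pure scaling
  # and the converse invariances: tanova is scale invariant, gfp_test is not
  maps2 <- random_maps(n = 6, L = 2, K = K, T = 1)
  t1 <- tanova(maps2, d, n_perm = 199, seed = 9)
  t2 <- tanova(maps2 * 3, d, n_perm = 199, seed = 9)
  expect_equal(t1$p, t2$p)
  expect_equal(t1$effect, t2$effect, tolerance = 1e-9)
  g1 <- gfp_test(maps2, d, n_perm = 199, seed = 9)
  g2 <- gfp_test(maps2 * 3, d, n_perm = 199, seed = 9)
  expect_equal(g2$effect, 3 * g1$effect, tolerance = 1e-9)
})

test_that("between-subject and interaction factors are exercised", {
  withr::local_seed(47)
  K <- 10
  pat <- normalize_map(rnorm(K))
  maps <- random_maps(n = 8, L = 2, K = K, T = 1) * 0.2
  groups <- rep(c("g1", "g2"), each = 4)
  for (s in 5:8) for (c in 1:2) maps[s, c, , 1] <- maps[s, c, , 1] + 3 * pat
  d <- design_spec(within = c("A", "B"), between = groups)
  res <- tanova(maps, d, n_perm = 499, seed = 11)
  expect_setequal(unique(res$factor), c("within", "between", "interaction"))
  expect_lte(res$p[res$factor == "between"], 0.05)
  # the group separation dominates the (null) within-condition contrast
  expect_gt(res$effect[res$factor == "between"], res$effect[res$factor == "within"])
  expect_error(
    tanova(maps, design_spec(within = c("A", "B"), between = rep("g", 3))),
    "one group per subject"
  )
})

test_that("single-subject designs are rejected (no exchangeability)", {
  maps <- random_maps(n = 1, L = 2, K = 6, T = 1)
  expect_error(gfp_test(maps, design_spec(within = c("A", "B"))), "at least 2")
  expect_error(tct(array(rnorm(8), c(1, 8, 1))), "at least 2")
})

test_that("TCT: shared topography is detected, shuffling kills it", {
  withr::local_seed(53)
  K <- 8
  shared <- normalize_map(rnorm(K))
  maps <- array(rep(shared, each = 6), c(6, K, 1))
  res <- tct(maps, n_perm = 499, seed = 13)
  expect_equal(res$p, 1 / 500) # minimum attainable
  expect_equal(res$effect, 1, tolerance = 1e-9) # mean of identical unit maps
})

test_that("p values are reproducible bit-for-bit given (seed, n_perm)", {
  withr::local_seed(59)
  maps <- random_maps(n = 6, L = 3, K = 10, T = 2)
  d <- design_spec(within = c("a", "b", "c"))
  r1 <- tanova(maps, d, n_perm = 299, seed = 123)
  r2 <- tanova(maps, d, n_perm = 299, seed = 123)
  expect_identical(r1$p, r2$p)
  g1 <- gfp_test(maps, d, n_perm = 299, seed = 123)
  g2 <- gfp_test(maps, d, n_perm = 299, seed = 123)
  expect_identical(g1$p, g2$p)
  m3 <- array(rnorm(5 * 8 * 2), c(5, 8, 2))
  expect_identical(
    tct(m3, n_perm = 99, seed = 7)$p,
    tct(m3, n_perm = 99, seed = 7)$p
  )
})

test_that("t-maps match the textbook formulas and stats::t.test", {
  # hand-computed 3-subject paired example on one channel
  x <- matrix(c(2, 4, 9), 3, 1)
  y <- matrix(c(1, 1, 4), 3, 1)
  d <- c(1, 3, 5)
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  res <- t_map(x, y, paired = TRUE)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 2)
  # against stats::t.test on random multichannel data, paired and Welch
  withr::local_seed(61)
  X <- matrix(rnorm(40), 8, 5)
  Y <- matrix(rnorm(40, 0.5), 8, 5)
  tp <- t_map(X, Y, paired = TRUE)
  tw <- t_map(X, Y, paired = FALSE)
  for (ch in 1:5) {
    expect_equal(tp$t[ch], unname(t.test(X[, ch], Y[, ch], paired = TRUE)$statistic),
      tolerance = 1e-10
    )
    ref <- t.test(X[, ch], Y[, ch])
    expect_equal(tw$t[ch], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(tw$df[ch], unname(ref$parameter), tolerance = 1e-10)
  }
  # antisymmetry
  expect_equal(t_map(Y, X, paired = TRUE)$t, -tp$t)
  # identical data -> t = 0
  expect_equal(t_map(X, X, paired = FALSE)$t, rep(0, 5))
})

test_that("marker-locked statistics agree with the time-wise machinery", {
  withr::local_seed(67)
  maps <- random_maps(n = 5, L = 2, K = 8, T = 6)
  time <- seq(0, 100, by = 20)
  lat <- matrix(40, 5, 2) # everyone marked at 40 ms = sample 3
  d <- design_spec(within = c("A", "B"))
  res <- marker_statistics(maps, time, lat, d, n_perm = 199, seed = 3)
  direct_t <- tanova(maps[, , , 3, drop = FALSE], d, n_perm = 199, seed = 3)
  direct_g <- gfp_test(maps[, , , 3, drop = FALSE], d, n_perm = 199, seed = 3)
  expect_equal(res$p[res$test == "tanova"], direct_t$p)
  expect_equal(res$p[res$test == "gfp"], direct_g$p)
  # identical maps -> p = 1
  mm <- maps
  for (s in 1:5) for (c in 1:2) mm[s, c, , ] <- mm[1, 1, , ]
  res2 <- marker_statistics(mm, time, lat, d, n_perm = 99, seed = 4)
  expect_true(all(res2$p == 1))
})

test_that("significant intervals are extracted per factor", {
  x <- tibble::tibble(
    time_ms = rep(c(0, 10, 20, 30), 2),
    factor = rep(c("within", "between"), each = 4),
    effect = 1,
    p = c(0.2, 0.01, 0.01, 0.3, 0.5, 0.6, 0.01, 0.01)
  )
  class(x) <- c("sep_rand_test", class(x))
  iv <- significant_intervals(x)
  expect_equal(iv$start_ms[iv$factor == "within"], 10)
  expect_equal(iv$end_ms[iv$factor == "within"], 20)
  expect_equal(iv$start_ms[iv$factor == "between"], 20)
  expect_equal(iv$end_ms[iv$factor == "between"], 30)
})
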