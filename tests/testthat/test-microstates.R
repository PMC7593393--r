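# AAHC segmentation, cross-validated k, class-parameter comparison.

orth_templates <- function(K = 12, k = 3) {
  # mutually orthogonal mean-zero unit-GFP maps
  withr::local_seed(71)
  M <- matrix(rnorm(K * k), k, K)
  M <- M - rowMeans(M)
  M <- t(qr.Q(qr(t(M)))[, 1:k])
  M <- M - rowMeans(M)
  M / sqrt(rowMeans((M - rowMeans(M))^2))
}

test_that("AAHC recovers orthogonal template clusters perfectly", {
  tmpl <- orth_templates(K = 12, k = 3)
  withr::local_seed(73)
  maps <- tmpl[rep(1:3, each = 10), ] * runif(30, 0.5, 2) +
    matrix(rnorm(30 * 12, 0, 1e-4), 30, 12) # tiny jitter
  model <- aahc(maps, k_target = 3)
  expect_equal(model$k, 3)
  # label purity 100%
  expect_equal(length(unique(model$labels[1:10])), 1)
  expect_equal(length(unique(model$labels[11:20])), 1)
  expect_equal(length(unique(model$labels[21:30])), 1)
  expect_equal(length(unique(model$labels)), 3)
  # prototype-truth correlation >= 0.999
  for (i in 1:3) {
    proto <- model$prototypes[model$labels[(i - 1) * 10 + 1], ]
    expect_gte(sum(proto * tmpl[i, ]) / 12, 0.999)
  }
  expect_gte(model$gev, 0.999)
})

test_that("k = number of distinct maps gives GEV = 1", {
  tmpl <- orth_templates(K = 10, k = 4)
  maps <- tmpl[c(1, 2, 3, 4, 1, 2, 3, 4), ] * 2
  model <- aahc(maps, k_target = 4)
  expect_equal(model$gev, 1, tolerance = 1e-12)
  expect_error(aahc(maps, k_target = 9), "1\\.\\.8")
  expect_error(aahc(maps, k_target = 0), "1\\.\\.8")
})

test_that("the 2-channel 4-map case follows the hand trace", {
  # maps (1,-1), (2,-2), (-1,1), (-3,3): atomize the weakest singleton
  # (gfp 1), absorb it into (2,-2); then the (-1,1) singleton joins (-3,3).
  maps <- rbind(c(1, -1), c(2, -2), c(-1, 1), c(-3, 3))
  model <- aahc(maps, k_target = 2)
  expect_equal(model$labels[1], model$labels[2])
  expect_equal(model$labels[3], model$labels[4])
  expect_false(model$labels[1] == model$labels[3])
  # prototypes are the two unit polarities of the shared topography
  p1 <- model$prototypes[model$labels[1], ]
  expect_equal(p1, c(1, -1), tolerance = 1e-12)
  expect_equal(model$prototypes[model$labels[3], ], c(-1, 1), tolerance = 1e-12)
  expect_equal(model$gev, 1, tolerance = 1e-12)
})

test_that("GEV is non-decreasing in k on the same data", {
  withr::local_seed(79)
  maps <- matrix(rnorm(40 * 8), 40, 8)
  path <- aahc_path(maps, k_set = 2:10)
  gevs <- vapply(as.character(2:10), function(k) path[[k]]$gev, 0)
  expect_true(all(diff(gevs) >= -1e-12))
})

test_that("labels are invariant to global amplitude scaling", {
  withr::local_seed(83)
  maps <- matrix(rnorm(30 * 10), 30, 10)
  m1 <- aahc(maps, 4)
  m2 <- aahc(maps * 7.3, 4)
  expect_identical(m1$labels, m2$labels)
  expect_equal(m1$prototypes, m2$prototypes, tolerance = 1e-12)
})

test_that("polarity handling: sensitive splits sign flips, ignorant does not", {
  tmpl <- orth_templates(K = 10, k = 2)
  a <- tmpl[1, ]
  maps <- rbind(a, a, -a, -a)
  ms <- aahc(maps, k_target = 2, polarity = "sensitive")
  expect_equal(ms$labels[1], ms$labels[2])
  expect_false(ms$labels[1] == ms$labels[3])
  mi <- aahc(maps, k_target = 1, polarity = "ignorant")
  expect_equal(mi$gev, 1, tolerance = 1e-12) # |corr| = 1 for both polarities
})

test_that("cross-validation picks the smallest k on degenerate flat curves", {
  a <- orth_templates(K = 10, k = 2)[1, ]
  subj <- replicate(6, {
    m <- matrix(rep(a, 12), 12, 10, byrow = TRUE)
    m * seq(0.8, 1.2, length.out = 12)
  }, simplify = FALSE)
  cv <- cross_validate_k(subj, k_grid = 2:4, n_repeats = 3, seed = 2)
  expect_equal(attr(cv, "chosen_k"), 2L)
  expect_true(all(abs(cv$mean_correlation - 1) < 1e-9))
  expect_error(cross_validate_k(subj[1:3], k_grid = 2:3), "at least 4")
  expect_error(cross_validate_k(subj, k_grid = 2:40), "time points")
})

test_that("cross-validation is reproducible and returns both curves", {
  withr::local_seed(89)
  tmpl <- orth_templates(K = 10, k = 3)
  subj <- replicate(8, {
    tmpl[rep(1:3, each = 8), ] * 3 + matrix(rnorm(24 * 10), 24, 10)
  }, simplify = FALSE)
  cv1 <- cross_validate_k(subj, k_grid = 2:5, n_repeats = 4, seed = 31)
  cv2 <- cross_validate_k(subj, k_grid = 2:5, n_repeats = 4, seed = 31)
  expect_identical(cv1$mean_correlation, cv2$mean_correlation)
  expect_identical(attr(cv1, "chosen_k"), attr(cv2, "chosen_k"))
  expect_true(all(c("mean_correlation", "assignment_correlation") %in% names(cv1)))
})

test_that("class assignment and parameter tests behave on constructed conditions", {
  tmpl <- orth_templates(K = 10, k = 2)
  Tn <- 20
  series <- rbind(
    tmpl[rep(1, 10), ] * 2,
    tmpl[rep(2, 10), ] * 2
  )
  time <- seq(25, 500, length.out = Tn)
  n <- 8
  maps <- array(0, c(n, 2, 10, Tn))
  withr::local_seed(97)
  for (s in seq_len(n)) {
    jit <- matrix(rnorm(Tn * 10, 0, 0.05), Tn, 10)
    maps[s, 1, , ] <- t(series + jit)
    maps[s, 2, , ] <- t((series + jit) * 0.5) # condition B: pure scaling
  }
  model <- aahc(series, k_target = 2)
  d <- design_spec(within = c("A", "B"))
  res <- assign_and_compare(model, maps, time,
    window_ms = c(20, 600),
    design = d, n_perm = 199, seed = 3
  )
  # identical label sequences, so durations match across conditions
  dur <- tidyr::pivot_wider(
    dplyr::distinct(res$parameters[, c("condition", "class", "duration_ms")]),
    names_from = "condition", values_from = "duration_ms"
  )
  expect_equal(dur$A, dur$B)
  # mean GFP per class differs strongly between conditions
  pg <- res$tests[res$tests$parameter == "mean_gfp", ]
  expect_true(all(pg$p <= 0.05))
  pd <- res$tests[res$tests$parameter == "duration_ms", ]
  expect_true(all(pd$p == 1)) # no duration differences at all
  expect_error(
    assign_and_compare(model, maps, time, window_ms = c(700, 900), design = d),
    "window"
  )
})

test_that("identical conditions yield p = 1 for every class parameter", {
  tmpl <- orth_templates(K = 8, k = 2)
  series <- rbind(tmpl[rep(1, 8), ], tmpl[rep(2, 8), ]) * 2
  time <- seq(25, 500, length.out = 16)
  maps <- array(0, c(5, 2, 8, 16))
  for (s in 1:5) for (c in 1:2) maps[s, c, , ] <- t(series)
  model <- aahc(series, k_target = 2)
  res <- assign_and_compare(model, maps, time,
    design = design_spec(within = c("A", "B")), n_perm = 99, seed = 1
  )
  expect_true(all(res$tests$p == 1))
})

test_that("microstate models serialize to JSON and back", {
  withr::local_seed(101)
  model <- aahc(matrix(rnorm(20 * 8), 20, 8), k_target = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_microstates_json(model, path)
  m2 <- read_microstates_json(path)
  expect_equal(m2$k, model$k)
  expect_equal(m2$prototypes, model$prototypes, tolerance = 1e-12)
  expect_identical(as.integer(m2$labels), as.integer(model$labels))
  expect_equal(m2$gev, model$gev, tolerance = 1e-12)
})
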