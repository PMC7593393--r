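# Reference-independent map strength (GFP) and randomization inference:
# GFP condition test, TANOVA, topographic consistency test, channel t-maps.
#
# Effect size convention: "generalized dissimilarity", the sum over factor
# levels of the GFP of (level mean map - grand mean map). p values use the
# +1/+1 convention, p = (#{null >= observed} + 1) / (n_perm + 1), so p is
# never 0 and its minimum is 1/(n_perm + 1).

#' Global field power
#'
#' The spatial standard deviation of a map (population divisor), equal to the
#' root mean square of the voltages once the map is average referenced.
#'
#' @param x Numeric map vector, a channels x samples matrix, or a
#'   `sep_evoked` (per-sample GFP over its channels).
#' @return A single value for a vector, else a per-sample numeric vector.
#' @export
gfp <- function(x) {
  if (inherits(x, "sep_evoked")) x <- x$data
  if (is.null(dim(x))) {
    if (length(x) < 2) abort("GFP needs at least 2 channels")
    return(pop_sd(x))
  }
  if (nrow(x) < 2) abort("GFP needs at least 2 channels")
  cm <- colMeans(x)
  sqrt(pmax(0, colMeans(x^2) - cm^2))
}

#' GFP curve of an evoked series
#'
#' @param evoked A `sep_evoked`.
#' @return Tibble with columns `time_ms`, `gfp`.
#' @export
gfp_curve <- function(evoked) {
  tibble(time_ms = evoked$time, gfp = gfp(evoked))
}

#' Normalize a map to unit GFP
#'
#' @param map Numeric map vector.
#' @param eps Maps with GFP below `eps` cannot be normalized.
#' @return The map divided by its GFP.
#' @export
normalize_map <- function(map, eps = 1e-12) {
  g <- gfp(map)
  if (g <= eps) abort("cannot normalize a map with near-zero GFP")
  map / g
}

#' Design specification for randomization tests
#'
#' @param within Character vector naming the within-subject factor levels
#'   (e.g. the three stimulation frequencies), matching the condition
#'   dimension of the data; `NULL` when there is no within factor.
#' @param between Factor (or character) of length `n_subjects` assigning each
#'   subject to a group (e.g. stimulation location); `NULL` for a single
#'   group.
#' @param n_perm Default number of randomization runs (5000).
#' @param seed Default RNG seed for the randomization.
#' @return A `design_spec` list.
#' @export
design_spec <- function(within = NULL, between = NULL, n_perm = 5000,
                        seed = NULL) {
  if (!is.null(between)) between <- as.factor(between)
  structure(
    list(
      within = within, between = between,
      n_perm = as.integer(n_perm), seed = seed
    ),
    class = "design_spec"
  )
}

# --- internal helpers -------------------------------------------------------

# Validate a subject x condition x channel x time array against a design.
.check_maps <- function(maps, design) {
  d <- dim(maps)
  if (length(d) != 4) {
    abort("`maps` must be a subject x condition x channel x time array")
  }
  if (!is.null(design$within) && length(design$within) != d[2]) {
    abort("length of design$within must equal the condition dimension")
  }
  if (!is.null(design$between)) {
    if (length(design$between) != d[1]) {
      abort("design$between must give one group per subject")
    }
    if (any(table(design$between) == 0)) abort("empty between-factor group")
  }
  if (d[1] < 2) abort("randomization tests need at least 2 subjects")
  d
}

# Normalize each (subject, condition, time) map to unit GFP.  Near-zero-GFP
# maps are left untouched and counted; callers report the count.
.normalize_maps4 <- function(maps, eps = 1e-12) {
  d <- dim(maps)
  mu <- apply(maps, c(1, 2, 4), mean)
  g <- sqrt(pmax(0, apply(maps^2, c(1, 2, 4), mean) - mu^2))
  bad <- g <= eps
  g[bad] <- 1
  scale <- aperm(array(g, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(maps = maps / scale, n_dropped = sum(bad))
}

# Dissimilarity null distribution for a within-subject factor.
# R: (n*L) x (K*T) matrix, row s + (l-1)*n; returns list(obs, null) where
# null is n_perm x T.  When exact = TRUE all (L!)^n label assignments are
# enumerated instead (small designs only).
.rand_within <- function(R, n, L, K, T, n_perm, exact = FALSE,
                         chunk_target = 2e7) {
  GM <- colMeans(R)
  ptab <- all_permutations(L) # L! x L
  nfact <- nrow(ptab)

  level_effect <- function(idx_rows) {
    # idx_rows: P x n matrix of row indices for one level; returns P x T gfp
    P <- nrow(idx_rows)
    G <- R[as.vector(t(idx_rows)), , drop = FALSE]
    S <- rowsum(G, group = rep(seq_len(P), each = n), reorder = FALSE) / n
    E <- sweep(S, 2, GM)
    E2 <- array(E * E, c(P, K, T))
    sq <- colSums(aperm(E2, c(2, 1, 3))) # P x T sums over channels
    sqrt(sq / K)
  }

  obs <- 0
  for (l in seq_len(L)) {
    obs <- obs + level_effect(matrix(seq_len(n) + (l - 1) * n, nrow = 1))
  }

  if (exact) {
    if (nfact^n > 2e5) abort("exact enumeration too large; use random sampling")
    grid <- as.matrix(expand.grid(rep(list(seq_len(nfact)), n)))
    A <- grid # rows = assignments, cols = subjects, values = perm id
    n_perm_eff <- nrow(A)
  } else {
    A <- matrix(sample.int(nfact, n_perm * n, replace = TRUE), n_perm, n)
    n_perm_eff <- n_perm
  }

  null <- matrix(0, n_perm_eff, T)
  chunk <- max(1L, as.integer(chunk_target / (n * K * T)))
  starts <- seq(1L, n_perm_eff, by = chunk)
  subj_off <- seq_len(n)
  for (st in starts) {
    rows <- st:min(st + chunk - 1L, n_perm_eff)
    Ac <- A[rows, , drop = FALSE]
    acc <- 0
    for (l in seq_len(L)) {
      cond <- matrix(ptab[Ac, l], nrow(Ac), n) # original condition at level l
      idx <- matrix(rep(subj_off, each = nrow(Ac)), nrow(Ac), n) + (cond - 1) * n
      acc <- acc + level_effect(idx)
    }
    null[rows, ] <- acc
  }
  list(obs = drop(obs), null = null, n_perm = n_perm_eff, exact = exact)
}

# Dissimilarity null for a between-subject factor.  Y: n x (K*T) matrix of
# per-subject maps (collapsed over within levels); groups: factor length n.
.rand_between <- function(Y, groups, K, T, n_perm, chunk_target = 2e7) {
  n <- nrow(Y)
  GM <- colMeans(Y)
  glev <- levels(groups)
  pos <- split(seq_len(n), groups)

  group_effect <- function(subject_rows) {
    # subject_rows: P x n matrix; per perm the permuted subject order
    P <- nrow(subject_rows)
    acc <- 0
    for (g in glev) {
      members <- subject_rows[, pos[[g]], drop = FALSE]
      G <- Y[as.vector(t(members)), , drop = FALSE]
      S <- rowsum(G, group = rep(seq_len(P), each = ncol(members)), reorder = FALSE) /
        ncol(members)
      E <- sweep(S, 2, GM)
      E2 <- array(E * E, c(P, K, T))
      acc <- acc + sqrt(colSums(aperm(E2, c(2, 1, 3))) / K)
    }
    acc
  }

  obs <- group_effect(matrix(seq_len(n), nrow = 1))
  null <- matrix(0, n_perm, T)
  chunk <- max(1L, as.integer(chunk_target / (n * K * T)))
  for (st in seq(1L, n_perm, by = chunk)) {
    rows <- st:min(st + chunk - 1L, n_perm)
    Pm <- t(vapply(rows, function(i) sample.int(n), integer(n)))
    null[rows, ] <- group_effect(Pm)
  }
  list(obs = drop(obs), null = null, n_perm = n_perm, exact = FALSE)
}

.p_from_null <- function(obs, null, exact = FALSE, tol = 1e-12) {
  ge <- colSums(null >= matrix(obs - tol, nrow(null), length(obs), byrow = TRUE))
  if (exact) ge / nrow(null) else (ge + 1) / (nrow(null) + 1)
}

# Residualize maps for the interaction test: subtract subject-mean and
# level-mean maps (adding back the grand mean) before permuting within-subject
# labels.
.residualize4 <- function(maps) {
  d <- dim(maps)
  subj <- apply(maps, c(1, 3, 4), mean) # n x K x T
  lev <- apply(maps, c(2, 3, 4), mean) # L x K x T
  grand <- apply(maps, c(3, 4), mean) # K x T
  out <- maps
  for (l in seq_len(d[2])) {
    ml <- array(maps[, l, , , drop = FALSE], d[c(1, 3, 4)])
    lg <- array(lev[l, , ], c(d[3], d[4])) - grand
    out[, l, , ] <- ml - subj - aperm(
      array(lg, c(d[3], d[4], d[1])), c(3, 1, 2)
    )
  }
  out
}

# Shared skeleton for tanova() / gfp_test(): computes per-factor results.
.rand_factor_tests <- function(maps, design, factors, n_perm, seed, exact,
                               time, statistic = c("maps", "gfp", "scalar")) {
  statistic <- match.arg(statistic)
  d <- .check_maps(maps, design)
  n <- d[1]; L <- d[2]; K <- d[3]; T <- d[4]
  time <- time %||% seq_len(T)

  has_within <- !is.null(design$within) && L > 1
  has_between <- !is.null(design$between) && nlevels(design$between) > 1
  if (is.null(factors)) {
    factors <- c(
      if (has_within) "within",
      if (has_between) "between",
      if (has_within && has_between) "interaction"
    )
  }
  if (length(factors) == 0) abort("no testable factors in this design")

  if (statistic == "maps") {
    norm <- .normalize_maps4(maps)
    if (norm$n_dropped > 0) {
      inform(sprintf(
        "%d map(s) with near-zero GFP left unnormalized", norm$n_dropped
      ))
    }
    X <- norm$maps
    Keff <- K
  } else if (statistic == "gfp") {
    # scalar GFP per map; reuse the same machinery with a 1-channel "map"
    mu <- apply(maps, c(1, 2, 4), mean)
    g <- sqrt(pmax(0, apply(maps^2, c(1, 2, 4), mean) - mu^2))
    X <- array(g, c(n, L, 1, T))
    Keff <- 1L
  } else {
    # per-map scalar already supplied (class-parameter tests)
    if (K != 1) abort("statistic = 'scalar' expects a 1-channel array")
    X <- maps
    Keff <- 1L
  }

  run_factor <- function(fac) {
    if (fac == "within") {
      if (!has_within) abort("design has no within factor to test")
      R <- X
      dim(R) <- c(n * L, Keff * T)
      res <- .rand_within(R, n, L, Keff, T, n_perm, exact = exact)
    } else if (fac == "between") {
      if (!has_between) abort("design has no between factor to test")
      Y <- apply(X, c(1, 3, 4), mean) # collapse within levels
      dim(Y) <- c(n, Keff * T)
      res <- .rand_between(Y, design$between, Keff, T, n_perm)
    } else if (fac == "interaction") {
      if (!(has_within && has_between)) {
        abort("interaction requires both a within and a between factor")
      }
      Xr <- .residualize4(X)
      # effect: dissimilarity of cell means; permute within-subject labels
      res <- .rand_interaction(Xr, design$between, Keff, T, n_perm)
    } else {
      abort(sprintf("unknown factor '%s'", fac))
    }
    p <- .p_from_null(res$obs, res$null, exact = res$exact)
    tibble(
      time_ms = time, factor = fac,
      effect = as.numeric(res$obs), p = as.numeric(p)
    )
  }

  out <- dplyr::bind_rows(lapply(factors, run_factor))
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "exact") <- exact
  class(out) <- c("sep_rand_test", class(out))
  out
}

# Interaction: dissimilarity of residualized cell means over (level, group)
# cells, null from permuting within-subject labels of the residualized maps.
.rand_interaction <- function(Xr, groups, K, T, n_perm, chunk_target = 2e7) {
  d <- dim(Xr)
  n <- d[1]; L <- d[2]
  glev <- levels(groups)
  pos <- split(seq_len(n), groups)
  R <- Xr
  dim(R) <- c(n * L, K * T)
  ptab <- all_permutations(L)

  cell_effect <- function(A) {
    # A: P x n perm-id matrix (identity row = all 1s)
    P <- nrow(A)
    acc <- 0
    for (l in seq_len(L)) {
      cond <- matrix(ptab[A, l], P, n)
      for (g in glev) {
        sg <- pos[[g]]
        idx <- matrix(rep(sg, each = P), P, length(sg)) +
          (cond[, sg, drop = FALSE] - 1) * n
        G <- R[as.vector(t(idx)), , drop = FALSE]
        S <- rowsum(G, group = rep(seq_len(P), each = length(sg)), reorder = FALSE) /
          length(sg)
        E2 <- array(S * S, c(P, K, T)) # cell means of residuals, center ~ 0
        acc <- acc + sqrt(colSums(aperm(E2, c(2, 1, 3))) / K)
      }
    }
    acc
  }

  obs <- cell_effect(matrix(1L, 1, n))
  null <- matrix(0, n_perm, T)
  chunk <- max(1L, as.integer(chunk_target / (n * L * K * T)))
  for (st in seq(1L, n_perm, by = chunk)) {
    rows <- st:min(st + chunk - 1L, n_perm)
    A <- matrix(sample.int(nrow(ptab), length(rows) * n, replace = TRUE),
      length(rows), n
    )
    null[rows, ] <- cell_effect(A)
  }
  list(obs = drop(obs), null = null, n_perm = n_perm, exact = FALSE)
}

#' Topographic analysis of variance (TANOVA)
#'
#' Time-point-wise randomization test for topographic differences between
#' conditions or groups, independent of map strength: every map is
#' GFP-normalized, the effect size is the generalized dissimilarity (sum over
#' factor levels of the GFP of the level mean map minus the grand mean map),
#' and the null distribution is built by permuting condition labels within
#' subjects (within factors), subjects across groups (between factors), or
#' within-subject labels of subject- and level-mean-residualized maps
#' (interaction).
#'
#' @param maps Subject x condition x channel x time array of
#'   average-referenced maps, microvolts.
#' @param design A [design_spec()].
#' @param factors Which factors to test (`"within"`, `"between"`,
#'   `"interaction"`); default: all that the design supports.
#' @param n_perm Number of randomization runs.
#' @param seed RNG seed; results are bit-for-bit reproducible given
#'   `(seed, n_perm)`.
#' @param exact Enumerate all within-subject label assignments instead of
#'   sampling (small designs only; within factor only).
#' @param time Optional time axis (ms) for the result table.
#' @return A `sep_rand_test` tibble: `time_ms`, `factor`, `effect`, `p`.
#' @export
tanova <- function(maps, design, factors = NULL, n_perm = design$n_perm,
                   seed = design$seed, exact = FALSE, time = NULL) {
  with_seed(
    seed,
    .rand_factor_tests(maps, design, factors, n_perm, seed, exact, time,
      statistic = "maps"
    )
  )
}

#' GFP randomization test
#'
#' Same permutation schemes as [tanova()], but the statistic is computed on
#' the per-map GFP values (maps are deliberately NOT normalized -- map
#' strength is the tested quantity): sum over factor levels of the absolute
#' difference between the level mean GFP and the grand mean GFP.
#'
#' @inheritParams tanova
#' @return A `sep_rand_test` tibble.
#' @export
gfp_test <- function(maps, design, factors = NULL, n_perm = design$n_perm,
                     seed = design$seed, exact = FALSE, time = NULL) {
  with_seed(
    seed,
    .rand_factor_tests(maps, design, factors, n_perm, seed, exact, time,
      statistic = "gfp"
    )
  )
}

#' Topographic consistency test (TCT)
#'
#' Tests, per time point, whether subjects share a common scalp topography:
#' the observed statistic is the GFP of the mean of the subjects'
#' GFP-normalized maps; the null shuffles channel values independently within
#' each subject's map and recomputes.
#'
#' @param maps Subject x channel x time array (average-referenced).
#' @param n_perm Number of randomization runs.
#' @param seed RNG seed.
#' @param time Optional time axis (ms).
#' @return A `sep_rand_test` tibble with `factor = "consistency"`.
#' @export
tct <- function(maps, n_perm = 5000, seed = NULL, time = NULL) {
  d <- dim(maps)
  if (length(d) != 3) abort("`maps` must be a subject x channel x time array")
  n <- d[1]; K <- d[2]; T <- d[3]
  if (n < 2) abort("TCT needs at least 2 subjects")
  time <- time %||% seq_len(T)

  with_seed(seed, {
    obs <- numeric(T)
    pvals <- numeric(T)
    for (t in seq_len(T)) {
      D <- maps[, , t, drop = TRUE]
      if (n == 2 || K == 1) D <- matrix(D, n, K)
      g <- sqrt(pmax(0, rowMeans(D^2) - rowMeans(D)^2))
      ok <- g > 1e-12
      if (sum(ok) < 2) {
        obs[t] <- 0
        pvals[t] <- 1
        next
      }
      U <- D[ok, , drop = FALSE] / g[ok]
      m <- sum(ok)
      obs[t] <- pop_sd(colMeans(U))
      # all channel shuffles for all permutations at once
      P <- vapply(
        seq_len(n_perm * m), function(i) sample.int(K),
        integer(K)
      ) # K x (n_perm*m)
      subj <- rep(seq_len(m), times = n_perm)
      idx <- cbind(rep(subj, each = K), as.vector(P))
      V <- array(U[idx], c(K, m, n_perm))
      M <- colMeans(aperm(V, c(2, 1, 3))) # K x n_perm means over subjects
      nullg <- sqrt(pmax(0, colMeans(M^2) - colMeans(M)^2))
      pvals[t] <- (sum(nullg >= obs[t] - 1e-12) + 1) / (n_perm + 1)
    }
    out <- tibble(
      time_ms = time, factor = "consistency",
      effect = obs, p = pvals
    )
    attr(out, "n_perm") <- n_perm
    attr(out, "seed") <- seed
    class(out) <- c("sep_rand_test", class(out))
    out
  })
}

#' Channel-wise t-maps
#'
#' Descriptive per-channel t statistics between two conditions (paired) or
#' two groups (Welch unpaired), mirrored after routine SEP practice; no
#' multiplicity correction is applied.
#'
#' @param x,y Subject x channel matrices of window-mean (or peak) amplitudes
#'   for the two conditions/groups.
#' @param paired Paired t over subjects (`TRUE`) or Welch two-sample
#'   (`FALSE`).
#' @return Tibble with columns `channel`, `t`, `df`.
#' @export
t_map <- function(x, y, paired = TRUE) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (ncol(x) != ncol(y)) abort("`x` and `y` must have the same channels")
  channels <- colnames(x) %||% as.character(seq_len(ncol(x)))
  if (paired) {
    if (nrow(x) != nrow(y)) abort("paired t-maps require equal subject sets")
    d <- x - y
    n <- nrow(d)
    if (n < 2) abort("need >= 2 subjects")
    tv <- colMeans(d) / (apply(d, 2, stats::sd) / sqrt(n))
    df <- rep(n - 1, ncol(x))
  } else {
    n1 <- nrow(x); n2 <- nrow(y)
    if (n1 < 2 || n2 < 2) abort("need >= 2 subjects per group")
    v1 <- apply(x, 2, stats::var) / n1
    v2 <- apply(y, 2, stats::var) / n2
    tv <- (colMeans(x) - colMeans(y)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tibble(channel = channels, t = as.numeric(tv), df = as.numeric(df))
}

#' Randomization statistics at individually set marker latencies
#'
#' Extracts, per subject and condition, the single map at that subject's
#' component latency and runs [tanova()] and/or [gfp_test()] on the
#' resulting one-sample series -- the marker-locked counterpart of the
#' time-wise analyses.
#'
#' @param maps Subject x condition x channel x time array.
#' @param time Time axis of `maps`, ms.
#' @param latencies Subject x condition matrix of latencies (ms), e.g. from
#'   [detect_markers()] per recording; a vector is recycled across
#'   conditions.
#' @param design A [design_spec()].
#' @param tests Which tests to run: `"tanova"`, `"gfp"` or both.
#' @inheritParams tanova
#' @return A `sep_rand_test` tibble with one row per factor and test.
#' @export
marker_statistics <- function(maps, time, latencies, design,
                              tests = c("tanova", "gfp"), n_perm = design$n_perm,
                              seed = design$seed, exact = FALSE) {
  d <- .check_maps(maps, design)
  if (is.null(dim(latencies))) {
    latencies <- matrix(latencies, d[1], d[2])
  }
  picked <- array(0, c(d[1], d[2], d[3], 1))
  for (s in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      picked[s, c, , 1] <- maps[s, c, , which.min(abs(time - latencies[s, c]))]
    }
  }
  out <- list()
  if ("tanova" %in% tests) {
    r <- tanova(picked, design, n_perm = n_perm, seed = seed, exact = exact)
    r$test <- "tanova"
    out <- c(out, list(r))
  }
  if ("gfp" %in% tests) {
    r <- gfp_test(picked, design, n_perm = n_perm, seed = seed, exact = exact)
    r$test <- "gfp"
    out <- c(out, list(r))
  }
  res <- dplyr::bind_rows(out)
  res$time_ms <- NULL
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  class(res) <- c("sep_rand_test", class(res))
  res
}

#' Significant time intervals of a randomization test
#'
#' @param result A `sep_rand_test` with a `time_ms` column.
#' @param alpha Significance level.
#' @return Tibble with columns `factor`, `start_ms`, `end_ms`.
#' @export
significant_intervals <- function(result, alpha = 0.05) {
  if (!"time_ms" %in% names(result)) abort("result carries no time axis")
  result |>
    dplyr::group_by(.data$factor) |>
    dplyr::group_modify(function(df, key) {
      sig <- df$p <= alpha
      if (!any(sig)) {
        return(tibble(start_ms = numeric(), end_ms = numeric()))
      }
      r <- rle(sig)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- r$values
      tibble(start_ms = df$time_ms[starts[keep]], end_ms = df$time_ms[ends[keep]])
    }) |>
    dplyr::ungroup()
}
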