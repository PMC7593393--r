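# Microstate segmentation: atomize-and-agglomerate hierarchical clustering
# (AAHC), split-half cross-validated choice of the class count, and
# randomization-based comparison of class parameters across conditions.
#
# Spatial correlation between average-referenced maps is computed on
# unit-GFP maps as sum(u1 * u2) / K (the Pearson correlation with population
# scaling). Polarity-sensitive mode uses the signed correlation (evoked
# data: a negativity and a positivity are different states); polarity-
# ignorant mode uses |r| (resting-style use).

# Normalize rows of a time x channel matrix to zero mean / unit GFP.
# Rows with GFP <= eps are returned as zero rows and flagged.
.unit_maps <- function(M, eps = 1e-12) {
  ctr <- M - rowMeans(M)
  g <- sqrt(rowMeans(ctr^2))
  ok <- g > eps
  U <- ctr / pmax(g, eps)
  U[!ok, ] <- 0
  list(U = U, gfp = g, ok = ok)
}

# Prototype of a member set: normalized mean (sensitive) or first principal
# direction (ignorant) of the members' unit maps.
.prototype <- function(U_members, polarity) {
  if (polarity == "sensitive") {
    m <- colMeans(U_members)
  } else {
    m <- svd(U_members, nu = 0, nv = 1)$v[, 1]
  }
  ctr <- m - mean(m)
  g <- sqrt(mean(ctr^2))
  if (g <= 1e-12) {
    return(rep(0, length(m)))
  }
  ctr / g
}

#' Atomize-and-agglomerate hierarchical clustering (AAHC)
#'
#' Segments a time-ordered map sequence into `k_target` microstate classes:
#' every map starts as its own cluster; at each step the cluster contributing
#' least to the global explained variance (GEV) is atomized and its maps are
#' reassigned to the remaining cluster with the highest spatial correlation;
#' prototypes are recomputed after every step.
#'
#' @param maps Time x channel matrix of average-referenced maps (possibly
#'   concatenated condition grand averages), microvolts.
#' @param k_target Number of classes to keep (1 <= k <= number of maps).
#' @param polarity `"sensitive"` (signed correlation; default for evoked
#'   data) or `"ignorant"` (absolute correlation, principal-direction
#'   prototypes).
#' @return A `sep_microstates` object: `k`, `prototypes` (k x channels,
#'   unit GFP), `labels` (per time point), `gev`, `polarity`.
#' @export
aahc <- function(maps, k_target, polarity = c("sensitive", "ignorant")) {
  polarity <- match.arg(polarity)
  maps <- as.matrix(maps)
  path <- aahc_path(maps, k_set = k_target, polarity = polarity)
  path[[as.character(k_target)]]
}

#' AAHC solutions along the full merge path
#'
#' One hierarchical run yields the segmentation at every requested `k`
#' (used by the cross-validation, which needs all of `k_grid` at once).
#'
#' @inheritParams aahc
#' @param k_set Integer vector of class counts to snapshot.
#' @return Named list of `sep_microstates`, one per requested `k`.
#' @export
aahc_path <- function(maps, k_set, polarity = c("sensitive", "ignorant")) {
  polarity <- match.arg(polarity)
  maps <- as.matrix(maps)
  Tn <- nrow(maps)
  K <- ncol(maps)
  k_set <- sort(unique(as.integer(k_set)), decreasing = TRUE)
  if (any(k_set < 1) || any(k_set > Tn)) {
    abort(sprintf("k_target must lie in 1..%d (number of maps)", Tn))
  }
  um <- .unit_maps(maps)
  U <- um$U
  W <- um$gfp
  totW2 <- sum(W^2)
  if (totW2 <= 0) abort("all maps have zero GFP")

  corr_to <- function(proto, idx) as.vector(U[idx, , drop = FALSE] %*% proto) / K
  fit_r <- function(r) if (polarity == "ignorant") abs(r) else r

  members <- as.list(seq_len(Tn))
  protos <- U
  out <- list()

  snapshot <- function(members, protos) {
    labels <- integer(Tn)
    for (i in seq_along(members)) labels[members[[i]]] <- i
    r <- vapply(seq_len(Tn), function(t) {
      fit_r(sum(U[t, ] * protos[labels[t], ]) / K)
    }, 0)
    structure(
      list(
        k = length(members), prototypes = protos, labels = labels,
        gev = sum((W * r)^2) / totW2, polarity = polarity,
        gfp = W
      ),
      class = "sep_microstates"
    )
  }

  repeat {
    k_now <- length(members)
    if (k_now %in% k_set) out[[as.character(k_now)]] <- snapshot(members, protos)
    if (k_now <= min(k_set)) break
    contrib <- vapply(seq_along(members), function(i) {
      mm <- members[[i]]
      r <- fit_r(corr_to(protos[i, ], mm))
      sum((W[mm] * r)^2)
    }, 0)
    worst <- which.min(contrib)
    freed <- members[[worst]]
    members <- members[-worst]
    protos <- protos[-worst, , drop = FALSE]
    for (t in freed) {
      r <- fit_r(as.vector(protos %*% U[t, ]) / K)
      j <- which.max(r)
      members[[j]] <- c(members[[j]], t)
    }
    for (i in seq_along(members)) {
      protos[i, ] <- .prototype(U[members[[i]], , drop = FALSE], polarity)
    }
  }
  out
}

#' @export
print.sep_microstates <- function(x, ...) {
  cat(sprintf(
    "<sep_microstates> k = %d, GEV = %.3f, polarity-%s\n",
    x$k, x$gev, x$polarity
  ))
  invisible(x)
}

# Best-matching assignment of one map series to a prototype set.
# Returns list(label, r): per-row winning prototype and its fit correlation.
.assign_maps <- function(maps, prototypes, polarity, eps = 1e-12) {
  um <- .unit_maps(maps, eps)
  R <- um$U %*% t(prototypes) / ncol(maps)
  Rf <- if (polarity == "ignorant") abs(R) else R
  lab <- max.col(Rf, ties.method = "first")
  r <- Rf[cbind(seq_len(nrow(Rf)), lab)]
  lab[!um$ok] <- NA_integer_
  r[!um$ok] <- NA_real_
  list(label = lab, r = r, gfp = um$gfp)
}

# Mean correlation of two optimally matched prototype sets (one-to-one).
# Exhaustive matching for k <= 7, greedy otherwise.
.match_corr <- function(PA, PB, polarity) {
  k <- nrow(PA)
  R <- PA %*% t(PB) / ncol(PA)
  if (polarity == "ignorant") R <- abs(R)
  if (k <= 7) {
    pm <- all_permutations(k)
    best <- -Inf
    for (i in seq_len(nrow(pm))) {
      s <- mean(R[cbind(seq_len(k), pm[i, ])])
      if (s > best) best <- s
    }
    best
  } else {
    tot <- 0
    Rw <- R
    for (i in seq_len(k)) {
      w <- which(Rw == max(Rw), arr.ind = TRUE)[1, ]
      tot <- tot + Rw[w[1], w[2]]
      Rw[w[1], ] <- -Inf
      Rw[, w[2]] <- -Inf
    }
    tot / k
  }
}

#' Cross-validated choice of the microstate class count
#'
#' For each of `n_repeats` random half-splits of the subjects, AAHC models
#' with every `k` in `k_grid` are fitted to the two halves' grand-average
#' series and the two prototype sets are compared by their mean spatial
#' correlation under the best one-to-one matching; the chosen `k` maximizes
#' the repeat-mean correlation (split-half reproducibility). Ties break
#' toward the smaller `k` (parsimony). An odd subject count drops one random
#' subject per repeat so the halves stay equal. The assignment-based
#' correlation (mean best-fit correlation of one half's time points to the
#' other half's prototypes) is reported alongside for reference; it is
#' non-decreasing in `k` by construction and therefore not used for
#' selection.
#'
#' @param subject_maps List with one time x channel matrix per subject (same
#'   dimensions; concatenate condition grand averages beforehand if needed).
#' @param k_grid Candidate class counts (default 3..20).
#' @param n_repeats Number of random half-splits (default 50).
#' @param seed RNG seed.
#' @param polarity Passed to [aahc()].
#' @return A `sep_cv` tibble (`k`, `mean_correlation`,
#'   `assignment_correlation`) with attributes `chosen_k`, `n_repeats`,
#'   `seed` and the per-repeat correlation matrix.
#' @export
cross_validate_k <- function(subject_maps, k_grid = 3:20, n_repeats = 50,
                             seed = NULL,
                             polarity = c("sensitive", "ignorant")) {
  polarity <- match.arg(polarity)
  n <- length(subject_maps)
  if (n < 4) abort("cross-validation needs at least 4 subjects")
  Tn <- nrow(subject_maps[[1]])
  if (max(k_grid) > Tn) abort("k_grid exceeds the number of time points")
  half <- n %/% 2

  with_seed(seed, {
    rep_corr <- matrix(NA_real_, n_repeats, length(k_grid))
    rep_assign <- matrix(NA_real_, n_repeats, length(k_grid))
    for (r in seq_len(n_repeats)) {
      idx <- sample(n) # odd n: the last subject is left out this repeat
      A <- idx[seq_len(half)]
      B <- idx[half + seq_len(half)]
      GA <- Reduce(`+`, subject_maps[A]) / half
      GB <- Reduce(`+`, subject_maps[B]) / half
      pa <- aahc_path(GA, k_set = k_grid, polarity = polarity)
      pb <- aahc_path(GB, k_set = k_grid, polarity = polarity)
      for (ki in seq_along(k_grid)) {
        PA <- pa[[as.character(k_grid[ki])]]$prototypes
        PB <- pb[[as.character(k_grid[ki])]]$prototypes
        rep_corr[r, ki] <- .match_corr(PA, PB, polarity)
        rep_assign[r, ki] <- mean(.assign_maps(GB, PA, polarity)$r, na.rm = TRUE)
      }
    }
    mc <- colMeans(rep_corr)
    # ties (within numerical noise) break toward the smaller k (parsimony)
    chosen <- k_grid[which(mc >= max(mc) - 1e-9)[1]]
    out <- tibble(
      k = as.integer(k_grid), mean_correlation = mc,
      assignment_correlation = colMeans(rep_assign)
    )
    attr(out, "chosen_k") <- chosen
    attr(out, "n_repeats") <- n_repeats
    attr(out, "seed") <- seed
    attr(out, "repeat_correlations") <- rep_corr
    class(out) <- c("sep_cv", class(out))
    out
  })
}

#' Assign microstate classes to conditions and compare their parameters
#'
#' Labels every time point of each subject x condition map series with the
#' best-fitting prototype of a fitted model (inside an analysis window,
#' default 20-600 ms), derives per class and condition the occurrence
#' parameters -- onset, offset, duration, mean GFP and GFP-weighted
#' occurrence (the share of total GFP spent in the class) -- and tests
#' condition differences in duration, mean GFP and occurrence with the same
#' within-/between-subject permutation schemes as the topographic tests.
#' Maps with near-zero GFP inside the window are left unassigned.
#'
#' @param model A `sep_microstates` from [aahc()].
#' @param maps Subject x condition x channel x time array.
#' @param time Time axis of `maps`, ms.
#' @param window_ms Analysis window, ms.
#' @param design A [design_spec()].
#' @param n_perm,seed Randomization settings.
#' @return List with `parameters` (tibble: subject, condition, class, onset,
#'   offset, duration, mean_gfp, occurrence), `grand_labels` (tibble of the
#'   per-condition grand-average label sequence with GFP, for plotting the
#'   class time courses), and `tests` (a `sep_rand_test`: class x parameter
#'   x factor effects and p values).
#' @export
assign_and_compare <- function(model, maps, time, window_ms = c(20, 600),
                               design, n_perm = design$n_perm,
                               seed = design$seed) {
  d <- .check_maps(maps, design)
  widx <- which(time >= window_ms[1] & time <= window_ms[2])
  if (length(widx) == 0) abort("analysis window lies outside the map series")
  dt <- time_step(time)
  n <- d[1]; L <- d[2]; k <- model$k
  cond_names <- design$within %||% as.character(seq_len(L))

  par_rows <- vector("list", n * L)
  ii <- 0
  for (s in seq_len(n)) {
    for (cc in seq_len(L)) {
      M <- t(maps[s, cc, , widx]) # time x channel
      asg <- .assign_maps(M, model$prototypes, model$polarity)
      ii <- ii + 1
      par_rows[[ii]] <- dplyr::bind_rows(lapply(seq_len(k), function(cl) {
        sel <- which(!is.na(asg$label) & asg$label == cl)
        tibble(
          subject = s, condition = cond_names[cc], class = cl,
          onset_ms = if (length(sel)) time[widx[min(sel)]] else NA_real_,
          offset_ms = if (length(sel)) time[widx[max(sel)]] else NA_real_,
          duration_ms = length(sel) * dt,
          mean_gfp = if (length(sel)) mean(asg$gfp[sel]) else 0,
          occurrence = sum(asg$gfp[sel]) / sum(asg$gfp)
        )
      }))
    }
  }
  params <- dplyr::bind_rows(par_rows)

  # per-condition grand-average label time course (for plotting)
  grand_rows <- lapply(seq_len(L), function(cc) {
    G <- apply(maps[, cc, , , drop = FALSE], c(3, 4), mean)
    asg <- .assign_maps(t(G[, widx]), model$prototypes, model$polarity)
    tibble(
      condition = cond_names[cc], time_ms = time[widx],
      class = asg$label, gfp = asg$gfp, fit_r = asg$r
    )
  })
  grand_labels <- dplyr::bind_rows(grand_rows)

  # permutation tests on scalar class parameters via the shared engine:
  # build a subject x condition x 1 x 1 array per class and parameter
  test_rows <- list()
  for (par in c("duration_ms", "mean_gfp", "occurrence")) {
    for (cl in seq_len(k)) {
      vals <- matrix(0, n, L)
      for (cc in seq_len(L)) {
        v <- params[[par]][params$condition == cond_names[cc] & params$class == cl]
        vals[, cc] <- ifelse(is.na(v), 0, v)
      }
      arr <- array(vals, c(n, L, 1, 1))
      # scalar dissimilarity: sum over levels of |level mean - grand mean|
      res <- with_seed(seed, .rand_factor_tests(
        arr, design,
        factors = NULL, n_perm = n_perm,
        seed = seed, exact = FALSE, time = NULL, statistic = "scalar"
      ))
      res$class <- cl
      res$parameter <- par
      res$time_ms <- NULL
      test_rows <- c(test_rows, list(res))
    }
  }
  tests <- dplyr::bind_rows(test_rows)
  attr(tests, "n_perm") <- n_perm
  attr(tests, "seed") <- seed
  class(tests) <- c("sep_rand_test", class(tests))

  list(parameters = params, grand_labels = grand_labels, tests = tests)
}

#' Serialize / read a microstate model as JSON
#'
#' @param model A `sep_microstates`.
#' @param path Destination file.
#' @return `write_microstates_json()` returns `path` invisibly;
#'   `read_microstates_json()` the model.
#' @export
write_microstates_json <- function(model, path) {
  jsonlite::write_json(
    list(
      k = model$k, polarity = model$polarity, gev = model$gev,
      prototypes = model$prototypes, labels = model$labels
    ),
    path,
    digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_microstates_json
#' @export
read_microstates_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  structure(
    list(
      k = o$k, prototypes = o$prototypes, labels = o$labels,
      gev = o$gev, polarity = o$polarity
    ),
    class = "sep_microstates"
  )
}
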