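# Simulation-based validation suite: type-I-error calibration of the
# randomization tests, power/dissociation of the frequency effect, marker
# recovery, and microstate class-count recovery -- all driven by the
# synthetic generator, with fixed desk-scale study conditions documented in
# the methods vignette.

# Calibration / power studies run on a reduced 20-channel montage and short
# epochs so that hundreds of replicates stay cheap; noise is spatially and
# temporally white here (the tests' exchangeability assumptions do not
# depend on noise smoothness, and the white case is the canonical null for
# the topographic consistency test).
.calib_config <- function(n_subjects = 10, frequencies = c("0.5 Hz", "1.1 Hz"),
                          trials = 4, sampling_rate = 125,
                          epoch_window_ms = c(-100, 300)) {
  generator_config(
    montage = standard_montage("10-20-20"), n_subjects = n_subjects,
    frequencies = frequencies, trials = trials,
    sampling_rate = sampling_rate, epoch_window_ms = epoch_window_ms,
    noise_sd = 1, noise_spatial_fwhm_deg = NULL, noise_temporal_fwhm_ms = NULL
  )
}

# Extract the subject x condition x channel x 1 map array at one latency.
.maps_at <- function(stk, at_ms) {
  ti <- which.min(abs(stk$time - at_ms))
  stk$maps[, , , ti, drop = FALSE]
}

#' Type-I-error calibration of the randomization tests
#'
#' Simulates null datasets (condition labels carry no signal; for the TCT,
#' pure noise with no topography shared across subjects) and records, per
#' replicate, whether TANOVA, the GFP test and the TCT reject at `alpha`
#' at a fixed evaluation latency. Under a valid test the rejection rates
#' match `alpha` up to binomial noise.
#'
#' @param n_sims Number of simulated null datasets.
#' @param n_perm Randomization runs per test.
#' @param alpha Nominal level.
#' @param at_ms Evaluation latency, ms.
#' @param seed Base seed; replicate i uses `seed + i`.
#' @return Tibble with columns `test`, `rate`, `n_sims`, `n_perm`.
#' @export
sim_type1_rates <- function(n_sims = 500, n_perm = 999, alpha = 0.05,
                            at_ms = 115, seed = 1) {
  cfg <- .calib_config()
  rej <- matrix(FALSE, n_sims, 3, dimnames = list(NULL, c("tanova", "gfp", "tct")))
  for (i in seq_len(n_sims)) {
    ds <- null_dataset(cfg, seed = seed + i)
    stk <- evoked_stack(ds)
    m <- .maps_at(stk, at_ms)
    rej[i, "tanova"] <- tanova(m, stk$design, n_perm = n_perm, seed = seed + i)$p <= alpha
    rej[i, "gfp"] <- gfp_test(m, stk$design, n_perm = n_perm, seed = seed + i)$p <= alpha
    dsn <- null_dataset(cfg, components = NULL, seed = seed + i + 600000L)
    stkn <- evoked_stack(dsn)
    pooled <- apply(.maps_at(stkn, at_ms), c(1, 3, 4), mean)
    rej[i, "tct"] <- tct(pooled, n_perm = n_perm, seed = seed + i)$p <= alpha
  }
  tibble(
    test = colnames(rej), rate = colMeans(rej),
    n_sims = n_sims, n_perm = n_perm
  )
}

#' Frequency-effect recovery and strength/topography dissociation
#'
#' Simulates the headline study contrast -- amplitude multipliers 1 / 0.8 /
#' 0.6 across the three stimulation frequencies, n = 20 subjects, 1 uV
#' trial noise -- where map strength differs between conditions but (up to
#' noise) topography does not. Per replicate, the GFP test and TANOVA are
#' evaluated at the peak-GFP latency inside the N1 search window: the GFP
#' test should detect the effect (power), TANOVA should stay at its nominal
#' false-positive rate (dissociation).
#'
#' @param n_runs Number of replicates.
#' @param n_subjects,trials Study size per replicate.
#' @param n_perm Randomization runs.
#' @param n1_window_ms Window searched for the evaluation latency.
#' @param seed Base seed.
#' @return Tibble with one row per replicate: `p_gfp`, `p_tanova`,
#'   `peak_ms`.
#' @export
sim_frequency_effect <- function(n_runs = 50, n_subjects = 20, trials = 30,
                                 n_perm = 999, n1_window_ms = c(80, 170),
                                 seed = 1) {
  freqs <- c("0.5 Hz", "1.1 Hz", "1.6 Hz")
  cfg <- .calib_config(
    n_subjects = n_subjects, frequencies = freqs, trials = trials,
    sampling_rate = 250, epoch_window_ms = c(-100, 600)
  )
  # identical multipliers for every component: a pure map-strength scaling,
  # leaving the topographic null exactly true
  comps <- lapply(make_component_defaults(freqs), function(cp) {
    cp$condition_multipliers <- stats::setNames(c(1, 0.8, 0.6), freqs)
    cp
  })
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    ds <- simulate_sep(cfg, comps, seed = seed + i)
    stk <- evoked_stack(ds)
    gg <- gfp(apply(stk$maps, c(3, 4), mean))
    win <- which(stk$time >= n1_window_ms[1] & stk$time <= n1_window_ms[2])
    t_star <- stk$time[win[which.max(gg[win])]]
    m <- .maps_at(stk, t_star)
    rows[[i]] <- tibble(
      run = i, peak_ms = t_star,
      p_gfp = gfp_test(m, stk$design, n_perm = n_perm, seed = seed + i)$p,
      p_tanova = tanova(m, stk$design, n_perm = n_perm, seed = seed + i)$p
    )
  }
  dplyr::bind_rows(rows)
}

#' Marker-recovery simulation
#'
#' Simulates single-subject recordings at the generator's programmed
#' component latencies (with subject jitter) and checks that the automated
#' windowed-extremum marking recovers each subject's true N1 and P2 latency
#' on the Cz-Fz derivation within one sample. The per-run evoked SNR
#' (peak N1 amplitude over baseline noise SD on the trace) is reported so
#' callers can verify the SNR >= 5 regime.
#'
#' @param n_runs Number of simulated recordings.
#' @param trials Trials averaged per recording; the default of 200 sweeps is
#'   the routine clinical SEP averaging count.
#' @param seed Base seed.
#' @return Tibble per run: `snr`, `n1_err_ms`, `p2_err_ms`, `dt_ms`.
#' @export
sim_marker_recovery <- function(n_runs = 200, trials = 200, seed = 1) {
  cfg <- generator_config(
    montage = standard_montage("10-20-20"), n_subjects = 1,
    frequencies = "0.5 Hz", trials = trials, sampling_rate = 250,
    epoch_window_ms = c(-100, 600), noise_sd = 1
  )
  comps <- make_component_defaults("0.5 Hz")
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    ds <- simulate_sep(cfg, comps, seed = seed + i)
    ev <- average_epochs(ds$epochs[[1]])
    tr <- difference_channel(ev, "Cz", "Fz")
    mk <- detect_markers(tr)
    truth <- ds$truth[ds$truth$subject == "S001", ]
    n1_true <- truth$latency_ms[truth$component == "N1"]
    p2_true <- truth$latency_ms[truth$component == "P2"]
    base <- tr$value[tr$time_ms < -3]
    snr <- abs(mk$amplitude_uv[mk$component == "N1"]) / stats::sd(base)
    rows[[i]] <- tibble(
      run = i, snr = snr,
      n1_err_ms = mk$latency_ms[mk$component == "N1"] - n1_true,
      p2_err_ms = mk$latency_ms[mk$component == "P2"] - p2_true,
      dt_ms = time_step(tr$time_ms)
    )
  }
  dplyr::bind_rows(rows)
}

# Four spread template maps used by the microstate recovery study.
.recovery_templates <- function(montage) {
  mk <- function(center, gain = 1, fwhm = 60) {
    p <- component_pattern(
      component_spec("T",
        lobes = data.frame(center = center, fwhm_deg = fwhm, gain = gain),
        latency_ms = 0, width_ms = 1
      ),
      montage
    )
    p / sqrt(mean(p^2))
  }
  rbind(mk("CPz"), mk("Fz", gain = -1), mk("P7"), mk("C4"))
}

# One subject's map series: 4 states in fixed order with boundary jitter,
# per-state lognormal amplitude, additive white noise.
.recovery_subject <- function(templates, t_per_state = 24, amp = 3,
                              noise_sd = 1.5, jitter_sd = 2) {
  k <- nrow(templates)
  Tn <- k * t_per_state
  cuts <- pmin(pmax(
    cumsum(rep(t_per_state, k - 1)) + round(stats::rnorm(k - 1, 0, jitter_sd)),
    1
  ), Tn)
  lab <- findInterval(seq_len(Tn) - 0.5, c(0, sort(cuts), Tn))
  amps <- amp * exp(stats::rnorm(k, 0, 0.3))
  templates[lab, ] * amps[lab] +
    matrix(stats::rnorm(Tn * ncol(templates), 0, noise_sd), Tn, ncol(templates))
}

#' Microstate class-count recovery simulation
#'
#' Generates subject map series visiting four programmed template states
#' (with subject-level amplitude variability, boundary jitter and noise),
#' runs the split-half cross-validation over `k_grid`, and fits the final
#' AAHC model at k = 4 on the grand mean to measure prototype recovery.
#'
#' @param n_seeds Number of independent replicate datasets.
#' @param n_subjects Subjects per dataset.
#' @param k_grid Candidate class counts.
#' @param n_repeats Cross-validation half-splits per dataset.
#' @param seed Base seed.
#' @return Tibble per replicate: `chosen_k`, `prototype_corr` (mean matched
#'   correlation between the k = 4 prototypes and the true templates).
#' @export
sim_k_recovery <- function(n_seeds = 25, n_subjects = 20, k_grid = 3:8,
                           n_repeats = 10, seed = 1) {
  mnt <- standard_montage("10-20-20")
  templates <- .recovery_templates(mnt)
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    res <- with_seed(seed + i, {
      subj <- replicate(n_subjects, .recovery_subject(templates), simplify = FALSE)
      cv <- cross_validate_k(subj,
        k_grid = k_grid, n_repeats = n_repeats,
        seed = seed + i
      )
      model <- aahc(Reduce(`+`, subj) / n_subjects, k_target = 4)
      list(
        chosen_k = attr(cv, "chosen_k"),
        corr = .match_corr(model$prototypes, templates, "sensitive")
      )
    })
    rows[[i]] <- tibble(
      replicate = i, chosen_k = res$chosen_k,
      prototype_corr = res$corr
    )
  }
  dplyr::bind_rows(rows)
}
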