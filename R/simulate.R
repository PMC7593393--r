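# Synthetic stimulus-locked SEP generator: multichannel epochs with
# programmed components, condition effects, subject variability and
# spatio-temporally smoothed noise -- the ground-truth substrate for every
# downstream analysis.

#' Component specification for the SEP generator
#'
#' A component is a fixed scalp pattern (sum of von-Mises-like lobes on the
#' sphere, mean-centered so it is average-reference compatible) modulated in
#' time by a Gaussian pulse (or, for slow anticipatory activity, a
#' pre-stimulus ramp), scaled per condition and per subject.
#'
#' @param name Component label (e.g. "N1").
#' @param lobes Data frame with columns `center` (a montage label), `fwhm_deg`
#'   (angular full width at half maximum of the lobe) and `gain` (signed
#'   microvolt weight at the lobe center before mean-centering).
#' @param latency_ms Pulse center, ms (ignored for `shape = "ramp"`).
#' @param width_ms Pulse full width at half maximum, ms.
#' @param amplitude Base amplitude multiplier (the lobe gains are in
#'   microvolts; `amplitude` scales the whole pattern).
#' @param condition_multipliers Named numeric vector: amplitude multiplier
#'   per within-condition (frequency) level.
#' @param amp_sigma Subject-level lognormal amplitude sigma.
#' @param latency_sd_ms Subject-level latency jitter SD, ms.
#' @param shape `"pulse"` (Gaussian) or `"ramp"` (linear pre-stimulus build-up
#'   decaying back to zero over 100 ms post-stimulus).
#' @return A `component_spec` list.
#' @export
component_spec <- function(name, lobes, latency_ms, width_ms, amplitude = 1,
                           condition_multipliers = NULL, amp_sigma = 0.3,
                           latency_sd_ms = 7, shape = c("pulse", "ramp")) {
  shape <- match.arg(shape)
  structure(
    list(
      name = name, lobes = as.data.frame(lobes), latency_ms = latency_ms,
      width_ms = width_ms, amplitude = amplitude,
      condition_multipliers = condition_multipliers,
      amp_sigma = amp_sigma, latency_sd_ms = latency_sd_ms, shape = shape
    ),
    class = "component_spec"
  )
}

# von-Mises-like lobe kernel on the sphere: exp(kappa * (cos(gamma) - 1)),
# with kappa chosen so the lobe's angular FWHM matches fwhm_deg.
.kappa_from_fwhm <- function(fwhm_deg) log(2) / (1 - cos(deg2rad(fwhm_deg / 2)))

# Mean-centered spatial pattern of a component on a montage (unit vector of
# per-channel microvolt weights).
component_pattern <- function(comp, montage) {
  E <- montage_xyz(montage)
  pat <- rep(0, nrow(E))
  for (i in seq_len(nrow(comp$lobes))) {
    lb <- comp$lobes[i, ]
    ci <- match(lb$center, montage$label)
    if (is.na(ci)) abort(sprintf("lobe center '%s' not in montage", lb$center))
    cosg <- as.vector(E %*% E[ci, ])
    pat <- pat + lb$gain * exp(.kappa_from_fwhm(lb$fwhm_deg) * (cosg - 1))
  }
  pat - mean(pat)
}

# Temporal profile of a component on a time axis (unit peak).
component_profile <- function(comp, time, latency_ms = comp$latency_ms) {
  if (comp$shape == "ramp") {
    t0 <- min(time)
    up <- ifelse(time <= 0, (time - t0) / (0 - t0), 0)
    down <- ifelse(time > 0 & time <= 100, 1 - time / 100, 0)
    return(up + down)
  }
  sigma <- comp$width_ms / 2.355 # FWHM -> SD
  exp(-(time - latency_ms)^2 / (2 * sigma^2))
}

#' Default SEP components
#'
#' Four components emulating lower-urinary-tract SEP morphology: a weak
#' central P1 positivity (60 ms), the dominant centro-parietal N1 negativity
#' with a frontal positive counterpart (115 ms), a central P2 positivity
#' with a surrounding negativity (255 ms), and a slow central pre-stimulus
#' CNV ramp. Amplitude multipliers fall with stimulation frequency
#' (1 / 0.8 / 0.6 across 0.5 / 1.1 / 1.6 Hz; the CNV falls faster since
#' anticipation needs slow pacing).
#'
#' @param frequencies Within-condition level names the multipliers map onto.
#' @return List of [component_spec()]s.
#' @export
make_component_defaults <- function(frequencies = c("0.5 Hz", "1.1 Hz", "1.6 Hz")) {
  mult <- function(x) stats::setNames(x[seq_along(frequencies)], frequencies)
  sep_mult <- mult(c(1, 0.8, 0.6))
  list(
    component_spec("P1",
      lobes = data.frame(center = "Cz", fwhm_deg = 50, gain = 1.2),
      latency_ms = 60, width_ms = 30, condition_multipliers = sep_mult,
      latency_sd_ms = 5
    ),
    component_spec("N1",
      lobes = data.frame(
        center = c("CPz", "Fz"), fwhm_deg = c(45, 60),
        gain = c(-4, 1.6)
      ),
      latency_ms = 115, width_ms = 50, condition_multipliers = sep_mult,
      latency_sd_ms = 7
    ),
    component_spec("P2",
      lobes = data.frame(
        center = c("Cz", "Cz"), fwhm_deg = c(45, 110),
        gain = c(5, -1.5)
      ),
      latency_ms = 255, width_ms = 80, condition_multipliers = sep_mult,
      latency_sd_ms = 10
    ),
    component_spec("CNV",
      lobes = data.frame(center = "Cz", fwhm_deg = 70, gain = -2),
      latency_ms = 0, width_ms = 100,
      condition_multipliers = mult(c(1, 0.4, 0.2)),
      latency_sd_ms = 0, shape = "ramp"
    )
  )
}

#' Generator configuration
#'
#' The default configuration mirrors a three-frequency, five-location
#' lower-urinary-tract stimulation study (group sizes 20/17/19/9/18) at
#' desk-scale sampling (250 Hz, 60 trials per condition); override
#' `sampling_rate = 5000` and `trials = 100`+ to emulate the full recording
#' protocol.
#'
#' @param montage A `sep_montage`.
#' @param n_subjects Named integer vector: subjects per location group (the
#'   between factor); a single unnamed number gives one group.
#' @param frequencies Within-condition (frequency) level names.
#' @param trials Trials per subject x condition.
#' @param sampling_rate Hz.
#' @param epoch_window_ms Epoch span relative to the stimulus.
#' @param noise_sd Per-trial noise SD per channel, microvolts.
#' @param noise_spatial_fwhm_deg Angular FWHM of the spatial noise smoothing
#'   kernel (`NULL` for spatially white noise).
#' @param noise_temporal_fwhm_ms Temporal FWHM of the noise smoothing kernel
#'   (`NULL` for temporally white noise).
#' @return A `generator_config` list.
#' @export
generator_config <- function(montage = standard_montage("10-10-64"),
                             n_subjects = c(
                               BD = 20, TG = 17, pUR = 19,
                               mUR = 9, dUR = 18
                             ),
                             frequencies = c("0.5 Hz", "1.1 Hz", "1.6 Hz"),
                             trials = 60, sampling_rate = 250,
                             epoch_window_ms = c(-100, 600), noise_sd = 1,
                             noise_spatial_fwhm_deg = 60,
                             noise_temporal_fwhm_ms = 20) {
  if (is.null(names(n_subjects))) {
    names(n_subjects) <- if (length(n_subjects) == 1) "G1" else {
      paste0("G", seq_along(n_subjects))
    }
  }
  if (any(n_subjects < 1) || trials < 1) abort("all counts must be >= 1")
  stopifnot_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  structure(
    list(
      montage = montage, n_subjects = n_subjects, frequencies = frequencies,
      trials = as.integer(trials), sampling_rate = sampling_rate,
      epoch_window_ms = epoch_window_ms, noise_sd = noise_sd,
      noise_spatial_fwhm_deg = noise_spatial_fwhm_deg,
      noise_temporal_fwhm_ms = noise_temporal_fwhm_ms
    ),
    class = "generator_config"
  )
}

# Variance-preserving smoothing matrices for the noise model.
.noise_kernels <- function(config, time) {
  K <- nrow(config$montage)
  S <- NULL
  if (!is.null(config$noise_spatial_fwhm_deg)) {
    E <- montage_xyz(config$montage)
    S <- exp(.kappa_from_fwhm(config$noise_spatial_fwhm_deg) * (tcrossprod(E) - 1))
    S <- S / sqrt(rowSums(S^2)) # unit output variance for iid input
  }
  Tm <- NULL
  if (!is.null(config$noise_temporal_fwhm_ms)) {
    sigma <- config$noise_temporal_fwhm_ms / 2.355
    D <- outer(time, time, function(a, b) exp(-(a - b)^2 / (2 * sigma^2)))
    Tm <- D / sqrt(rowSums(D^2))
  }
  list(spatial = S, temporal = Tm)
}

.make_noise <- function(n_trials, K, Tn, sd, kernels) {
  out <- array(stats::rnorm(n_trials * K * Tn, 0, sd), c(n_trials, K, Tn))
  if (is.null(kernels$spatial) && is.null(kernels$temporal)) {
    return(out)
  }
  for (tr in seq_len(n_trials)) {
    M <- out[tr, , ]
    if (Tn == 1) M <- matrix(M, K, 1)
    if (!is.null(kernels$spatial)) M <- kernels$spatial %*% M
    if (!is.null(kernels$temporal)) M <- M %*% t(kernels$temporal)
    out[tr, , ] <- M
  }
  out
}

#' Simulate a synthetic SEP dataset
#'
#' Generates, per subject and condition, a stack of stimulus-locked epochs:
#' `epoch(t) = sum over components of pattern x pulse(t; latency + subject
#' jitter) x (base amplitude x condition multiplier x subject lognormal
#' factor) + noise`. The exact per-subject amplitudes and latencies are
#' returned as a ground-truth table so downstream tests never have to
#' re-infer them.
#'
#' @param config A [generator_config()].
#' @param components List of [component_spec()]s.
#' @param seed RNG seed; the full dataset is deterministic given the seed.
#' @return A `sep_dataset`: list with `epochs` (list of `sep_epochs`, one
#'   per subject x condition, named `"<subject>|<frequency>"`), `truth`
#'   (tibble: subject, group, frequency, component, amplitude, latency_ms),
#'   `subjects` (tibble: subject, group), `config`, `components`.
#' @export
simulate_sep <- function(config = generator_config(),
                         components = make_component_defaults(config$frequencies),
                         seed = NULL) {
  with_seed(seed, {
    mnt <- config$montage
    K <- nrow(mnt)
    fs <- config$sampling_rate
    time <- seq(config$epoch_window_ms[1], config$epoch_window_ms[2], by = 1000 / fs)
    Tn <- length(time)
    kernels <- .noise_kernels(config, time)
    patterns <- lapply(components, component_pattern, montage = mnt)

    groups <- rep(names(config$n_subjects), config$n_subjects)
    n <- length(groups)
    subjects <- sprintf("S%03d", seq_len(n))

    epochs <- list()
    truth_rows <- list()
    for (s in seq_len(n)) {
      # subject traits: one amplitude factor and one latency offset per component
      amp_f <- vapply(components, function(cp) exp(stats::rnorm(1, 0, cp$amp_sigma)), 0)
      lat_off <- vapply(components, function(cp) stats::rnorm(1, 0, cp$latency_sd_ms), 0)
      for (f in config$frequencies) {
        signal <- matrix(0, K, Tn)
        for (ci in seq_along(components)) {
          cp <- components[[ci]]
          m <- if (is.null(cp$condition_multipliers)) 1 else cp$condition_multipliers[[f]]
          amp <- cp$amplitude * m * amp_f[ci]
          lat <- cp$latency_ms + lat_off[ci]
          signal <- signal + amp * patterns[[ci]] %o%
            component_profile(cp, time, latency_ms = lat)
          truth_rows[[length(truth_rows) + 1]] <- tibble(
            subject = subjects[s], group = groups[s], frequency = f,
            component = cp$name, amplitude = amp, latency_ms = lat
          )
        }
        noise <- .make_noise(config$trials, K, Tn, config$noise_sd, kernels)
        data <- noise + aperm(
          array(signal, c(K, Tn, config$trials)),
          c(3, 1, 2)
        )
        epochs[[paste0(subjects[s], "|", f)]] <- epoch_set(
          data, time,
          montage = mnt, subject_id = subjects[s],
          condition = c(frequency = f, location = groups[s])
        )
      }
    }
    structure(
      list(
        epochs = epochs, truth = dplyr::bind_rows(truth_rows),
        subjects = tibble(subject = subjects, group = groups),
        config = config, components = components, seed = seed
      ),
      class = "sep_dataset"
    )
  })
}

#' @export
print.sep_dataset <- function(x, ...) {
  cat(sprintf(
    "<sep_dataset> %d subjects x %d conditions, %d trials each, %d channels\n",
    nrow(x$subjects), length(x$config$frequencies), x$config$trials,
    nrow(x$config$montage)
  ))
  invisible(x)
}

#' Null dataset for type-I-error calibration
#'
#' Generates data whose condition labels carry no signal: every component's
#' condition multipliers are forced to 1 so all frequencies share identical
#' expected maps (subject traits still vary). With `components = NULL` the
#' output is pure noise -- no topography shared across subjects -- which is
#' the appropriate null for the topographic consistency test.
#'
#' @param config A [generator_config()].
#' @param components Component list to flatten, or `NULL` for noise only.
#' @param seed RNG seed.
#' @return A `sep_dataset`.
#' @export
null_dataset <- function(config = generator_config(),
                         components = make_component_defaults(config$frequencies),
                         seed = NULL) {
  if (is.null(components)) {
    components <- list()
  } else {
    components <- lapply(components, function(cp) {
      cp$condition_multipliers <- NULL
      cp
    })
  }
  simulate_sep(config, components, seed = seed)
}

#' Stack a dataset into evoked maps for the randomization tests
#'
#' Averages each subject x condition epoch stack (optionally after average
#' referencing and baseline correction) into the subject x condition x
#' channel x time array consumed by [tanova()], [gfp_test()] and
#' [assign_and_compare()].
#'
#' @param dataset A `sep_dataset` (or plain named list of `sep_epochs` with
#'   `"subject|frequency"` names).
#' @param average_reference Re-reference each average to the common average.
#' @param baseline Baseline-correct each average (window per
#'   [baseline_correct()]) before stacking.
#' @return List: `maps` (array), `time`, `design` (a [design_spec()] with
#'   the dataset's frequencies and groups), `subjects`, `montage`.
#' @export
evoked_stack <- function(dataset, average_reference = TRUE, baseline = FALSE) {
  eps <- dataset$epochs
  subjects <- dataset$subjects$subject
  freqs <- dataset$config$frequencies
  first <- eps[[1]]
  time <- first$time
  K <- dim(first$data)[2]
  maps <- array(0, c(length(subjects), length(freqs), K, length(time)))
  for (s in seq_along(subjects)) {
    for (f in seq_along(freqs)) {
      e <- eps[[paste0(subjects[s], "|", freqs[f])]]
      ev <- average_epochs(e)
      if (average_reference) ev <- to_average_reference(ev)
      if (baseline) ev <- baseline_correct(ev)
      maps[s, f, , ] <- ev$data
    }
  }
  list(
    maps = maps, time = time,
    design = design_spec(
      within = freqs,
      between = if (length(unique(dataset$subjects$group)) > 1) {
        dataset$subjects$group
      } else {
        NULL
      }
    ),
    subjects = subjects, montage = first$montage
  )
}

#' Grand-average evoked series of a dataset
#'
#' @param dataset A `sep_dataset`.
#' @param frequency Restrict to one frequency level (default: all conditions
#'   pooled).
#' @inheritParams evoked_stack
#' @return A `sep_evoked`.
#' @export
grand_average <- function(dataset, frequency = NULL, average_reference = TRUE,
                          baseline = FALSE) {
  keep <- dataset$epochs
  if (!is.null(frequency)) {
    keep <- keep[vapply(keep, function(e) e$condition[["frequency"]] == frequency, TRUE)]
  }
  if (!length(keep)) abort("no epochs match the requested condition")
  evs <- lapply(keep, function(e) {
    ev <- average_epochs(e)
    if (average_reference) ev <- to_average_reference(ev)
    if (baseline) ev <- baseline_correct(ev)
    ev
  })
  avg <- Reduce(`+`, lapply(evs, `[[`, "data")) / length(evs)
  evoked_series(avg, evs[[1]]$time,
    n_trials = sum(vapply(evs, `[[`, 0L, "n_trials")),
    montage = evs[[1]]$montage,
    reference = evs[[1]]$reference,
    baseline_corrected = evs[[1]]$baseline_corrected
  )
}
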