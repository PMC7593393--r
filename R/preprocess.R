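# Filtering, referencing, epoching, artifact rejection, baseline correction
# and trial averaging.

#' Band-pass / notch filter specification
#'
#' The default mirrors a common SEP analysis setting: 0.5-70 Hz zero-phase
#' Butterworth with 24 dB/oct slopes (analog order 4 per edge) and a 50 Hz
#' notch. The zero-phase forward-backward pass doubles the effective
#' attenuation, as in standard analyzer software.
#'
#' @param band Length-2 numeric, `(low, high)` corner frequencies in Hz.
#' @param slope_db_per_oct Stop-band slope; 24 dB/oct corresponds to a
#'   4-pole Butterworth and is the only supported multiple-of-6 mapping:
#'   order = slope / 6.
#' @param notch_hz Notch center frequency in Hz, or `NULL` for none. The
#'   notch is a 2nd-order band-stop spanning `notch_hz` +/- 2 Hz.
#' @param zero_phase Apply forward-backward (`TRUE`, default).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(band = c(0.5, 70), slope_db_per_oct = 24,
                        notch_hz = 50, zero_phase = TRUE) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1]) {
    abort("`band` must be (low, high) with 0 < low < high")
  }
  order <- slope_db_per_oct / 6
  if (order != round(order) || order < 1) {
    abort("`slope_db_per_oct` must be a positive multiple of 6")
  }
  structure(
    list(
      band = as.numeric(band), slope_db_per_oct = slope_db_per_oct,
      order = as.integer(order), notch_hz = notch_hz,
      zero_phase = isTRUE(zero_phase)
    ),
    class = "filter_spec"
  )
}

# Reflection-padded filtfilt of one signal with a signal::Arma filter.
.filtfilt_padded <- function(flt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad > 0) {
    x <- c(
      2 * x[1] - x[(pad + 1):2], x,
      2 * x[n] - x[(n - 1):(n - pad)]
    )
  }
  y <- signal::filtfilt(flt, x)
  if (pad > 0) y <- y[(pad + 1):(pad + n)]
  y
}

#' Band-pass and notch filter a continuous recording
#'
#' Zero-phase Butterworth filtering per channel. The band-pass is realized
#' as an order-`order` high-pass followed by an order-`order` low-pass (a
#' numerically robust cascade equivalent in slope to the one-shot band-pass),
#' each applied forward-backward over a reflection-padded signal so edge
#' transients stay out of the recording.
#'
#' @param rec A `sep_continuous`.
#' @param spec A [filter_spec()].
#' @return The filtered `sep_continuous`.
#' @export
bandpass_notch <- function(rec, spec = filter_spec()) {
  if (!inherits(rec, "sep_continuous")) abort("`rec` must be a sep_continuous")
  fs <- rec$sampling_rate
  nyq <- fs / 2
  if (spec$band[2] >= nyq) {
    abort(sprintf("high corner %g Hz >= Nyquist (%g Hz)", spec$band[2], nyq))
  }
  if (!spec$zero_phase) {
    abort("only zero-phase (forward-backward) filtering is implemented")
  }
  bh <- signal::butter(spec$order, spec$band[1] / nyq, type = "high")
  bl <- signal::butter(spec$order, spec$band[2] / nyq, type = "low")
  bn <- NULL
  if (!is.null(spec$notch_hz)) {
    edges <- c(spec$notch_hz - 2, spec$notch_hz + 2) / nyq
    if (any(edges <= 0) || any(edges >= 1)) abort("notch band outside (0, Nyquist)")
    bn <- signal::butter(2, edges, type = "stop")
  }
  pad <- as.integer(min(round(3 * spec$order * fs / spec$band[1]), ncol(rec$data) - 1))
  for (ch in seq_len(nrow(rec$data))) {
    y <- .filtfilt_padded(bh, rec$data[ch, ], pad)
    y <- .filtfilt_padded(bl, y, pad)
    if (!is.null(bn)) y <- .filtfilt_padded(bn, y, pad)
    rec$data[ch, ] <- y
  }
  rec
}

#' Transform to average reference
#'
#' Subtracts the per-sample mean over channels from every channel, making
#' each map sum to zero; requires at least two channels.
#'
#' @param x A `sep_continuous`, `sep_epochs` or `sep_evoked`.
#' @return Same class, with `reference` set to `"average"`.
#' @export
to_average_reference <- function(x) {
  if (inherits(x, "sep_evoked") || inherits(x, "sep_continuous")) {
    if (nrow(x$data) < 2) abort("average reference undefined for a single channel")
    x$data <- sweep(x$data, 2, colMeans(x$data))
    x$reference <- "average"
    return(x)
  }
  if (inherits(x, "sep_epochs")) {
    if (dim(x$data)[2] < 2) abort("average reference undefined for a single channel")
    mean_ts <- apply(x$data, c(1, 3), mean) # trials x samples
    x$data <- x$data - aperm(
      array(mean_ts, c(dim(x$data)[1], dim(x$data)[3], dim(x$data)[2])),
      c(1, 3, 2)
    )
    x$reference <- "average"
    return(x)
  }
  abort("`x` must be a sep_continuous, sep_epochs or sep_evoked")
}

#' Difference (bipolar) channel
#'
#' Returns the per-sample difference `a - b`, e.g. the clinically
#' established Cz-Fz SEP derivation.
#'
#' @param x A `sep_evoked` or `sep_epochs`.
#' @param a_label,b_label Channel labels.
#' @return For evoked input, a tibble with columns `time_ms` and `value`;
#'   for epochs, a trials x samples matrix.
#' @export
difference_channel <- function(x, a_label, b_label) {
  ia <- channel_index(x, a_label)
  ib <- channel_index(x, b_label)
  if (inherits(x, "sep_evoked")) {
    return(tibble(time_ms = x$time, value = x$data[ia, ] - x$data[ib, ]))
  }
  if (inherits(x, "sep_epochs")) {
    return(x$data[, ia, ] - x$data[, ib, ])
  }
  abort("`x` must be a sep_epochs or sep_evoked")
}

#' Segment a continuous recording into stimulus-locked epochs
#'
#' Cuts one epoch per matching event. With the default window and a 5000 Hz
#' recording the epoch spans samples `event - 500` to `event + 3000`. Events
#' whose window falls outside the recording are dropped with a message.
#'
#' @param rec A `sep_continuous` with events.
#' @param event_codes Character vector of marker codes to epoch on, or `NULL`
#'   for all events.
#' @param t_min_ms,t_max_ms Epoch window relative to the stimulus, ms.
#' @param subject_id,condition Metadata copied onto the epoch stack.
#' @return A `sep_epochs`.
#' @export
segment_epochs <- function(rec, event_codes = NULL, t_min_ms = -100,
                           t_max_ms = 600, subject_id = NA_character_,
                           condition = character()) {
  if (!inherits(rec, "sep_continuous")) abort("`rec` must be a sep_continuous")
  if (t_min_ms >= t_max_ms) abort("`t_min_ms` must be below `t_max_ms`")
  ev <- rec$events
  if (!is.null(event_codes)) ev <- ev[ev$code %in% event_codes, ]
  if (nrow(ev) == 0) abort("no matching events to segment on")
  fs <- rec$sampling_rate
  o_min <- round(t_min_ms * fs / 1000)
  o_max <- round(t_max_ms * fs / 1000)
  lo <- ev$sample + o_min
  hi <- ev$sample + o_max
  ok <- lo >= 1 & hi <= ncol(rec$data)
  if (any(!ok)) {
    inform(sprintf(
      "segment_epochs: dropped %d event(s) whose window exceeds the recording",
      sum(!ok)
    ))
  }
  ev <- ev[ok, ]
  if (nrow(ev) == 0) abort("all epoch windows fall outside the recording")
  n_samp <- o_max - o_min + 1
  time <- (o_min:o_max) / fs * 1000
  data <- array(0, c(nrow(ev), nrow(rec$data), n_samp))
  for (i in seq_len(nrow(ev))) {
    data[i, , ] <- rec$data[, (ev$sample[i] + o_min):(ev$sample[i] + o_max)]
  }
  epoch_set(data, time,
    montage = rec$montage, subject_id = subject_id,
    condition = condition,
    reference = if (identical(rec$reference, "average")) "average" else "recording"
  )
}

#' Threshold-based artifact rejection
#'
#' Flags a trial as rejected iff any channel sample exceeds `threshold_uv` in
#' absolute value. The semiautomatic part of routine workflows is covered by
#' explicit override lists which win over the automatic rule.
#'
#' @param epochs A `sep_epochs`.
#' @param threshold_uv Rejection threshold, microvolts (> 0).
#' @param keep,reject Optional integer trial indices forced to be kept or
#'   rejected regardless of the threshold.
#' @return The `sep_epochs` with its `kept` mask updated.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 100, keep = NULL,
                             reject = NULL) {
  stopifnot_scalar_number(threshold_uv, "threshold_uv", positive = TRUE)
  peak <- apply(abs(epochs$data), 1, max)
  kept <- peak <= threshold_uv
  if (!is.null(keep)) kept[keep] <- TRUE
  if (!is.null(reject)) kept[reject] <- FALSE
  epochs$kept <- kept
  epochs
}

#' Baseline correction
#'
#' Subtracts, per channel (and per trial), the mean over the pre-stimulus
#' baseline window. The default window of -53 to -3 ms leaves a short guard
#' before the stimulus artifact.
#'
#' @param x A `sep_epochs` or `sep_evoked`.
#' @param window_ms Length-2 baseline window, ms (inclusive).
#' @return Same class with `baseline_corrected = TRUE`.
#' @export
baseline_correct <- function(x, window_ms = c(-53, -3)) {
  idx <- which(x$time >= window_ms[1] & x$time <= window_ms[2])
  if (length(idx) == 0) abort("baseline window contains no samples")
  if (inherits(x, "sep_evoked")) {
    x$data <- x$data - rowMeans(x$data[, idx, drop = FALSE])
    x$baseline_corrected <- TRUE
    return(x)
  }
  if (inherits(x, "sep_epochs")) {
    bl <- apply(x$data[, , idx, drop = FALSE], c(1, 2), mean)
    x$data <- x$data - array(bl, dim(x$data)) # recycles over samples
    x$baseline_corrected <- TRUE
    return(x)
  }
  abort("`x` must be a sep_epochs or sep_evoked")
}

#' Average kept trials into an evoked series
#'
#' @param epochs A `sep_epochs` with at least one kept trial.
#' @return A `sep_evoked`.
#' @export
average_epochs <- function(epochs) {
  kept <- which(epochs$kept)
  if (length(kept) < 1) abort("no kept trials to average")
  avg <- apply(epochs$data[kept, , , drop = FALSE], c(2, 3), mean)
  evoked_series(avg, epochs$time,
    n_trials = length(kept),
    montage = epochs$montage, reference = epochs$reference,
    baseline_corrected = epochs$baseline_corrected
  )
}

#' Split-half (odd / even) averages
#'
#' Splits the kept trials by their ordinal parity in acquisition order and
#' averages each half; used for waveform-stability checks.
#'
#' @param epochs A `sep_epochs` with at least two kept trials.
#' @return A list with elements `odd` and `even`, both `sep_evoked`.
#' @export
split_half_averages <- function(epochs) {
  kept <- which(epochs$kept)
  if (length(kept) < 2) abort("need at least 2 kept trials for a split-half")
  halves <- list(
    odd = kept[seq_along(kept) %% 2 == 1],
    even = kept[seq_along(kept) %% 2 == 0]
  )
  lapply(halves, function(idx) {
    avg <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
    evoked_series(avg, epochs$time,
      n_trials = length(idx),
      montage = epochs$montage, reference = epochs$reference,
      baseline_corrected = epochs$baseline_corrected
    )
  })
}
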