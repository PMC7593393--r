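# Core data containers: continuous recordings, epoch stacks, evoked series.

#' Continuous multichannel recording
#'
#' @param data Channels x samples matrix, microvolts. Row names, when present,
#'   must match the montage labels.
#' @param sampling_rate Sampling rate in Hz.
#' @param events Tibble with columns `sample` (1-based sample index) and
#'   `code` (character marker description). May have zero rows.
#' @param montage A `sep_montage` with one row per data row.
#' @param reference Label of the recording reference (default "Fz") or
#'   `"average"` once re-referenced.
#' @return A `sep_continuous` object.
#' @export
continuous_recording <- function(data, sampling_rate, events = NULL,
                                 montage = NULL, reference = "Fz") {
  data <- as.matrix(data)
  stopifnot_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  if (is.null(events)) events <- tibble(sample = integer(), code = character())
  events <- as_tibble(events)
  if (!all(c("sample", "code") %in% names(events))) {
    abort("`events` needs columns sample and code")
  }
  if (nrow(events) && (any(events$sample < 1) || any(events$sample > ncol(data)))) {
    abort("event sample indices must lie within the recording")
  }
  if (!is.null(montage) && nrow(montage) != nrow(data)) {
    abort(sprintf(
      "montage has %d channels but data has %d rows",
      nrow(montage), nrow(data)
    ))
  }
  if (!is.null(montage)) rownames(data) <- montage$label
  structure(
    list(
      data = data, sampling_rate = sampling_rate, events = events,
      montage = montage, reference = reference
    ),
    class = "sep_continuous"
  )
}

#' @export
print.sep_continuous <- function(x, ...) {
  cat(sprintf(
    "<sep_continuous> %d channels x %d samples @ %g Hz, %d events, ref %s\n",
    nrow(x$data), ncol(x$data), x$sampling_rate, nrow(x$events), x$reference
  ))
  invisible(x)
}

#' Stack of stimulus-locked epochs
#'
#' @param data Trials x channels x samples array, microvolts.
#' @param time Time axis in ms relative to stimulus onset; strictly
#'   increasing and bracketing 0.
#' @param montage Optional `sep_montage` (one row per channel).
#' @param subject_id,condition Metadata; `condition` is a named character
#'   vector, typically `c(frequency = ..., location = ...)`.
#' @param kept Logical per-trial keep mask (default all `TRUE`).
#' @param baseline_corrected,reference State flags; `reference` is
#'   `"recording"` or `"average"`.
#' @return A `sep_epochs` object.
#' @export
epoch_set <- function(data, time, montage = NULL, subject_id = NA_character_,
                      condition = character(), kept = NULL,
                      baseline_corrected = FALSE, reference = "recording") {
  if (length(dim(data)) != 3) abort("`data` must be a trials x channels x samples array")
  if (length(time) != dim(data)[3]) abort("`time` length must equal the sample count")
  if (any(diff(time) <= 0)) abort("`time` must be strictly increasing")
  if (min(time) > 0 || max(time) < 0) abort("`time` must contain stimulus onset (0 ms)")
  kept <- kept %||% rep(TRUE, dim(data)[1])
  if (length(kept) != dim(data)[1]) abort("`kept` length must equal the trial count")
  if (!is.null(montage) && nrow(montage) != dim(data)[2]) {
    abort("montage channel count must match data")
  }
  structure(
    list(
      data = data, time = as.numeric(time), montage = montage,
      subject_id = subject_id, condition = condition,
      kept = as.logical(kept), baseline_corrected = isTRUE(baseline_corrected),
      reference = reference
    ),
    class = "sep_epochs"
  )
}

#' @export
print.sep_epochs <- function(x, ...) {
  cat(sprintf(
    "<sep_epochs> %d trials (%d kept) x %d channels x %d samples [%g..%g ms]%s\n",
    dim(x$data)[1], sum(x$kept), dim(x$data)[2], dim(x$data)[3],
    min(x$time), max(x$time),
    if (x$baseline_corrected) ", baseline-corrected" else ""
  ))
  invisible(x)
}

#' Evoked (averaged) map series
#'
#' @param data Channels x samples matrix, microvolts.
#' @param time Time axis, ms.
#' @param n_trials Number of trials averaged (>= 1).
#' @param montage Optional `sep_montage`.
#' @param reference `"recording"` or `"average"`.
#' @param baseline_corrected Logical flag.
#' @return A `sep_evoked` object.
#' @export
evoked_series <- function(data, time, n_trials, montage = NULL,
                          reference = "recording", baseline_corrected = FALSE) {
  data <- as.matrix(data)
  if (length(time) != ncol(data)) abort("`time` length must equal the sample count")
  if (n_trials < 1) abort("`n_trials` must be >= 1")
  if (!is.null(montage)) {
    if (nrow(montage) != nrow(data)) abort("montage channel count must match data")
    rownames(data) <- montage$label
  }
  structure(
    list(
      data = data, time = as.numeric(time), n_trials = as.integer(n_trials),
      montage = montage, reference = reference,
      baseline_corrected = isTRUE(baseline_corrected)
    ),
    class = "sep_evoked"
  )
}

#' @export
print.sep_evoked <- function(x, ...) {
  cat(sprintf(
    "<sep_evoked> %d channels x %d samples [%g..%g ms], %d trials, ref %s%s\n",
    nrow(x$data), ncol(x$data), min(x$time), max(x$time), x$n_trials,
    x$reference, if (x$baseline_corrected) ", baseline-corrected" else ""
  ))
  invisible(x)
}

# Sampling step of a time axis, ms.
time_step <- function(time) {
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-6 * mean(dt)) abort("time axis is not regular")
  mean(dt)
}

channel_index <- function(x, label) {
  labs <- if (!is.null(x$montage)) x$montage$label else rownames(x$data)
  if (is.null(labs)) abort("object carries no channel labels")
  i <- match(label, labs)
  if (anyNA(i)) abort(sprintf("unknown channel label '%s'", label[which(is.na(i))[1]]))
  i
}

# ---------------------------------------------------------------------------
# Epoch fixture container: a single-file binary format with an explicit
# schema version, chosen over text for lossless float round-trips.  Layout:
#   bytes 1-4   magic "SEPE"
#   int32       schema version (1)
#   int32       header length H
#   H bytes     UTF-8 JSON header (dims, time, kept, metadata, montage)
#   doubles     data payload, column-major trials x channels x samples
#' Write / read an epoch fixture file
#'
#' Lossless round-trip of an epoch stack (data, time axis, keep mask,
#' metadata, montage) through a small versioned binary container.
#'
#' @param epochs A `sep_epochs`.
#' @param path Destination file.
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()` returns
#'   the `sep_epochs`.
#' @export
write_epochs <- function(epochs, path) {
  if (!inherits(epochs, "sep_epochs")) abort("`epochs` must be a sep_epochs")
  hdr <- list(
    dims = dim(epochs$data), time = epochs$time, kept = epochs$kept,
    subject_id = epochs$subject_id, condition = as.list(epochs$condition),
    baseline_corrected = epochs$baseline_corrected, reference = epochs$reference,
    montage = if (is.null(epochs$montage)) {
      NULL
    } else {
      list(
        label = epochs$montage$label, theta = epochs$montage$theta,
        phi = epochs$montage$phi
      )
    }
  )
  hjson <- charToRaw(jsonlite::toJSON(hdr, digits = NA, auto_unbox = TRUE, null = "null"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SEPE"), con)
  writeBin(c(1L, length(hjson)), con, size = 4, endian = "little")
  writeBin(hjson, con)
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!identical(magic, "SEPE")) {
    abort(sprintf("'%s' is not an epoch container (bad magic '%s')", path, magic))
  }
  meta <- readBin(con, "integer", 2, size = 4, endian = "little")
  if (meta[1] != 1L) {
    abort(sprintf("unsupported epoch container schema version %d (expected 1)", meta[1]))
  }
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", meta[2])),
    simplifyVector = TRUE
  )
  n <- prod(hdr$dims)
  payload <- readBin(con, "double", n, size = 8, endian = "little")
  if (length(payload) != n) abort("truncated epoch container payload")
  mont <- if (is.null(hdr$montage)) {
    NULL
  } else {
    montage(hdr$montage$label, hdr$montage$theta, hdr$montage$phi)
  }
  epoch_set(
    array(payload, hdr$dims),
    time = hdr$time, montage = mont,
    subject_id = hdr$subject_id,
    condition = unlist(hdr$condition) %||% character(),
    kept = if (length(hdr$kept)) hdr$kept else rep(TRUE, hdr$dims[1]),
    baseline_corrected = hdr$baseline_corrected, reference = hdr$reference
  )
}
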