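# Automated SEP component marking, split-half stability, responder rate and
# data-driven component time windows.

#' Default component search windows
#'
#' P1 40-90 ms, N1 80-170 ms, P2 185-380 ms: the canonical search ranges for
#' lower-urinary-tract SEP components on the vertex derivations. Any named
#' list of `(start, end)` windows may be used instead (e.g. pudendal
#' P40/N50/P65/N85 windows).
#'
#' @return Named list of length-2 numeric windows, ms.
#' @export
marker_windows_default <- function() {
  list(P1 = c(40, 90), N1 = c(80, 170), P2 = c(185, 380))
}

#' Detect SEP component markers on a single trace
#'
#' Within each search window, positive components (`P*`) are marked at the
#' maximum and negative components (`N*`) at the minimum; plateau ties break
#' toward the earliest sample. Peak-to-peak amplitudes P1N1 and P2N1 are
#' attached when the corresponding components are present.
#'
#' @param trace Numeric vector (one channel / derivation), or a data frame
#'   with columns `time_ms`/`time` and `value` (as returned by
#'   [difference_channel()]).
#' @param time Time axis in ms (ignored when `trace` is a data frame).
#' @param search_windows Named list of `(start, end)` windows, ms; names
#'   starting with "N" are treated as negative components.
#' @param channel_pair Label describing the derivation, e.g. `"Cz-Fz"`.
#' @return A `sep_markers` tibble with columns `component`, `latency_ms`,
#'   `amplitude_uv` and attributes `peak_to_peak` and `channel_pair`.
#' @export
detect_markers <- function(trace, time = NULL,
                           search_windows = marker_windows_default(),
                           channel_pair = NA_character_) {
  if (is.data.frame(trace)) {
    time <- trace[["time_ms"]] %||% trace[["time"]]
    trace <- trace[["value"]]
  }
  if (is.null(time) || length(time) != length(trace)) {
    abort("`time` must accompany `trace` and match its length")
  }
  rows <- purrr::imap(search_windows, function(win, comp) {
    idx <- which(time >= win[1] & time <= win[2])
    if (length(idx) == 0) {
      abort(sprintf("search window for %s lies outside the trace", comp))
    }
    seg <- trace[idx]
    negative <- startsWith(comp, "N")
    target <- if (negative) min(seg) else max(seg)
    at <- idx[which(seg == target)[1]] # earliest sample on ties
    tibble(
      component = comp, latency_ms = time[at], amplitude_uv = trace[at],
      polarity = if (negative) "negative" else "positive"
    )
  })
  out <- dplyr::bind_rows(rows)
  p2p <- c(
    P1N1 = if (all(c("P1", "N1") %in% out$component)) {
      out$amplitude_uv[out$component == "P1"] - out$amplitude_uv[out$component == "N1"]
    } else {
      NA_real_
    },
    P2N1 = if (all(c("P2", "N1") %in% out$component)) {
      out$amplitude_uv[out$component == "P2"] - out$amplitude_uv[out$component == "N1"]
    } else {
      NA_real_
    }
  )
  attr(out, "peak_to_peak") <- p2p
  attr(out, "channel_pair") <- channel_pair
  class(out) <- c("sep_markers", class(out))
  out
}

#' Split-half waveform stability
#'
#' Pearson correlation of the odd- and even-trial average traces over a time
#' window; a recording counts as stable when the correlation reaches
#' `r_min`. This is a numeric
#' proxy for the visual "overlapping waveform" criterion of clinical
#' practice; the default `r_min = 0.5` is a package choice and should be
#' tuned to the lab's standards.
#'
#' @param odd,even Numeric traces on a shared time axis, or data frames with
#'   `time_ms`/`value` columns.
#' @param time Shared time axis, ms (for numeric input).
#' @param window_ms Window over which to correlate, default 0-600 ms.
#' @param r_min Stability threshold on the correlation.
#' @return A list with elements `r` and `stable`.
#' @export
stability <- function(odd, even, time = NULL, window_ms = c(0, 600),
                      r_min = 0.5) {
  if (is.data.frame(odd)) {
    time <- odd[["time_ms"]] %||% odd[["time"]]
    odd <- odd[["value"]]
  }
  if (is.data.frame(even)) even <- even[["value"]]
  if (is.null(time) || length(odd) != length(even) || length(time) != length(odd)) {
    abort("`odd` and `even` must share one time axis")
  }
  idx <- which(time >= window_ms[1] & time <= window_ms[2])
  if (length(idx) < 3) abort("stability window contains fewer than 3 samples")
  r <- stats::cor(odd[idx], even[idx])
  list(r = r, stable = !is.na(r) && r >= r_min)
}

#' Responder rate
#'
#' Percentage of recordings that yielded a stable SEP with all components
#' marked.
#'
#' @param x Either a data frame with a logical `stable` column (and an
#'   optional logical `marked` column, default all `TRUE`), or a list of
#'   per-recording lists/objects with `stable` (and optional `marked`)
#'   entries.
#' @return Percentage in \[0, 100\].
#' @export
responder_rate <- function(x) {
  if (is.data.frame(x)) {
    stable <- x[["stable"]]
    marked <- x[["marked"]] %||% rep(TRUE, nrow(x))
  } else if (is.list(x) && length(x)) {
    stable <- vapply(x, function(e) isTRUE(e$stable), TRUE)
    marked <- vapply(x, function(e) isTRUE(e$marked %||% TRUE), TRUE)
  } else {
    abort("`x` must be a non-empty data frame or list of recordings")
  }
  if (length(stable) == 0) abort("no recordings supplied")
  100 * sum(stable & marked) / length(stable)
}

#' Group time window from individual latencies (mean +/- 2 SD)
#'
#' Computes `mean(latencies) +/- 2 * sd(latencies)` (sample SD, n-1 divisor)
#' and widens outward to the sample grid. A degenerate window (zero SD) is
#' widened to +/- one sample with a warning.
#'
#' @param latencies Individual peak latencies, ms (length >= 2, or length 1+
#'   identical values for the degenerate path).
#' @param dt_ms Sample step for outward rounding; `NULL` keeps continuous ms.
#' @return Length-2 numeric `(start, end)`, ms.
#' @export
windows_mean2sd <- function(latencies, dt_ms = NULL) {
  if (length(latencies) < 1 || anyNA(latencies)) {
    abort("`latencies` must be non-missing")
  }
  m <- mean(latencies)
  s <- if (length(latencies) > 1) stats::sd(latencies) else 0
  lo <- m - 2 * s
  hi <- m + 2 * s
  step <- dt_ms %||% 1
  if (!is.null(dt_ms)) {
    lo <- floor(lo / dt_ms) * dt_ms
    hi <- ceiling(hi / dt_ms) * dt_ms
  }
  if (hi - lo < step / 2) {
    warn("degenerate (zero-width) window; widened to +/- one sample")
    lo <- lo - step
    hi <- hi + step
  }
  c(start = lo, end = hi)
}

# Centered moving average with window of `w` samples (odd; shrinks at edges).
.smooth_ma <- function(x, w) {
  if (w <= 1) return(x)
  half <- (w - 1) %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Component time windows from the GFP curve
#'
#' Finds GFP peaks in the post-stimulus segment and brackets each with either
#' the flanking local GFP minima (`mode = "minima"`; component start/end
#' points) or the flanking inflection points of the smoothed curve
#' (`mode = "inflection"`; narrower windows nested inside the minima
#' windows). Components are labelled in temporal order; by default the first
#' GFP peak after 50 ms is N1 and the next P2 -- P1 is intentionally not
#' assigned a GFP window since weak early components need not produce a
#' distinct GFP peak.
#'
#' @param gfp Numeric GFP curve, or a data frame with `time_ms`/`gfp`
#'   columns (see [gfp_curve()]).
#' @param time Time axis, ms (for numeric input).
#' @param mode `"minima"` or `"inflection"`.
#' @param labels Component labels assigned to the peaks in temporal order.
#' @param min_latency_ms Peaks before this latency are ignored.
#' @param smooth_ms Width of the moving-average smoother applied before the
#'   minima / second-derivative search (the derivative of raw GFP is noise
#'   dominated).
#' @param min_prominence Minimum peak height as a fraction of the smoothed
#'   curve's range, guarding against ripple peaks.
#' @return A `sep_windows` tibble with columns `component`, `start_ms`,
#'   `end_ms`, `peak_ms`, `method`.
#' @export
windows_from_gfp <- function(gfp, time = NULL, mode = c("minima", "inflection"),
                             labels = c("N1", "P2"), min_latency_ms = 50,
                             smooth_ms = 5, min_prominence = 0.1) {
  mode <- match.arg(mode)
  if (is.data.frame(gfp)) {
    time <- gfp[["time_ms"]] %||% gfp[["time"]]
    gfp <- gfp[["gfp"]]
  }
  if (is.null(time) || length(time) != length(gfp)) {
    abort("`time` must accompany `gfp` and match its length")
  }
  dt <- time_step(time)
  w <- max(1L, 2L * floor(smooth_ms / dt / 2) + 1L)
  s <- .smooth_ma(gfp, w)
  n <- length(s)
  interior <- 2:(n - 1)
  is_peak <- s[interior] > s[interior - 1] & s[interior] >= s[interior + 1]
  peaks <- interior[is_peak]
  peaks <- peaks[time[peaks] > min_latency_ms]
  peaks <- peaks[s[peaks] >= min(s) + min_prominence * (max(s) - min(s))]
  if (length(peaks) < length(labels)) {
    abort(sprintf(
      "GFP window detection failed: needed %d peak(s) after %g ms, found %d (at %s ms)",
      length(labels), min_latency_ms, length(peaks),
      if (length(peaks)) paste(round(time[peaks], 1), collapse = ", ") else "none"
    ))
  }
  # keep the `length(labels)` tallest peaks, then label them in temporal order
  keep <- sort(peaks[order(s[peaks], decreasing = TRUE)][seq_along(labels)])

  is_min <- s[interior] < s[interior - 1] & s[interior] <= s[interior + 1]
  minima <- c(1L, interior[is_min], n)

  d2 <- c(NA, diff(diff(s)), NA) / dt^2

  rows <- purrr::map2(keep, labels, function(pk, lab) {
    if (mode == "minima") {
      lo <- max(minima[minima < pk])
      hi <- min(minima[minima > pk])
      start <- time[lo]
      end <- time[hi]
    } else {
      # inflection: nearest sign change of the second derivative on each side,
      # position linearly interpolated between samples
      cross <- function(from, dir) {
        i <- from
        repeat {
          j <- i + dir
          if (j < 2 || j > n - 1) return(time[i])
          if (!is.na(d2[i]) && !is.na(d2[j]) && d2[i] * d2[j] <= 0 && d2[i] != d2[j]) {
            f <- abs(d2[i]) / (abs(d2[i]) + abs(d2[j]))
            return(time[i] + f * (time[j] - time[i]))
          }
          i <- j
        }
      }
      start <- cross(pk, -1L)
      end <- cross(pk, 1L)
    }
    tibble(
      component = lab, start_ms = start, end_ms = end,
      peak_ms = time[pk], method = paste0("gfp_", mode)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sep_windows", class(out))
  out
}
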