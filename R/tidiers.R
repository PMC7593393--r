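# broom-style tidy()/glance() methods for the result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy methods for erptopo results
#'
#' `tidy()` returns the underlying per-time-point / per-class tibble;
#' `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy-erptopo
NULL

#' @rdname tidy-erptopo
#' @export
tidy.sep_rand_test <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sep_rand_test")
  as_tibble(out)
}

#' @rdname tidy-erptopo
#' @param alpha Significance level used for the summary counts.
#' @export
glance.sep_rand_test <- function(x, alpha = 0.05, ...) {
  tibble(
    n_tests = nrow(x),
    n_significant = sum(x$p <= alpha),
    min_p = min(x$p),
    n_perm = attr(x, "n_perm") %||% NA_integer_,
    seed = attr(x, "seed") %||% NA_integer_
  )
}

#' @rdname tidy-erptopo
#' @export
tidy.sep_microstates <- function(x, ...) {
  tibble(
    t = seq_along(x$labels), class = x$labels,
    gfp = x$gfp %||% NA_real_
  )
}

#' @rdname tidy-erptopo
#' @export
glance.sep_microstates <- function(x, ...) {
  tibble(k = x$k, gev = x$gev, polarity = x$polarity)
}

#' @rdname tidy-erptopo
#' @export
tidy.sep_cv <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sep_cv")
  as_tibble(out)
}

#' @rdname tidy-erptopo
#' @export
glance.sep_cv <- function(x, ...) {
  tibble(
    chosen_k = attr(x, "chosen_k"),
    best_correlation = max(x$mean_correlation),
    n_repeats = attr(x, "n_repeats"),
    seed = attr(x, "seed") %||% NA_integer_
  )
}

#' @rdname tidy-erptopo
#' @export
tidy.sep_markers <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sep_markers")
  as_tibble(out)
}

#' @rdname tidy-erptopo
#' @export
glance.sep_markers <- function(x, ...) {
  p2p <- attr(x, "peak_to_peak")
  tibble(
    channel_pair = attr(x, "channel_pair") %||% NA_character_,
    p1n1_uv = unname(p2p["P1N1"]),
    p2n1_uv = unname(p2p["P2N1"])
  )
}

#' @rdname tidy-erptopo
#' @export
glance.sep_evoked <- function(x, ...) {
  tibble(
    n_channels = nrow(x$data), n_samples = ncol(x$data),
    n_trials = x$n_trials, reference = x$reference,
    baseline_corrected = x$baseline_corrected,
    peak_gfp = max(gfp(x))
  )
}
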