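# Spherical-spline scalp interpolation (Perrin-type).
#
# Kernel: g(cos gamma) = (1/4pi) * sum_{n=1..N} (2n+1)/[n(n+1)]^m * P_n(cos gamma),
# with spline order m (default 4) and series degree N (default 10).  The
# interpolant v(t) = c0 + sum_i c_i g(cos gamma(t, e_i)) is obtained from the
# constrained linear system
#   [G + lambda I   1] [c ]   [v]
#   [1'             0] [c0] = [0]
# where G_ij = g(e_i . e_j).  lambda = 0 gives exact interpolation; a small
# ridge (default 1e-8) guards against near-duplicate electrodes.

# P_1..P_N Legendre polynomials at x (vectorized; Bonnet recurrence).
legendre_table <- function(x, N) {
  P <- matrix(0, length(x), N)
  P[, 1] <- x
  if (N >= 2) P[, 2] <- (3 * x^2 - 1) / 2
  if (N >= 3) {
    for (n in 3:N) P[, n] <- ((2 * n - 1) * x * P[, n - 1] - (n - 1) * P[, n - 2]) / n
  }
  P
}

spline_g <- function(cosg, order_m, degree_n) {
  n <- seq_len(degree_n)
  w <- (2 * n + 1) / (n * (n + 1))^order_m
  P <- legendre_table(pmin(1, pmax(-1, as.vector(cosg))), degree_n)
  out <- as.vector(P %*% w) / (4 * pi)
  if (!is.null(dim(cosg))) dim(out) <- dim(cosg)
  out
}

#' Spherical spline interpolation of scalp potentials
#'
#' Interpolates per-channel values measured at the montage electrodes onto
#' arbitrary unit-sphere targets. `values` may be a vector (one map) or a
#' channels x samples matrix; the spline system is factorized once and
#' applied to every column.
#'
#' @param montage A `sep_montage` giving the electrode positions.
#' @param values Numeric vector (length = channels) or channels x samples
#'   matrix of potentials, microvolts.
#' @param targets Matrix of unit vectors (rows = targets, columns x, y, z),
#'   or a two-column matrix of spherical `(theta, phi)` degrees.
#' @param order_m Spline order m (default 4).
#' @param degree_n Series degree N (default 10).
#' @param lambda_reg Ridge added to the diagonal of the kernel matrix;
#'   `0` gives an exact interpolant through the data.
#' @return A targets x samples matrix (dropped to a vector for vector input).
#' @export
spline_interpolate <- function(montage, values, targets, order_m = 4,
                               degree_n = 10, lambda_reg = 1e-8) {
  E <- montage_xyz(montage)
  vec_in <- is.null(dim(values))
  V <- if (vec_in) matrix(values, ncol = 1) else as.matrix(values)
  if (nrow(V) != nrow(E)) abort("`values` must have one row per montage channel")
  if (ncol(targets) == 2) targets <- sph_to_cart(targets[, 1], targets[, 2])
  targets <- targets / sqrt(rowSums(targets^2))

  K <- nrow(E)
  G <- spline_g(tcrossprod(E), order_m, degree_n) + diag(lambda_reg, K)
  A <- rbind(cbind(G, 1), c(rep(1, K), 0))
  sol <- tryCatch(
    solve(A, rbind(V, 0)),
    error = function(e) {
      abort(paste0(
        "singular spline system (duplicate or near-duplicate electrodes?); ",
        "set `lambda_reg` > 0. Underlying error: ", conditionMessage(e)
      ))
    }
  )
  Gt <- spline_g(tcrossprod(targets, E), order_m, degree_n)
  dim(Gt) <- c(nrow(targets), K)
  out <- Gt %*% sol[seq_len(K), , drop = FALSE] +
    matrix(sol[K + 1, ], nrow(targets), ncol(V), byrow = TRUE)
  if (vec_in) drop(out) else out
}

#' Append spline-interpolated virtual channels
#'
#' Adds virtual channels at given spherical positions to an epoch stack or
#' evoked series, computed per sample (and per trial) by spherical spline
#' interpolation from the existing montage. Defaults are the midline SEP
#' channels CzCPz (theta 11, phi -90) and FzFCz (theta 34, phi 90).
#'
#' @param x A `sep_epochs` or `sep_evoked` carrying a montage.
#' @param defs Data frame with columns `label`, `theta`, `phi`.
#' @inheritParams spline_interpolate
#' @return Object of the same class with the channels appended and the
#'   montage extended.
#' @export
add_virtual_channels <- function(x, defs = virtual_channel_defaults(),
                                 order_m = 4, degree_n = 10, lambda_reg = 1e-8) {
  if (is.null(x$montage)) abort("`x` must carry a montage")
  defs <- as.data.frame(defs)
  if (any(defs$label %in% x$montage$label)) {
    abort(sprintf(
      "channel label(s) already present: %s",
      paste(intersect(defs$label, x$montage$label), collapse = ", ")
    ))
  }
  targets <- sph_to_cart(defs$theta, defs$phi)
  new_m <- montage(
    c(x$montage$label, defs$label),
    c(x$montage$theta, defs$theta),
    c(x$montage$phi, defs$phi)
  )
  if (inherits(x, "sep_evoked")) {
    add <- spline_interpolate(x$montage, x$data, targets,
      order_m = order_m,
      degree_n = degree_n, lambda_reg = lambda_reg
    )
    x$data <- rbind(x$data, matrix(add, nrow = nrow(defs)))
    rownames(x$data) <- new_m$label
    x$montage <- new_m
    return(x)
  }
  if (inherits(x, "sep_epochs")) {
    d <- dim(x$data)
    out <- array(0, c(d[1], d[2] + nrow(defs), d[3]))
    out[, seq_len(d[2]), ] <- x$data
    for (tr in seq_len(d[1])) {
      out[tr, d[2] + seq_len(nrow(defs)), ] <-
        spline_interpolate(x$montage, x$data[tr, , ], targets,
          order_m = order_m, degree_n = degree_n, lambda_reg = lambda_reg
        )
    }
    x$data <- out
    x$montage <- new_m
    return(x)
  }
  abort("`x` must be a sep_epochs or sep_evoked")
}

#' @rdname add_virtual_channels
#' @export
virtual_channel_defaults <- function() {
  data.frame(
    label = c("CzCPz", "FzFCz"),
    theta = c(11, 34),
    phi = c(-90, 90)
  )
}
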