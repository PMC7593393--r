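# Montage definition and spherical/Cartesian coordinate handling.
#
# Coordinate convention (fixed throughout the package, documented because EEG
# software disagrees): electrodes live on a unit sphere; `theta` is the polar
# angle in degrees measured from the vertex (Cz, theta = 0), `phi` is the
# azimuth in degrees with +90 pointing to the nose, 0 to the right preauricular
# point and -90 to the inion.  Cartesian axes: +z vertex, +y nose, +x right.
# Under this convention the anterior midline virtual channel FzFCz sits at
# (theta = 34, phi = 90) and the posterior midline CzCPz at (theta = 11,
# phi = -90).

#' Convert spherical electrode coordinates to Cartesian unit vectors
#'
#' Angles are taken modulo 360 degrees; the radius is fixed at 1.
#' `x = sin(theta) cos(phi)`, `y = sin(theta) sin(phi)`, `z = cos(theta)`.
#'
#' @param theta Polar angle(s) from the vertex, degrees.
#' @param phi Azimuth(s), degrees; +90 is anterior (nose), -90 posterior.
#' @return A matrix with one row per input angle pair and columns `x`, `y`, `z`.
#' @examples
#' sph_to_cart(0, 0)        # the vertex Cz
#' sph_to_cart(34, 90)      # anterior midline (FzFCz)
#' @export
sph_to_cart <- function(theta, phi) {
  th <- deg2rad(theta %% 360)
  ph <- deg2rad(phi %% 360)
  cbind(x = sin(th) * cos(ph), y = sin(th) * sin(ph), z = cos(th))
}

#' Convert Cartesian unit vectors to spherical coordinates
#'
#' Inverse of [sph_to_cart()]; input rows are normalized to unit length first.
#'
#' @param xyz Numeric matrix (or length-3 vector) of positions, columns x, y, z.
#' @return A matrix with columns `theta`, `phi` in degrees; `theta` in
#'   \[0, 180\], `phi` in (-180, 180\].
#' @export
cart_to_sph <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nrm <- sqrt(rowSums(xyz^2))
  if (any(nrm == 0)) abort("zero-length position vector")
  xyz <- xyz / nrm
  theta <- rad2deg(acos(pmin(1, pmax(-1, xyz[, 3]))))
  phi <- rad2deg(atan2(xyz[, 2], xyz[, 1]))
  phi[theta < 1e-12] <- 0 # azimuth undefined at the pole
  cbind(theta = theta, phi = phi)
}

#' Construct a montage
#'
#' A montage is a tibble (class `sep_montage`) with one row per channel and
#' columns `label`, `theta`, `phi`, `x`, `y`, `z`. Labels must be unique and
#' at least two channels are required.
#'
#' @param labels Character vector of channel names.
#' @param theta,phi Spherical coordinates in degrees (see [sph_to_cart()]).
#' @return A `sep_montage` tibble.
#' @export
montage <- function(labels, theta, phi) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) abort("montage labels must be unique")
  if (length(labels) < 2) abort("a montage needs at least 2 channels")
  if (length(theta) != length(labels) || length(phi) != length(labels)) {
    abort("labels, theta and phi must have equal length")
  }
  xyz <- sph_to_cart(theta, phi)
  out <- tibble(
    label = labels, theta = as.numeric(theta), phi = as.numeric(phi),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  class(out) <- c("sep_montage", class(out))
  out
}

#' @export
print.sep_montage <- function(x, ...) {
  cat(sprintf("<sep_montage> %d channels\n", nrow(x)))
  NextMethod()
}

# Cartesian positions of a montage as a plain matrix (rows = channels).
montage_xyz <- function(m) {
  out <- as.matrix(m[, c("x", "y", "z")])
  rownames(out) <- m$label
  out
}

# The 64 labels of the extended 10-20 (10-10) layout shipped by default.
.labels_6410 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2", "FC6",
  "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
  "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10",
  "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6", "FT9", "FT7",
  "FC3", "FC4", "FT8", "FT10", "C5", "C1", "C2", "C6", "TP7", "CP3",
  "CPz", "CP4", "TP8", "P5", "P1", "P2", "P6", "PO7", "PO3", "POz",
  "PO4", "PO8"
)

# Idealized spherical position for a 10-10 label.  Rows (Fp, AF, F, FC, C, CP,
# P, PO, O) are anterior-posterior coordinates v in {1, .75, .., -1}; numeric
# suffixes give the lateral coordinate u in steps of 0.25 (odd = left), with
# the 9/10 column below the equator (|u| = 1.25).  The square (u, v) grid is
# mapped onto the projection disk with the elliptical (squircular) mapping,
# then radius is read as polar angle (90 deg at the equator).  This puts the
# classic 10-20 sites where convention expects them (Fz at theta 45, CPz at
# 22.5, T7 on the equator at phi 180) and keeps the montage left-right
# symmetric with distinct positions.
.parse_1010_label <- function(lab) {
  m <- regmatches(lab, regexec("^(Fp|AF|FC|FT|CP|TP|PO|F|C|T|P|O)(z|[0-9]+)$", lab))[[1]]
  if (length(m) == 0) abort(sprintf("cannot parse 10-10 label '%s'", lab))
  row_v <- c(
    Fp = 1, AF = 0.75, F = 0.5, FC = 0.25, FT = 0.25, C = 0, T = 0,
    CP = -0.25, TP = -0.25, P = -0.5, PO = -0.75, O = -1
  )[[m[2]]]
  if (m[3] == "z") {
    u <- 0
  } else {
    n <- as.numeric(m[3])
    u <- ceiling(n / 2) / 4 * if (n %% 2 == 1) -1 else 1
  }
  c(v = row_v, u = u)
}

#' Standard montages
#'
#' Idealized spherical montages for the extended international 10-20 layout.
#' `"10-10-64"` is the default 64-channel cap; `"10-20-19"` the classic
#' 19-channel set; `"10-20-20"` adds CPz (handy as a small, well-spread test
#' montage). The exact electrode list of any given cap can always be supplied
#' via [montage()] or [read_montage_tsv()] instead.
#'
#' @param name Which montage to build.
#' @return A `sep_montage` tibble.
#' @export
standard_montage <- function(name = c("10-10-64", "10-20-19", "10-20-20")) {
  name <- match.arg(name)
  labs1020 <- c(
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz", "C4",
    "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2"
  )
  labs <- switch(name,
    "10-10-64" = .labels_6410,
    "10-20-19" = labs1020,
    "10-20-20" = c(labs1020, "CPz")
  )
  uv <- t(vapply(labs, .parse_1010_label, numeric(2)))
  u <- uv[, "u"]
  v <- uv[, "v"]
  X <- u * sqrt(pmax(0, 1 - v^2 / 2))
  Y <- v * sqrt(pmax(0, 1 - pmin(1, u^2) / 2))
  r <- sqrt(X^2 + Y^2)
  theta <- 90 * r
  phi <- rad2deg(atan2(Y, X))
  phi[r < 1e-12] <- 0
  montage(labs, theta, phi)
}

#' Read / write a montage as TSV
#'
#' The on-disk format is a three-column TSV (`label`, `theta`, `phi`) in the
#' package's spherical convention; Cartesian positions are rederived on read.
#'
#' @param path File path.
#' @return `read_montage_tsv()` returns a `sep_montage`;
#'   `write_montage_tsv()` returns `path` invisibly.
#' @export
read_montage_tsv <- function(path) {
  tb <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("label", "theta", "phi")
  if (!all(need %in% names(tb))) {
    abort("montage TSV must have columns label, theta, phi")
  }
  montage(tb$label, tb$theta, tb$phi)
}

#' @rdname read_montage_tsv
#' @param m A `sep_montage`.
#' @export
write_montage_tsv <- function(m, path) {
  utils::write.table(m[, c("label", "theta", "phi")],
    path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
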