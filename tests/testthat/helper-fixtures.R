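# Shared fixtures built in code: a small montage, random epoch stacks, and
# an on-the-fly BrainVision file writer for the reader tests.

test_montage <- function() standard_montage("10-20-20")

# Random average-referenced map array (subject x condition x channel x time).
random_maps <- function(n = 6, L = 2, K = 8, T = 3, sd = 1) {
  maps <- array(stats::rnorm(n * L * K * T, sd = sd), c(n, L, K, T))
  sweep(maps, c(1, 2, 4), apply(maps, c(1, 2, 4), mean))
}

random_epochs <- function(n_trials = 4, K = 20, fs = 250,
                          window = c(-100, 300), montage = test_montage()) {
  time <- seq(window[1], window[2], by = 1000 / fs)
  epoch_set(
    array(stats::rnorm(n_trials * K * length(time)), c(n_trials, K, length(time))),
    time = time, montage = montage, subject_id = "S001",
    condition = c(frequency = "0.5 Hz", location = "G1")
  )
}

# Write a minimal BrainVision file triplet; data is a channels x samples
# matrix of the values stored on disk (before resolution scaling for int16).
write_bv_fixture <- function(dir, name = "rec", data, resolution = 1,
                             format = c("INT_16", "IEEE_FLOAT_32"),
                             markers = list(), sampling_rate = 5000,
                             orientation = "MULTIPLEXED",
                             labels = paste0("Ch", seq_len(nrow(data)))) {
  format <- match.arg(format)
  K <- nrow(data)
  resolution <- rep(resolution, length.out = K)
  vhdr <- file.path(dir, paste0(name, ".vhdr"))
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", name, ".eeg"),
    paste0("MarkerFile=", name, ".vmrk"),
    "DataFormat=BINARY",
    paste0("DataOrientation=", orientation),
    paste0("NumberOfChannels=", K),
    paste0("SamplingInterval=", format(1e6 / sampling_rate, scientific = FALSE)),
    "[Binary Infos]",
    paste0("BinaryFormat=", format),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%g,µV", seq_len(K), labels, resolution)
  ), vhdr)
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", name, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0",
    if (length(markers)) {
      sprintf(
        "Mk%d=Stimulus,%s,%d,1,0",
        seq_along(markers) + 1,
        vapply(markers, `[[`, "", "code"),
        vapply(markers, function(m) as.integer(m$sample), 1L)
      )
    }
  ), file.path(dir, paste0(name, ".vmrk")))
  con <- file(file.path(dir, paste0(name, ".eeg")), "wb")
  vals <- as.vector(data) # multiplexed: channels fastest
  if (format == "INT_16") {
    writeBin(as.integer(round(vals)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 4, endian = "little")
  }
  close(con)
  vhdr
}

# Cartesian electrode positions of a montage (plain matrix).
montage_xyz_for_tests <- function(m) {
  out <- as.matrix(m[, c("x", "y", "z")])
  rownames(out) <- m$label
  out
}

# Four mutually orthogonal mean-zero unit-GFP template maps (K = 12).
orth_templates_acc <- function() {
  set.seed(303)
  M <- matrix(stats::rnorm(12 * 4), 4, 12)
  M <- M - rowMeans(M)
  M <- t(qr.Q(qr(t(M)))[, 1:4])
  M <- M - rowMeans(M)
  M / sqrt(rowMeans((M - rowMeans(M))^2))
}
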