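# Reader for a subset of the BrainVision format (.vhdr/.vmrk/.eeg):
# multiplexed IEEE float32 or int16 binary data with per-channel resolution.
# The vectorized binary layout and ASCII data are rejected explicitly.

# Parse an INI-style BrainVision header/marker file into named sections.
.parse_ini <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^﻿", "", lines) # strip BOM
  sections <- list()
  current <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, ";")) next
    if (grepl("^\\[.*\\]$", ln)) {
      current <- gsub("^\\[|\\]$", "", ln)
      sections[[current]] <- character()
    } else if (!is.null(current) && grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1, eq - 1))
      val <- substr(ln, eq + 1, nchar(ln))
      sections[[current]][key] <- val
    }
  }
  sections
}

.ini_get <- function(section, key) {
  if (is.null(section) || !key %in% names(section)) return(NULL)
  section[[key]]
}

.bv_companion <- function(vhdr_path, name) {
  # data/marker file names are given relative to the header's directory
  file.path(dirname(vhdr_path), name)
}

#' Read a BrainVision recording
#'
#' Reads the `.vhdr` header, the binary `.eeg` payload (multiplexed IEEE
#' float32 or int16 with per-channel resolution applied, yielding microvolts)
#' and stimulus markers from the `.vmrk` file. Marker positions in `.vmrk`
#' are 1-based sample indices and are kept 1-based.
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @param montage Optional `sep_montage` overriding the channel coordinates
#'   (labels must match the recorded channel order). When omitted, channel
#'   labels are taken from the header and coordinates are left unset unless
#'   all labels are part of the standard 10-10 set.
#' @return A `sep_continuous`.
#' @export
read_brainvision <- function(vhdr_path, montage = NULL) {
  if (!file.exists(vhdr_path)) abort(sprintf("header file not found: %s", vhdr_path))
  hdr <- .parse_ini(vhdr_path)
  ci <- hdr[["Common Infos"]]
  bi <- hdr[["Binary Infos"]]
  chs <- hdr[["Channel Infos"]]
  if (is.null(ci)) abort("malformed .vhdr: missing [Common Infos]")

  fmt <- toupper(.ini_get(ci, "DataFormat") %||% "BINARY")
  if (fmt != "BINARY") abort(sprintf("unsupported DataFormat '%s' (only BINARY)", fmt))
  orient <- toupper(.ini_get(ci, "DataOrientation") %||% "MULTIPLEXED")
  if (orient != "MULTIPLEXED") {
    abort(sprintf(
      "unsupported DataOrientation '%s': only the MULTIPLEXED dialect is supported",
      .ini_get(ci, "DataOrientation")
    ))
  }
  n_chan <- as.integer(.ini_get(ci, "NumberOfChannels"))
  fs <- 1e6 / as.numeric(.ini_get(ci, "SamplingInterval")) # header stores microseconds

  binfmt <- toupper(.ini_get(bi, "BinaryFormat") %||% "INT_16")
  if (!binfmt %in% c("INT_16", "IEEE_FLOAT_32")) {
    abort(sprintf("unsupported BinaryFormat '%s' (INT_16 or IEEE_FLOAT_32)", binfmt))
  }

  # Channel infos: "Ch<k>=<name>,<ref>,<resolution>,<unit>"
  labels <- character(n_chan)
  resolution <- rep(1, n_chan)
  for (k in seq_len(n_chan)) {
    entry <- .ini_get(chs, paste0("Ch", k))
    if (is.null(entry)) abort(sprintf("malformed .vhdr: missing Ch%d", k))
    parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
    labels[k] <- parts[1]
    if (length(parts) >= 3 && nzchar(trimws(parts[3]))) {
      resolution[k] <- as.numeric(parts[3])
    }
  }

  eeg_path <- .bv_companion(vhdr_path, .ini_get(ci, "DataFile"))
  if (!file.exists(eeg_path)) abort(sprintf("data file not found: %s", eeg_path))
  sz <- file.info(eeg_path)$size
  bytes <- if (binfmt == "INT_16") 2L else 4L
  n_samp <- as.integer(sz / (bytes * n_chan))
  con <- file(eeg_path, "rb")
  raw_vals <- if (binfmt == "INT_16") {
    readBin(con, "integer", n_chan * n_samp, size = 2, signed = TRUE, endian = "little")
  } else {
    readBin(con, "double", n_chan * n_samp, size = 4, endian = "little")
  }
  close(con)
  data <- matrix(as.numeric(raw_vals), nrow = n_chan) # multiplexed: channels vary fastest
  data <- data * resolution
  rownames(data) <- labels

  events <- tibble(sample = integer(), code = character())
  mrk_name <- .ini_get(ci, "MarkerFile")
  if (!is.null(mrk_name)) {
    mrk_path <- .bv_companion(vhdr_path, mrk_name)
    if (!file.exists(mrk_path)) abort(sprintf("marker file not found: %s", mrk_path))
    mrk <- .parse_ini(mrk_path)[["Marker Infos"]]
    if (!is.null(mrk)) {
      # "Mk<k>=<type>,<description>,<position>,<points>,<channel>"
      parts <- strsplit(unname(mrk), ",")
      keep <- vapply(parts, function(p) identical(trimws(p[1]), "Stimulus"), TRUE)
      parts <- parts[keep]
      if (length(parts)) {
        events <- tibble(
          sample = vapply(parts, function(p) as.integer(p[3]), 1L),
          code = vapply(parts, function(p) p[2], "")
        )
      }
    }
  }

  if (is.null(montage) && all(labels %in% .labels_6410)) {
    full <- standard_montage("10-10-64")
    montage <- full[match(labels, full$label), ]
    class(montage) <- class(full)
  }
  continuous_recording(data, fs,
    events = events, montage = montage,
    reference = .ini_get(ci, "Reference") %||% "Fz"
  )
}
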