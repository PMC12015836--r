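# BrainVision Core Data Format 1.0 reader/writer.
#
# A recording is a triplet: .vhdr (INI-style header), .vmrk (markers) and
# .eeg (raw binary). Supported binary dialects: IEEE_FLOAT_32 and INT_16
# (with per-channel Resolution scaling), in MULTIPLEXED or VECTORIZED
# orientation, little-endian. Everything else errors clearly.

parse_ini <- function(lines) {
  sec <- NULL; out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[sec]])) out[[sec]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && !is.null(sec)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1, eq - 1))
      out[[sec]][[key]] <- trimws(substr(ln, eq + 1, nchar(ln)))
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Reads the `.vhdr`/`.vmrk`/`.eeg` triplet named by the header path and
#' returns a [continuous_recording()] in microvolts, with markers resolved to
#' 1-based sample indices.
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @return A [continuous_recording()].
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stop("header file not found: ", vhdr_path)
  hdr <- parse_ini(readLines(vhdr_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: missing [Common Infos]")
  if (!identical(toupper(ci$DataFormat %||% "BINARY"), "BINARY"))
    stop("unsupported DataFormat '", ci$DataFormat, "' (only BINARY)")
  orientation <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  if (!orientation %in% c("MULTIPLEXED", "VECTORIZED"))
    stop("unsupported DataOrientation '", ci$DataOrientation, "'")
  nch <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)  # header stores microseconds
  fmt <- toupper(hdr[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")
  if (!fmt %in% c("IEEE_FLOAT_32", "INT_16"))
    stop("unsupported BinaryFormat '", fmt,
         "' (only IEEE_FLOAT_32 and INT_16)")

  chinfo <- hdr[["Channel Infos"]]
  if (is.null(chinfo) || length(chinfo) < nch)
    stop("channel count mismatch: header announces ", nch, " channels, [",
         "Channel Infos] lists ", length(chinfo))
  labels <- character(nch); resol <- rep(1, nch)
  for (i in seq_len(nch)) {
    parts <- strsplit(chinfo[[paste0("Ch", i)]], ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3]))
      resol[i] <- as.numeric(parts[3])
  }

  dir <- dirname(vhdr_path)
  eeg_path <- file.path(dir, ci$DataFile)
  if (!file.exists(eeg_path)) stop("data file not found: ", eeg_path)
  bytes_per <- if (fmt == "IEEE_FLOAT_32") 4L else 2L
  nvals <- file.size(eeg_path) / bytes_per
  if (nvals != round(nvals) || nvals %% nch != 0)
    stop("data file size inconsistent with ", nch, " channels")
  con <- file(eeg_path, "rb"); on.exit(close(con))
  raw_vals <- if (fmt == "IEEE_FLOAT_32")
    readBin(con, "numeric", n = nvals, size = 4, endian = "little")
  else
    readBin(con, "integer", n = nvals, size = 2, signed = TRUE,
            endian = "little")
  nsamp <- nvals / nch
  data <- if (orientation == "MULTIPLEXED")
    matrix(raw_vals, nrow = nch, ncol = nsamp)        # ch fastest
  else
    t(matrix(raw_vals, nrow = nsamp, ncol = nch))     # sample fastest
  data <- data * resol                                # to microvolts

  markers <- data.frame(sample = integer(0), label = character(0))
  if (!is.null(ci$MarkerFile)) {
    vmrk_path <- file.path(dir, ci$MarkerFile)
    if (!file.exists(vmrk_path)) stop("marker file not found: ", vmrk_path)
    mk <- parse_ini(readLines(vmrk_path, warn = FALSE))[["Marker Infos"]]
    if (length(mk)) {
      rows <- lapply(mk, function(v) strsplit(v, ",", fixed = TRUE)[[1]])
      keep <- vapply(rows, function(p) length(p) >= 3 &&
                       !identical(p[1], "New Segment"), logical(1))
      rows <- rows[keep]
      if (length(rows))
        markers <- data.frame(
          sample = vapply(rows, function(p) as.integer(p[3]), integer(1)),
          label = vapply(rows, function(p) p[2], character(1)))
    }
  }
  continuous_recording(data, fs, labels, markers)
}

#' Write a BrainVision recording
#'
#' Writes `rec` as a `.vhdr`/`.vmrk`/`.eeg` triplet. IEEE float 32 loses
#' nothing beyond float32 precision; INT_16 stores round(x / resolution).
#'
#' @param rec A [continuous_recording()].
#' @param path Base path without extension; the three files get their
#'   extensions appended.
#' @param binary_format `"IEEE_FLOAT_32"` (default) or `"INT_16"`.
#' @param orientation `"MULTIPLEXED"` (default) or `"VECTORIZED"`.
#' @param resolution Per-channel scaling written to the header (data are
#'   stored as value / resolution); scalar or one per channel.
#' @return Invisibly, the three file paths.
#' @export
write_brainvision <- function(rec, path, binary_format = "IEEE_FLOAT_32",
                              orientation = "MULTIPLEXED", resolution = 1) {
  stopifnot(inherits(rec, "ContinuousRecording"))
  binary_format <- toupper(binary_format)
  orientation <- toupper(orientation)
  if (!binary_format %in% c("IEEE_FLOAT_32", "INT_16"))
    stop("unsupported BinaryFormat '", binary_format, "'")
  if (!orientation %in% c("MULTIPLEXED", "VECTORIZED"))
    stop("unsupported DataOrientation '", orientation, "'")
  nch <- nrow(rec$data)
  resolution <- rep_len(resolution, nch)
  base <- basename(path)
  files <- paste0(path, c(".vhdr", ".vmrk", ".eeg"))

  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    paste0("DataOrientation=", orientation),
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / rec$sampling_rate,
                                       scientific = FALSE)),
    "",
    "[Binary Infos]",
    paste0("BinaryFormat=", binary_format),
    "",
    "[Channel Infos]",
    paste0("Ch", seq_len(nch), "=", rec$channel_labels, ",,",
           format(resolution, scientific = FALSE, trim = TRUE), ",µV"))
  writeLines(hdr, files[1], useBytes = TRUE)

  mk <- c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0",
    if (nrow(rec$markers))
      paste0("Mk", seq_len(nrow(rec$markers)) + 1, "=Stimulus,",
             rec$markers$label, ",", rec$markers$sample, ",1,0"))
  writeLines(mk, files[2])

  scaled <- rec$data / resolution
  vals <- if (orientation == "MULTIPLEXED") as.vector(scaled)
          else as.vector(t(scaled))
  con <- file(files[3], "wb")
  if (binary_format == "IEEE_FLOAT_32")
    writeBin(vals, con, size = 4, endian = "little")
  else {
    iv <- as.integer(round(vals))
    if (any(abs(iv) > 32767, na.rm = TRUE)) {
      close(con)
      stop("INT_16 overflow; increase resolution")
    }
    writeBin(iv, con, size = 2, endian = "little")
  }
  close(con)
  invisible(files)
}
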