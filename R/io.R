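# Signal and annotation file I/O: 16-bit PCM WAV, single-column text
# signals, and the onset/offset/label annotation CSV.

# --- minimal RIFF/WAVE (PCM) reader and writer -------------------------------
# Mono (or selectable-channel) 16/32-bit integer PCM only; little-endian.

read_wav_pcm <- function(path, channel = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1L, size = 2L,
                               endian = "little", signed = FALSE),
        n_channels = readBin(con, "integer", 1L, size = 2L,
                             endian = "little", signed = FALSE),
        sample_rate = readBin(con, "integer", 1L, size = 4L,
                              endian = "little"),
        byte_rate = readBin(con, "integer", 1L, size = 4L, endian = "little"),
        block_align = readBin(con, "integer", 1L, size = 2L,
                              endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1L, size = 2L, endian = "little",
                       signed = FALSE))
      extra <- size - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  if (fmt$audio_format != 1L)
    stop("only PCM WAV is supported", call. = FALSE)
  if (!fmt$bits %in% c(16L, 32L))
    stop("only 16- or 32-bit PCM WAV is supported", call. = FALSE)

  bytes <- fmt$bits %/% 8L
  vals <- readBin(data_raw, "integer", n = length(data_raw) %/% bytes,
                  size = bytes, endian = "little", signed = TRUE)
  if (fmt$n_channels > 1L) {
    if (is.null(channel))
      stop("multichannel WAV: specify `channel`", call. = FALSE)
    vals <- vals[seq(channel, length(vals), by = fmt$n_channels)]
  }
  list(samples = vals / 2^(fmt$bits - 1L), fs = fmt$sample_rate)
}

write_wav_pcm16 <- function(samples, fs, path) {
  peak <- max(abs(samples))
  if (peak > 1) samples <- samples / peak
  vals <- as.integer(round(samples * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(vals) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")                # PCM
  writeBin(1L, con, size = 2L, endian = "little")                # mono
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs) * 2L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(vals, con, size = 2L, endian = "little")
  invisible(path)
}

# --- public API --------------------------------------------------------------

#' Read an acoustic signal file
#'
#' Reads a 16/32-bit PCM WAV file or a single-column numeric text file into
#' an `"fpcg_record"`, normalizing the amplitude to unit peak. No resampling
#' is ever performed: when the file's sampling rate disagrees with
#' `expected_fs` a warning is raised and the file's own rate is kept.
#'
#' @param path Input file (`.wav` is read as WAV, anything else as
#'   whitespace/newline-separated numbers).
#' @param expected_fs Expected sampling rate in Hz; required for text input,
#'   checked against the header for WAV input.
#' @param channel Channel to extract from a multichannel WAV (1-based);
#'   reading a multichannel file without it is an error.
#' @return An `"fpcg_record"` (without ground truth).
#' @export
read_signal <- function(path, expected_fs = NULL, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  is_wav <- grepl("\\.wav$", path, ignore.case = TRUE)
  if (is_wav) {
    w <- read_wav_pcm(path, channel = channel)
    samples <- w$samples
    fs <- w$fs
    if (!is.null(expected_fs) && fs != expected_fs)
      warning("file sampling rate (", fs, " Hz) differs from expected (",
              expected_fs, " Hz); no resampling performed")
  } else {
    if (is.null(expected_fs))
      stop("expected_fs is required for text signal files", call. = FALSE)
    samples <- scan(path, what = numeric(), quiet = TRUE)
    fs <- expected_fs
  }
  if (!length(samples)) stop("empty signal file: ", path, call. = FALSE)
  peak <- max(abs(samples))
  if (peak > 0) samples <- samples / peak
  structure(list(samples = samples, clean = NULL, noise = numeric(0),
                 fs = fs, truth = NULL, snr_db = NA_real_,
                 condition = NULL, seed = NA_integer_),
            class = "fpcg_record")
}

#' Write an acoustic signal file
#'
#' Writes a record (or numeric vector) as 16-bit PCM WAV or as a
#' one-number-per-line text file.
#'
#' @param x An `"fpcg_record"` or numeric vector.
#' @param path Output path; `.wav` selects WAV, anything else text.
#' @param fs Sampling rate in Hz (taken from the record when given).
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path, fs = NULL) {
  if (inherits(x, "fpcg_record")) {
    fs <- x$fs
    x <- x$samples
  }
  if (grepl("\\.wav$", path, ignore.case = TRUE)) {
    if (is.null(fs)) stop("fs is required to write WAV", call. = FALSE)
    write_wav_pcm16(x, fs, path)
  } else {
    writeLines(format(x, digits = 17, scientific = FALSE, trim = TRUE), path)
  }
  invisible(path)
}

#' Read or write a beat annotation file
#'
#' Annotations are CSV files with header `onset_s,offset_s,label`, one row
#' per sound, labels restricted to S1/S2, times in seconds. The same schema
#' is used for simulator ground truth ([beat_intervals()]) and for detector
#' output ([detection_intervals()]), so the two can be diffed directly.
#'
#' @param path File path.
#' @return `read_annotations()` returns a data.frame with columns `onset_s`,
#'   `offset_s`, `label` (zero rows for an empty file). Malformed rows or
#'   labels raise an error naming the offending line.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  header <- trimws(strsplit(lines[1L], ",")[[1L]])
  if (!identical(header, c("onset_s", "offset_s", "label")))
    stop("bad annotation header (expected onset_s,offset_s,label): line 1",
         call. = FALSE)
  if (length(lines) == 1L) return(empty)
  rows <- vector("list", length(lines) - 1L)
  for (i in 2L:length(lines)) {
    parts <- trimws(strsplit(lines[i], ",")[[1L]])
    if (length(parts) != 3L)
      stop("malformed annotation row at line ", i, call. = FALSE)
    onset <- suppressWarnings(as.numeric(parts[1L]))
    offset <- suppressWarnings(as.numeric(parts[2L]))
    if (is.na(onset) || is.na(offset))
      stop("non-numeric onset/offset at line ", i, call. = FALSE)
    if (!parts[3L] %in% c("S1", "S2"))
      stop("invalid label '", parts[3L], "' at line ", i,
           " (must be S1 or S2)", call. = FALSE)
    rows[[i - 1L]] <- data.frame(onset_s = onset, offset_s = offset,
                                 label = parts[3L], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @rdname read_annotations
#' @param annotations A data.frame with `onset_s`, `offset_s`, `label`
#'   columns, a `"beat_timeline"`, or an `"fhs_detection"`.
#' @param fs Sampling rate (needed only when `annotations` is a raw
#'   `"labeled_sounds"` table without an `fs` attribute).
#' @export
write_annotations <- function(annotations, path, fs = NULL) {
  if (inherits(annotations, "beat_timeline"))
    annotations <- beat_intervals(annotations)
  if (inherits(annotations, "fhs_detection"))
    annotations <- detection_intervals(annotations)
  if (inherits(annotations, "labeled_sounds"))
    annotations <- detection_intervals(annotations, fs = fs)
  stopifnot(all(c("onset_s", "offset_s", "label") %in% names(annotations)))
  lines <- c("onset_s,offset_s,label",
             sprintf("%.6f,%.6f,%s", annotations$onset_s,
                     annotations$offset_s, annotations$label))
  writeLines(lines, path)
  invisible(path)
}
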