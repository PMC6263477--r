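#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the dialect the acquisition pipeline produces:
#' uncompressed 16-bit PCM, single channel, little-endian. Recordings must be
#' sampled at 10 kHz; any other rate is rejected, mirroring the acquisition
#' app's sampling-frequency validation. Stereo or non-PCM files are rejected
#' rather than silently converted.
#'
#' @param path Path to a WAV file.
#' @param label Optional auscultation-point label attached to the recording.
#' @return A raw-stage [sound_recording()] with samples scaled by 1/32767,
#'   the inverse of [write_wav()]'s quantization.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2, endian = "little"),
        n_channels   = readBin(con, "integer", 1, size = 2, endian = "little"),
        sample_rate  = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, size = 2, endian = "little"),
        bits         = readBin(con, "integer", 1, size = 2, endian = "little")
      )
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("corrupt WAV (missing chunk): ", path)
  if (fmt$audio_format != 1L) stop("unsupported WAV encoding (PCM required)")
  if (fmt$n_channels != 1L) stop("stereo input rejected: mono WAV required")
  if (fmt$bits != 16L) stop("unsupported bit depth ", fmt$bits, " (16-bit required)")
  .check_fs_10k(fmt$sample_rate)

  ints <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L,
                  size = 2, signed = TRUE, endian = "little")
  sound_recording(ints / 32767, fs = fmt$sample_rate, label = label,
                  stage = "raw")
}

#' Write a recording as a mono 16-bit PCM WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantized to 16 bits. The inverse of
#' [read_wav()] up to that quantization.
#'
#' @param rec A [sound_recording()] (any stage).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "sound_recording"))
  x <- pmax(-1, pmin(1, rec$samples))
  ints <- as.integer(round(x * 32767))
  n_bytes <- length(ints) * 2L
  con <- file(path, "wb")
  on.exit(close(con))

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")               # PCM
  writeBin(1L, con, size = 2, endian = "little")               # mono
  writeBin(as.integer(rec$fs), con, size = 4, endian = "little")
  writeBin(as.integer(rec$fs * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")               # block align
  writeBin(16L, con, size = 2, endian = "little")              # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}

#' Export a signal as plain text, one sample value per line
#'
#' @param rec A [sound_recording()] or numeric vector.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_signal_text <- function(rec, path) {
  x <- if (inherits(rec, "sound_recording")) rec$samples else as.numeric(rec)
  writeLines(formatC(x, format = "g", digits = 9), path)
  invisible(path)
}
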