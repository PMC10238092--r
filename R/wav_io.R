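# Minimal RIFF/WAVE reader and writer for IEEE float-32 PCM.
# Only what the HRIR manifest dialect needs: interleaved multi-channel
# float32, standard fmt/data chunks, little-endian. No compression, no
# cue/metadata chunks (unknown chunks are skipped on read).

WAVE_FORMAT_IEEE_FLOAT <- 3L

#' Write an IEEE float-32 WAV file
#'
#' @param path Output file path.
#' @param samples Numeric matrix, one column per channel (a vector is taken
#'   as one channel). Values are stored as 32-bit floats, so the round trip
#'   is exact at float32 precision.
#' @param sample_rate_hz Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav_float <- function(path, samples, sample_rate_hz) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  stopifnot(is.matrix(samples), is.numeric(samples))
  n_chan <- ncol(samples)
  n_frames <- nrow(samples)
  block_align <- 4L * n_chan
  data_bytes <- block_align * n_frames

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write WAV file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  w_u32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                                endian = "little")
  w_u16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                                endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w_u32(36L + data_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w_u32(16L)
  w_u16(WAVE_FORMAT_IEEE_FLOAT)
  w_u16(n_chan)
  w_u32(sample_rate_hz)
  w_u32(sample_rate_hz * block_align)   # byte rate
  w_u16(block_align)
  w_u16(32L)                            # bits per sample
  writeChar("data", con, eos = NULL)
  w_u32(data_bytes)
  # interleave channels frame by frame
  writeBin(as.numeric(t(samples)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an IEEE float-32 WAV file
#'
#' @param path Input file path.
#' @return List with `samples` (numeric matrix, one column per channel) and
#'   `sample_rate_hz`.
#' @export
read_wav_float <- function(path) {
  if (!file.exists(path)) {
    stop("WAV file not found: '", path, "'", call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  r_u32 <- function() readBin(con, "integer", size = 4L, endian = "little")
  r_u16 <- function() readBin(con, "integer", size = 2L, endian = "little",
                              signed = FALSE)
  tag <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(tag, "RIFF")) {
    stop("'", path, "' is not a RIFF/WAVE file", call. = FALSE)
  }
  r_u32()
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE")) {
    stop("'", path, "' is not a RIFF/WAVE file", call. = FALSE)
  }
  fmt <- NULL
  samples <- NULL
  repeat {
    chunk <- readChar(con, 4L, useBytes = TRUE)
    if (length(chunk) == 0L || nchar(chunk) < 4L) break
    size <- r_u32()
    if (identical(chunk, "fmt ")) {
      fmt <- list(format = r_u16(), n_chan = r_u16(),
                  sample_rate = r_u32(), byte_rate = r_u32(),
                  block_align = r_u16(), bits = r_u16())
      if (size > 16L) readBin(con, "raw", n = size - 16L)
    } else if (identical(chunk, "data")) {
      if (is.null(fmt)) stop("WAV data chunk before fmt chunk", call. = FALSE)
      if (fmt$format != WAVE_FORMAT_IEEE_FLOAT || fmt$bits != 32L) {
        stop("'", path, "' is not 32-bit float WAV (format ", fmt$format,
             ", ", fmt$bits, " bits)", call. = FALSE)
      }
      n_vals <- size %/% 4L
      x <- readBin(con, "numeric", n = n_vals, size = 4L, endian = "little")
      samples <- matrix(x, ncol = fmt$n_chan, byrow = TRUE)
      if (size %% 2L == 1L) readBin(con, "raw", n = 1L)
    } else {
      # skip unknown chunk (word-aligned)
      readBin(con, "raw", n = size + size %% 2L)
    }
    if (!is.null(samples) && !is.null(fmt)) break
  }
  if (is.null(samples)) {
    stop("no data chunk found in '", path, "'", call. = FALSE)
  }
  list(samples = samples, sample_rate_hz = fmt$sample_rate)
}
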