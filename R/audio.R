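#' Audio segment container
#'
#' A lightweight container for a mono audio segment: a numeric sample vector,
#' its sample rate in Hz, and the segment start time in seconds since the
#' dataset origin.
#'
#' @param samples Numeric vector of finite sample amplitudes.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param start_time Start time of the first sample, seconds since origin.
#' @return An object of class `audio_segment`.
#' @export
audio_segment <- function(samples, sample_rate, start_time = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("audio_segment: empty sample vector")
  if (!all(is.finite(samples))) stop("audio_segment: non-finite samples")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("audio_segment: sample_rate must be a positive scalar")
  structure(
    list(samples = samples, sample_rate = sample_rate, start_time = start_time),
    class = "audio_segment"
  )
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf(
    "<audio_segment> %d samples @ %g Hz (%.3f s), t0 = %.3f s\n",
    length(x$samples), x$sample_rate,
    length(x$samples) / x$sample_rate, x$start_time
  ))
  invisible(x)
}

#' @export
length.audio_segment <- function(x) length(x$samples)

#' Duration of an audio segment in seconds
#' @param seg An `audio_segment`.
#' @return Duration in seconds.
#' @export
segment_duration <- function(seg) length(seg$samples) / seg$sample_rate

#' Turn an audio segment into a tibble
#'
#' @param x An `audio_segment`.
#' @param ... Unused.
#' @return A tibble with columns `time` (s) and `amplitude`.
#' @export
tidy.audio_segment <- function(x, ...) {
  tibble::tibble(
    time = x$start_time + (seq_along(x$samples) - 1) / x$sample_rate,
    amplitude = x$samples
  )
}

# ---- PCM WAV I/O (hand-rolled: no audio package in the environment) --------

#' Write a mono PCM WAV file
#'
#' Writes 16- or 24-bit little-endian PCM. Samples are clipped to [-1, 1).
#'
#' @param seg An `audio_segment`.
#' @param path Output file path.
#' @param bits Bits per sample: 16 or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(seg, path, bits = 16) {
  stopifnot(inherits(seg, "audio_segment"), bits %in% c(16, 24))
  x <- pmin(pmax(seg$samples, -1), 1 - 2^-(bits - 1))
  n <- length(x)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(seg$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(seg$sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  q <- round(x * 2^(bits - 1))
  if (bits == 16) {
    writeBin(as.integer(q), con, size = 2, endian = "little")
  } else {
    q <- as.integer(q)
    neg <- q < 0
    u <- ifelse(neg, q + 16777216, q) # two's complement in 24 bits
    raw3 <- as.raw(rbind(u %% 256L, (u %/% 256L) %% 256L, (u %/% 65536L) %% 256L))
    writeBin(raw3, con)
  }
  invisible(path)
}

#' Read a mono PCM WAV file
#'
#' Supports 16- and 24-bit little-endian PCM, single channel.
#'
#' @param path WAV file path.
#' @param start_time Start time attached to the returned segment (seconds).
#' @return An `audio_segment` with samples scaled to [-1, 1).
#' @export
read_wav <- function(path, start_time = 0) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) stop("read_wav: not a RIFF file: ", path)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("read_wav: not a WAVE file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("read_wav: no data chunk found")
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", size = 2, endian = "little"),
        channels = readBin(con, "integer", size = 2, endian = "little"),
        sample_rate = readBin(con, "integer", size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", size = 4, endian = "little"),
        block_align = readBin(con, "integer", size = 2, endian = "little"),
        bits = readBin(con, "integer", size = 2, endian = "little")
      )
      if (size > 16) invisible(readBin(con, "raw", n = size - 16))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("read_wav: data chunk before fmt chunk")
      if (fmt$channels != 1L) stop("read_wav: only mono supported")
      if (fmt$audio_format != 1L) stop("read_wav: only PCM supported")
      if (fmt$bits == 16) {
        q <- readBin(con, "integer", n = size / 2, size = 2,
                     endian = "little", signed = TRUE)
        x <- q / 32768
      } else if (fmt$bits == 24) {
        raw3 <- readBin(con, "raw", n = size)
        m <- matrix(as.integer(raw3), nrow = 3)
        u <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        q <- ifelse(u >= 8388608, u - 16777216, u)
        x <- q / 8388608
      } else stop("read_wav: unsupported bit depth ", fmt$bits)
      return(audio_segment(x, fmt$sample_rate, start_time))
    } else {
      invisible(readBin(con, "raw", n = size + (size %% 2L)))
    }
  }
}
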