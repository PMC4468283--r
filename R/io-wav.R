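# RIFF/WAVE reading and writing (PCM 8/16/24/32-bit and IEEE float).
# Amplitudes are mapped to floating point in [-1, 1] regardless of the
# source bit depth; multi-channel data is returned as a samples x channels
# matrix.

#' Read a RIFF/WAVE file
#'
#' @param path path to a PCM or IEEE-float WAV file.
#' @return list with `samples` (matrix, samples x channels, amplitudes in
#'   \[-1, 1\]) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    voq_stop("voq_format_error", "not a RIFF file: %s", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    voq_stop("voq_format_error", "not a WAVE file: %s", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2L)
      next
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    voq_stop("voq_format_error", "missing fmt or data chunk: %s", path)
  af <- fmt$audio_format
  if (af == 65534L) af <- 1L  # WAVE_FORMAT_EXTENSIBLE, assume PCM payload
  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% (bytes * fmt$n_channels)
  if (af == 1L) {
    x <- switch(as.character(fmt$bits),
      "8"  = (as.numeric(readBin(data_raw, "integer", n * fmt$n_channels, 1,
                                 signed = FALSE)) - 128) / 128,
      "16" = readBin(data_raw, "integer", n * fmt$n_channels, 2,
                     signed = TRUE, endian = "little") / 32768,
      "24" = read_pcm24(data_raw, n * fmt$n_channels),
      "32" = readBin(data_raw, "integer", n * fmt$n_channels, 4,
                     endian = "little") / 2147483648,
      voq_stop("voq_format_error", "unsupported PCM bit depth %d", fmt$bits))
  } else if (af == 3L) {
    x <- readBin(data_raw, "double", n * fmt$n_channels, bytes, endian = "little")
  } else {
    voq_stop("voq_format_error",
             "unsupported (compressed?) WAV format code %d", fmt$audio_format)
  }
  list(samples = matrix(x, ncol = fmt$n_channels, byrow = TRUE),
       sample_rate = fmt$sample_rate)
}

read_pcm24 <- function(raw, n) {
  b <- matrix(as.integer(raw[seq_len(3 * n)]), nrow = 3)
  v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
  v <- ifelse(v >= 8388608, v - 16777216, v)
  v / 8388608
}

#' Write a RIFF/WAVE file
#'
#' @param samples numeric vector (mono) or samples x channels matrix in \[-1, 1\].
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @export
write_wav <- function(samples, sample_rate, path, bits = 16) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  n_ch <- ncol(samples)
  interleaved <- as.numeric(t(samples))
  if (bits == 16) {
    fmt_code <- 1L
    pcm <- as.integer(pmax(pmin(round(interleaved * 32768), 32767), -32768))
    payload_size <- length(pcm) * 2L
  } else if (bits == 32) {
    fmt_code <- 3L
    payload_size <- length(interleaved) * 4L
  } else voq_stop("voq_format_error", "bits must be 16 or 32")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + payload_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(as.integer(n_ch), con, 2, endian = "little")
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  byte_rate <- as.integer(sample_rate * n_ch * bits / 8)
  writeBin(byte_rate, con, 4, endian = "little")
  writeBin(as.integer(n_ch * bits / 8), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(payload_size), con, 4, endian = "little")
  if (bits == 16) writeBin(pcm, con, 2, endian = "little")
  else writeBin(interleaved, con, 4, endian = "little")
  invisible(path)
}

#' Load a recording (speech + optional electroglottogram)
#'
#' Reads one or two WAV files, routes channels, and conditions the speech
#' signal for analysis: resampling to 16 kHz with a polyphase anti-aliasing
#' filter. The EGG channel is kept at its native rate.
#'
#' @param audio_path WAV file containing the speech (and possibly EGG) channel.
#' @param egg_path optional separate WAV file with the EGG signal.
#' @param channel_map for multi-channel files, a list like
#'   `list(speech = 1, egg = 2)` (1-based channel indices).
#' @param id recording identifier; defaults to the audio file name.
#' @return an object of class `voq_recording` with elements `id`, `speech`
#'   (numeric, 16 kHz), `speech_rate`, `egg` (numeric or NULL), `egg_rate`,
#'   `duration` (seconds).
#' @export
read_recording <- function(audio_path, egg_path = NULL, channel_map = NULL,
                           id = NULL) {
  w <- read_wav(audio_path)
  n_ch <- ncol(w$samples)
  if (is.null(channel_map))
    channel_map <- if (n_ch >= 2 && is.null(egg_path))
      list(speech = 1L, egg = 2L) else list(speech = 1L)
  for (ch in unlist(channel_map))
    if (ch < 1 || ch > n_ch)
      voq_stop("voq_config_error",
               "channel_map references channel %d but file has %d", ch, n_ch)
  speech <- w$samples[, channel_map$speech]
  egg <- NULL; egg_rate <- NULL
  if (!is.null(egg_path)) {
    we <- read_wav(egg_path)
    egg <- we$samples[, 1]
    egg_rate <- we$sample_rate
  } else if (!is.null(channel_map$egg)) {
    egg <- w$samples[, channel_map$egg]
    egg_rate <- w$sample_rate
  }
  new_recording(id = id %||% sub("\\.wav$", "", basename(audio_path),
                                 ignore.case = TRUE),
                speech = speech, speech_rate = w$sample_rate,
                egg = egg, egg_rate = egg_rate)
}

#' Construct a recording object from in-memory signals
#'
#' Speech is resampled to the 16 kHz analysis rate if supplied at another
#' rate; amplitudes are expected in \[-1, 1\].
#'
#' @param id recording identifier.
#' @param speech numeric waveform.
#' @param speech_rate its sampling rate (Hz).
#' @param egg optional EGG waveform; `egg_rate` its rate.
#' @param egg_rate sampling rate of the EGG waveform (Hz).
#' @export
new_recording <- function(id, speech, speech_rate, egg = NULL, egg_rate = NULL) {
  target <- 16000L
  if (speech_rate != target) {
    g <- gcd2(target, speech_rate)
    speech <- as.numeric(signal::resample(speech, target / g, speech_rate / g))
    # polyphase output length can differ by a sample; fix to exact rate math
    n_out <- round(length(speech))
    speech <- speech[seq_len(n_out)]
    speech_rate <- target
  }
  rec <- structure(list(
    id = as.character(id),
    speech = as.numeric(speech),
    speech_rate = as.integer(speech_rate),
    egg = if (is.null(egg)) NULL else as.numeric(egg),
    egg_rate = if (is.null(egg)) NULL else as.integer(egg_rate),
    duration = length(speech) / speech_rate
  ), class = "voq_recording")
  rec
}

#' @export
print.voq_recording <- function(x, ...) {
  cat(sprintf("<voq_recording '%s': %.2f s speech @ %d Hz%s>\n",
              x$id, x$duration, x$speech_rate,
              if (is.null(x$egg)) ""
              else sprintf(", EGG @ %d Hz", x$egg_rate)))
  invisible(x)
}
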