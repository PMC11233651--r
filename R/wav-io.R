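#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' Samples are expected in \[-1, 1\] and are clipped before quantisation.
#'
#' @param samples Numeric vector of audio samples.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  pcm <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return List with `samples` (numeric in \[-1, 1\]) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop_pataka(sprintf("'%s' is not a RIFF/WAVE file", path), "pataka_io_error")
  sample_rate <- NULL; bits <- NULL; channels <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4)
      stop_pataka(sprintf("'%s': no data chunk found", path), "pataka_io_error")
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      channels <- fmt[2]
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      skip <- size - 16L
      if (skip > 0) readBin(con, "raw", n = skip)
    } else if (identical(id, "data")) {
      if (is.null(sample_rate))
        stop_pataka(sprintf("'%s': data chunk before fmt", path), "pataka_io_error")
      if (bits != 16L || channels != 1L)
        stop_pataka(sprintf("'%s': only 16-bit mono PCM supported", path),
                    "pataka_io_error")
      pcm <- readBin(con, "integer", n = size %/% 2L, size = 2,
                     endian = "little", signed = TRUE)
      return(list(samples = pcm / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, "raw", n = size + size %% 2L)
    }
  }
}
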