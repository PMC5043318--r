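# Minimal mono 16-bit PCM WAV I/O. No audio package ships with the
# analysis stack, and the generator only needs plain uncompressed
# waveform files, so the RIFF header is handled directly.

#' Write a mono waveform as a 16-bit PCM WAV file
#'
#' @param wave numeric vector in \[-1, 1\] (values are clipped).
#' @param path output file path.
#' @param sample_rate sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sample_rate = 44100) {
  samples <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  n <- length(samples)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")    # PCM
  writeBin(1L, con, size = 2, endian = "little")    # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")    # block align
  writeBin(16L, con, size = 2, endian = "little")   # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(samples, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path file path.
#' @return list with `wave` (numeric in \[-1, 1\]) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAV file: ", path)
  sample_rate <- NULL
  bits <- NULL
  channels <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1) stop("only PCM WAV supported")
      channels <- fmt[2]
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) readBin(con, raw(), n = size - 16)
    } else if (id == "data") {
      if (is.null(bits)) stop("malformed WAV: data before fmt chunk")
      if (bits != 16 || channels != 1) {
        stop("only mono 16-bit PCM WAV supported")
      }
      samples <- readBin(con, integer(), n = size / 2, size = 2,
                         signed = TRUE, endian = "little")
      return(list(wave = samples / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, raw(), n = size)
    }
  }
}
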