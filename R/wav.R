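# Minimal RIFF/WAVE PCM I/O (16- or 24-bit). Mono in the generator;
# stereo files are accepted on read and downmixed by channel averaging.

#' Write a mono waveform to a PCM WAV file
#'
#' @param samples numeric vector in [-1, 1].
#' @param sampleRate sampling rate in Hz.
#' @param path output file.
#' @param bits 16 or 24.
#' @return `path`, invisibly.
#' @export
writeWav <- function(samples, sampleRate, path, bits = 16L) {
  stopifnot(bits %in% c(16L, 24L), sampleRate > 0)
  if (any(abs(samples) > 1 + 1e-9))
    stop("samples out of [-1, 1] when writing ", path)
  n <- length(samples)
  bytesPer <- bits / 8L
  dataLen <- n * bytesPer
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataLen), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")            # PCM
  writeBin(1L, con, size = 2L, endian = "little")            # mono
  writeBin(as.integer(sampleRate), con, size = 4L, endian = "little")
  writeBin(as.integer(sampleRate * bytesPer), con, size = 4L,
           endian = "little")
  writeBin(as.integer(bytesPer), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataLen), con, size = 4L, endian = "little")
  full <- 2^(bits - 1L)
  q <- as.integer(pmax(pmin(round(samples * full), full - 1L), -full))
  if (bits == 16L) {
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    # 24-bit: little-endian byte triplets
    u <- ifelse(q < 0L, q + 16777216, q)
    b <- rbind(u %% 256L, (u %/% 256L) %% 256L, (u %/% 65536L) %% 256L)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}

#' Read a PCM WAV file
#'
#' Stereo content is downmixed to mono by averaging channels.
#'
#' @param path WAV file.
#' @return list with `samples` (numeric in [-1, 1]) and `sampleRate`.
#' @export
readWav <- function(path) {
  if (!file.exists(path)) stop("no such WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4L) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  if (readChar(con, 4L) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4L)
    if (!length(id) || !nzchar(id)) stop("no data chunk in ", path)
    len <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audioFormat = readBin(con, "integer", 1L, 2L, endian = "little"),
        channels = readBin(con, "integer", 1L, 2L, endian = "little"),
        sampleRate = readBin(con, "integer", 1L, 4L, endian = "little"),
        byteRate = readBin(con, "integer", 1L, 4L, endian = "little"),
        blockAlign = readBin(con, "integer", 1L, 2L, endian = "little"),
        bits = readBin(con, "integer", 1L, 2L, endian = "little")
      )
      if (len > 16L) invisible(readBin(con, "raw", len - 16L))
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt in ", path)
      if (fmt$audioFormat != 1L)
        stop("only PCM WAV supported: ", path)
      bytesPer <- fmt$bits / 8L
      n <- len / bytesPer
      if (fmt$bits == 16L) {
        x <- readBin(con, "integer", n, 2L, signed = TRUE,
                     endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        raw <- as.integer(readBin(con, "raw", len))
        m <- matrix(raw, nrow = 3L)
        u <- m[1L, ] + 256L * m[2L, ] + 65536 * m[3L, ]
        x <- ifelse(u >= 8388608, u - 16777216, u) / 8388608
      } else stop("unsupported bit depth ", fmt$bits, " in ", path)
      if (fmt$channels > 1L) {
        x <- colMeans(matrix(x, nrow = fmt$channels))
      }
      return(list(samples = x, sampleRate = fmt$sampleRate))
    } else {
      invisible(readBin(con, "raw", len + len %% 2L))
    }
  }
}
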