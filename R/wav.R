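## Minimal RIFF/WAV reader and writer ----------------------------------------
##
## Supports the formats used by field recorders: PCM 16-bit, PCM 24-bit and
## IEEE float 32-bit, any channel count, interleaved. (No audio package is
## available in the target environment, and the container is a simple
## chunked binary format.)

#' Write a multichannel WAV file
#'
#' @param samples channels x time numeric matrix; float output is written
#'   verbatim, PCM output is clipped to [-1, 1] and quantized.
#' @param rate sample rate in Hz.
#' @param path output file.
#' @param bits 16 or 24 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path, bits = 32L) {
  samples <- as.matrix(samples)
  if (!bits %in% c(16L, 24L, 32L)) stop2("bits must be 16, 24 or 32")
  nch <- nrow(samples)
  n <- ncol(samples)
  inter <- as.vector(samples)                    # column-major = interleaved
  bytes_per <- bits %/% 8L
  data_size <- n * nch * bytes_per
  fmt_code <- if (bits == 32L) 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(nch, con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * nch * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(nch * bytes_per), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 32L) {
    writeBin(inter, con, size = 4, endian = "little")
  } else if (bits == 16L) {
    q <- as.integer(round(pmax(pmin(inter, 1), -1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    q <- round(pmax(pmin(inter, 1), -1) * 8388607)
    q <- ifelse(q < 0, q + 16777216, q)          # two's complement, 24-bit
    b <- matrix(0L, 3, length(q))
    b[1, ] <- q %% 256
    b[2, ] <- (q %/% 256) %% 256
    b[3, ] <- (q %/% 65536) %% 256
    writeBin(as.raw(b), con)
  }
  invisible(path)
}

#' Read a WAV file
#'
#' @param path WAV file (PCM 16/24-bit or float 32-bit).
#' @return list: `samples` (channels x time, float in roughly [-1, 1] for
#'   PCM input), `rate`, `bits`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop2("WAV file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop2("%s is not a RIFF/WAVE file", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, raw(), n = size)
      u16 <- function(o) as.integer(fmt_raw[o]) + 256L * as.integer(fmt_raw[o + 1])
      u32 <- function(o) u16(o) + 65536 * u16(o + 2)
      fmt <- list(code = u16(1), channels = u16(3), rate = u32(5),
                  bits = u16(15))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, raw(), n = size)
    } else {
      readBin(con, raw(), n = size + size %% 2)  # skip (chunks are padded)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop2("%s: missing fmt/data chunk", path)
  nch <- fmt$channels
  if (fmt$code == 3L || (fmt$code == 1L && fmt$bits == 32L && FALSE)) {
    vals <- readBin(data_raw, numeric(), n = length(data_raw) %/% 4, size = 4,
                    endian = "little")
  } else if (fmt$code == 1L && fmt$bits == 16L) {
    vals <- readBin(data_raw, integer(), n = length(data_raw) %/% 2, size = 2,
                    signed = TRUE, endian = "little") / 32767
  } else if (fmt$code == 1L && fmt$bits == 24L) {
    b <- as.integer(data_raw)
    n3 <- length(b) %/% 3
    dim(b) <- c(3, n3)
    q <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    q <- ifelse(q >= 8388608, q - 16777216, q)
    vals <- q / 8388607
  } else {
    stop2("%s: unsupported WAV encoding (format %d, %d bits)",
          path, fmt$code, fmt$bits)
  }
  list(samples = matrix(vals, nrow = nch), rate = fmt$rate, bits = fmt$bits)
}
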