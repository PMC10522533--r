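#' Read a mono RIFF WAV file
#'
#' Supports uncompressed PCM (16- or 24-bit) and IEEE float32 mono files.
#' Samples are returned scaled to \[-1, 1\] for PCM and as stored for float.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")   # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels   = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data): ", path)
  if (fmt$n_channels != 1L) stop("only mono WAV supported (got ", fmt$n_channels, " channels)")

  x <- switch(as.character(fmt$audio_format),
    "1" = {  # integer PCM
      if (fmt$bits == 16L) {
        readBin(data_raw, "integer", length(data_raw) %/% 2L, 2, signed = TRUE,
                endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        n <- length(data_raw) %/% 3L
        b <- as.integer(data_raw)
        v <- b[seq(1, 3 * n, 3)] + 256 * b[seq(2, 3 * n, 3)] + 65536 * b[seq(3, 3 * n, 3)]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else stop("unsupported PCM bit depth: ", fmt$bits)
    },
    "3" = readBin(data_raw, "double", length(data_raw) %/% 4L, 4, endian = "little"),
    stop("unsupported WAV audio format code: ", fmt$audio_format))
  waveform(x, fmt$sample_rate, label = basename(path))
}

#' Write a mono waveform as RIFF WAV
#'
#' @param w A [waveform].
#' @param path Output path.
#' @param bits One of 16, 24 (integer PCM; samples are clipped to \[-1, 1\])
#'   or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bits = 16) {
  stopifnot(inherits(w, "waveform"), bits %in% c(16, 24, 32))
  n <- length(w$samples)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  fmt_code <- if (bits == 32) 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                      # mono
  writeBin(as.integer(w$rate), con, 4, endian = "little")
  writeBin(as.integer(w$rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    v <- pmin(pmax(w$samples, -1), 32767 / 32768)
    writeBin(as.integer(round(v * 32768)), con, 2, endian = "little")
  } else if (bits == 24) {
    v <- pmin(pmax(w$samples, -1), 8388607 / 8388608)
    iv <- as.integer(round(v * 8388608))
    iv <- ifelse(iv < 0, iv + 16777216L, iv)
    b <- rbind(iv %% 256L, (iv %/% 256L) %% 256L, iv %/% 65536L)
    writeBin(as.raw(as.vector(b)), con)
  } else {
    writeBin(w$samples, con, 4, endian = "little")
  }
  invisible(path)
}
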