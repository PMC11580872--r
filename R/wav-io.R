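#' Write a stimulus (or any stereo pair) as a WAV file
#'
#' Minimal RIFF/WAVE writer: 16-bit PCM or 32-bit IEEE float, two channels.
#' Samples outside \[-1, 1\] trigger a warning and the whole waveform is
#' rescaled to peak 1 before quantization.
#'
#' @param stimulus a `dichotic_stimulus` (see [synthesize_stimulus()]) or a
#'   list with `left`, `right`, `sample_rate`.
#' @param path output file path.
#' @param bit_depth 16 (PCM) or 32 (float); default 16.
#' @return `path`, invisibly.
#' @export
write_stimulus_wav <- function(stimulus, path, bit_depth = 16) {
  if (!bit_depth %in% c(16, 32)) stop("bit_depth must be 16 or 32")
  l <- stimulus$left
  r <- stimulus$right
  if (is.null(l) || is.null(r)) stop("stimulus must have two channels")
  stopifnot(length(l) == length(r))
  peak <- max(abs(c(l, r)), 0)
  if (peak > 1) {
    warning("samples exceed [-1, 1]; rescaling to peak 1")
    l <- l / peak
    r <- r / peak
  }
  fs <- as.integer(stimulus$sample_rate)
  inter <- as.vector(rbind(l, r)) # interleave L/R frames
  block_align <- as.integer(2 * bit_depth / 8)
  data_bytes <- as.integer(length(inter) * bit_depth / 8)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  fmt <- if (bit_depth == 16) 1L else 3L # PCM vs IEEE float
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * block_align), con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (bit_depth == 16) {
    writeBin(
      as.integer(round(pmax(pmin(inter, 1), -1) * 32767)),
      con,
      size = 2, endian = "little"
    )
  } else {
    writeBin(inter, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file written by [write_stimulus_wav()]
#'
#' Supports 2-channel 16-bit PCM and 32-bit float RIFF/WAVE.
#'
#' @param path WAV file path.
#' @return a list with `left`, `right`, `sample_rate`.
#' @export
read_stimulus_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        code = readBin(con, integer(), size = 2, endian = "little"),
        channels = readBin(con, integer(), size = 2, endian = "little"),
        sample_rate = readBin(con, integer(), size = 4, endian = "little")
      )
      readBin(con, raw(), n = sz - 8)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk precedes fmt chunk")
      if (fmt$channels != 2) stop("expected a 2-channel file")
      if (fmt$code == 1) {
        x <- readBin(con, integer(),
          n = sz / 2, size = 2,
          signed = TRUE, endian = "little"
        ) / 32767
      } else if (fmt$code == 3) {
        x <- readBin(con, numeric(), n = sz / 4, size = 4, endian = "little")
      } else {
        stop("unsupported WAV format code ", fmt$code)
      }
      return(list(
        left = x[c(TRUE, FALSE)], right = x[c(FALSE, TRUE)],
        sample_rate = fmt$sample_rate
      ))
    } else {
      readBin(con, raw(), n = sz)
    }
  }
}
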