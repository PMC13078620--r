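# Minimal mono 16-bit PCM WAV I/O (RIFF little-endian) plus JSON
# experiment-config plumbing.

#' Write a series as a 16-bit PCM mono WAV file
#'
#' Values are rescaled to the `[-1, 1]` full-scale range when they exceed
#' it.
#'
#' @param series A [sampled_series()].
#' @param path Output path.
#' @export
write_wav <- function(series, path) {
  stopifnot(inherits(series, "sampled_series"))
  x <- series$values
  peak <- max(abs(x), 1e-12)
  if (peak > 1) x <- x / peak
  pcm <- as.integer(round(x * 32767))
  rate <- as.integer(round(series$rate))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")   # byte rate
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file path (PCM, mono, 16-bit).
#' @return A [sampled_series()] with values in `[-1, 1]`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV is supported")
      if (fmt[2] != 1L) stop("only mono WAV is supported")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      ba <- readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit WAV is supported")
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz / 2, size = 2,
                     endian = "little", signed = TRUE)
      return(sampled_series(pcm / 32768, rate))
    } else {
      readBin(con, raw(), n = sz)
    }
  }
}

#' Read a flash-count CSV
#'
#' Columns `frame` and `count`; the frame rate is supplied by the caller
#' (default 29.97 frames/s).
#'
#' @param path CSV path.
#' @param fps Frame rate, frames/s.
#' @return A [sampled_series()].
#' @export
read_flash_counts <- function(path, fps = 29.97) {
  df <- utils::read.csv(path)
  if (!"count" %in% names(df)) stop("flash-count table needs a column count")
  sampled_series(df$count, fps)
}

#' Read a JSON experiment configuration
#'
#' Keys mirror the constructor arguments of [integration_config()],
#' [forcing()] and [freq_spec()]; missing blocks fall back to defaults.
#'
#' @param path JSON file path.
#' @return List with elements `config`, `forcing`, `freq_spec`, plus any
#'   further top-level keys passed through as-is.
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- raw
  out$config <- do.call(integration_config, as.list(raw$config))
  out$forcing <- if (!is.null(raw$forcing)) {
    do.call(forcing, as.list(raw$forcing))
  } else NULL
  out$freq_spec <- if (!is.null(raw$freq_spec)) {
    do.call(freq_spec, as.list(raw$freq_spec))
  } else freq_spec()
  out
}

#' Write a run manifest
#'
#' Records seeds, parameters and the package version next to experiment
#' outputs.
#'
#' @param path Output JSON path.
#' @param ... Named values to record.
#' @export
write_manifest <- function(path, ...) {
  jsonlite::write_json(
    c(list(package = "isochron",
           version = as.character(utils::packageVersion("isochron")),
           timestamp = format(Sys.time(), tz = "UTC")),
      list(...)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
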