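#' Heart-sound recording container
#'
#' A single-channel phonocardiogram with its metadata. Samples are stored as
#' doubles normalized to \[-1, 1\].
#'
#' @param samples numeric vector of audio samples.
#' @param fs_hz sampling rate in Hz.
#' @param id recording identifier.
#' @param label diagnostic class: `"no_murmur"`, `"stills"` or `"other"`.
#' @param location chest location: `"RUSB"`, `"LUSB"`, `"LLSB"` or `"apex"`.
#' @return An object of class `pcg_recording` with fields `id`, `samples`,
#'   `fs_hz`, `label`, `location`, `duration_s`.
#' @export
pcg_recording <- function(samples, fs_hz, id = "rec", label = "no_murmur",
                          location = "LLSB") {
  if (!length(samples)) stopf("recording has zero-length audio")
  if (!all(is.finite(samples))) stopf("recording contains non-finite samples")
  if (fs_hz <= 0) stopf("fs_hz must be positive")
  if (!label %in% .pcg_labels)
    stopf("unknown label '%s' (expected one of %s)", label,
          paste(.pcg_labels, collapse = ", "))
  if (!location %in% .pcg_locations)
    stopf("unknown location '%s'", location)
  structure(list(id = id, samples = as.numeric(samples),
                 fs_hz = fs_hz, label = label, location = location,
                 duration_s = length(samples) / fs_hz),
            class = "pcg_recording")
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording '%s'>  %.2f s @ %g Hz, label=%s, location=%s\n",
              x$id, x$duration_s, x$fs_hz, x$label, x$location))
  invisible(x)
}

#' Read a mono WAV file as a recording
#'
#' Supports RIFF WAV with 16-bit integer PCM (format 1) or 32-bit float
#' (format 3) samples. Integer PCM is rescaled to \[-1, 1\] by 1/32768. When
#' `target_fs` differs from the native rate, the signal is resampled with
#' `signal::resample` (anti-aliased polyphase FIR); duration is preserved to
#' within one sample period.
#'
#' @param path path to the WAV file.
#' @param target_fs desired sampling rate in Hz, or `NULL` to keep native.
#' @param id,label,location metadata attached to the returned recording;
#'   `id` defaults to the file name without extension.
#' @return A [pcg_recording()].
#' @export
read_wav <- function(path, target_fs = NULL, id = NULL,
                     label = "no_murmur", location = "LLSB") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopf("not a RIFF file: %s", path)
  readBin(con, "integer", 1, 4, endian = "little")      # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopf("not a WAVE file: %s", path)

  fmt <- NULL; dat <- NULL
  repeat {
    tag <- readChar(con, 4, useBytes = TRUE)
    if (length(tag) == 0 || !nzchar(tag)) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0) break
    if (tag == "fmt ") {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(raw_fmt[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw_fmt[3:4], "integer", 1, 2, endian = "little"),
        fs = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, 2, endian = "little"))
    } else if (tag == "data") {
      dat <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)          # chunk padding
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stopf("malformed WAV file: %s", path)
  if (fmt$channels != 1L)
    stopf("only mono WAV is supported (%d channels in %s)", fmt$channels, path)

  x <- if (fmt$format == 1L && fmt$bits == 16L) {
    readBin(dat, "integer", length(dat) / 2, 2, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(dat, "double", length(dat) / 4, 4, endian = "little")
  } else {
    stopf("unsupported WAV encoding (format %d, %d-bit)", fmt$format, fmt$bits)
  }
  if (!length(x)) stopf("zero-length audio in %s", path)

  fs <- fmt$fs
  if (!is.null(target_fs) && target_fs != fs) {
    g <- gcd_int(round(target_fs), round(fs))
    x <- as.numeric(signal::resample(x, round(target_fs) / g, round(fs) / g))
    fs <- target_fs
  }
  pcg_recording(x, fs,
                id = id %||% sub("\\.wav$", "", basename(path),
                                 ignore.case = TRUE),
                label = label, location = location)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Write samples to a 16-bit PCM mono WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantized to 16 bits.
#'
#' @param samples numeric vector in \[-1, 1\].
#' @param fs_hz sampling rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs_hz, path) {
  pcm <- as.integer(pmax(-32768, pmin(32767, round(samples * 32768))))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")               # PCM
  writeBin(1L, con, 2, endian = "little")               # mono
  writeBin(as.integer(fs_hz), con, 4, endian = "little")
  writeBin(as.integer(fs_hz * 2), con, 4, endian = "little")  # byte rate
  writeBin(2L, con, 2, endian = "little")               # block align
  writeBin(16L, con, 2, endian = "little")              # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

.manifest_cols <- c("id", "path", "label", "location", "class_detail")

#' Read and validate a dataset manifest
#'
#' The manifest is a comma-separated UTF-8 file with a header and at least
#' the columns `id`, `path`, `label`, `location` (optionally `class_detail`).
#' Labels and locations are validated against the diagnostic-class and
#' chest-location vocabularies; duplicate ids are rejected. Row order is
#' preserved.
#'
#' @param path path to the CSV manifest.
#' @return A data.frame of recording descriptors.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  validate_manifest(m)
}

validate_manifest <- function(m) {
  need <- c("id", "path", "label", "location")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stopf("manifest missing column(s): %s", paste(missing_cols, collapse = ", "))
  bad_lab <- setdiff(unique(m$label), .pcg_labels)
  if (length(bad_lab))
    stopf("unknown label value(s) in manifest: %s",
          paste(bad_lab, collapse = ", "))
  bad_loc <- setdiff(unique(m$location), .pcg_locations)
  if (length(bad_loc))
    stopf("unknown location value(s) in manifest: %s",
          paste(bad_loc, collapse = ", "))
  if (anyDuplicated(m$id))
    stopf("duplicate recording id(s): %s",
          paste(unique(m$id[duplicated(m$id)]), collapse = ", "))
  m
}

#' Write a dataset manifest
#'
#' @param manifest data.frame with columns `id`, `path`, `label`, `location`
#'   (and optionally `class_detail`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter a manifest by location and/or label
#'
#' @param manifest a manifest data.frame.
#' @param location keep only rows at this chest location (`NULL` keeps all).
#' @param labels keep only rows with these diagnostic labels.
#' @return The filtered manifest.
#' @export
filter_manifest <- function(manifest, location = NULL, labels = NULL) {
  keep <- rep(TRUE, nrow(manifest))
  if (!is.null(location)) keep <- keep & manifest$location %in% location
  if (!is.null(labels)) keep <- keep & manifest$label %in% labels
  manifest[keep, , drop = FALSE]
}
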