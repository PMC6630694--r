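#' Construct a PCG record
#'
#' The canonical container for one mono phonocardiogram trace. Amplitudes are
#' dimensionless, normalized to \[-1, 1\]; the canonical internal sample rate
#' after ingestion is 2000 Hz.
#'
#' @param samples numeric vector of finite amplitudes.
#' @param sample_rate_hz positive integer sampling rate.
#' @param record_id character identifier.
#' @param label one of `"normal"`, `"abnormal"`, `"unknown"`.
#' @param annotations optional data.frame with columns `event`
#'   (S1/S2/S3/S4/murmur) and `time_s` (seconds, strictly inside the record).
#' @param provenance character vector of processing notes.
#' @return An object of class `pcg_record`.
#' @export
pcg_record <- function(samples, sample_rate_hz, record_id = "record",
                       label = c("unknown", "normal", "abnormal"),
                       annotations = NULL, provenance = character()) {
  label <- match.arg(label)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("samples must be non-empty")
  if (!all(is.finite(samples))) stop("samples must all be finite")
  sample_rate_hz <- as.integer(sample_rate_hz)
  if (is.na(sample_rate_hz) || sample_rate_hz <= 0L) {
    stop("sample_rate_hz must be a positive integer")
  }
  dur <- length(samples) / sample_rate_hz
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations),
              all(c("event", "time_s") %in% names(annotations)))
    bad <- annotations$time_s <= 0 | annotations$time_s >= dur
    if (any(bad)) stop("annotation times must lie strictly inside (0, duration)")
  }
  structure(
    list(record_id = record_id, samples = samples,
         sample_rate_hz = sample_rate_hz, label = label,
         annotations = annotations, provenance = provenance),
    class = "pcg_record")
}

#' @export
print.pcg_record <- function(x, ...) {
  cat(sprintf("<pcg_record> %s: %.2f s at %d Hz, label=%s\n",
              x$record_id, length(x$samples) / x$sample_rate_hz,
              x$sample_rate_hz, x$label))
  if (!is.null(x$annotations)) {
    cat(sprintf("  annotations: %d events (%s)\n", nrow(x$annotations),
                paste(names(table(x$annotations$event)), collapse = ", ")))
  }
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Duration of a PCG record in seconds
#' @param record a `pcg_record`.
#' @return Duration in seconds.
#' @export
pcg_duration <- function(record) length(record$samples) / record$sample_rate_hz

# --- minimal RIFF/WAVE PCM16 mono codec -------------------------------------
# No WAV reader ships with base R; this implements the PCM 16-bit subset the
# toolkit emits and consumes. Little-endian throughout per the RIFF spec.

read_wav_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little"),
        channels     = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little"),
        bits         = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little"))
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data <- readBin(con, "integer", size %/% 2L, 2, signed = TRUE,
                      endian = "little")
      if (size %% 2L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV (missing fmt/data chunk): ", path)
  if (fmt$audio_format != 1L) stop("only PCM encoding supported, got format ", fmt$audio_format)
  if (fmt$bits != 16L) stop("only 16-bit PCM supported, got ", fmt$bits, " bits")
  list(fmt = fmt, data = data)
}

#' Read a heart-sound WAV file
#'
#' Reads a PCM 16-bit mono WAV file, scales amplitudes to \[-1, 1\], and
#' resamples (polyphase) to `expected_rate_hz` when the file rate differs;
#' the original rate is recorded in the record's provenance.
#'
#' @param path path to the WAV file.
#' @param expected_rate_hz canonical rate (default 2000 Hz).
#' @param record_id identifier; defaults to the file basename.
#' @param label optional class label.
#' @return A [pcg_record].
#' @export
read_wav <- function(path, expected_rate_hz = 2000L,
                     record_id = sub("\\.wav$", "", basename(path)),
                     label = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  w <- read_wav_raw(path)
  if (w$fmt$channels != 1L) {
    stop("expected mono WAV, got ", w$fmt$channels, " channels: ", path)
  }
  if (length(w$data) == 0L) stop("empty WAV file: ", path)
  x <- w$data / 32768
  prov <- sprintf("read_wav(%s)", basename(path))
  rate <- w$fmt$sample_rate
  if (rate != expected_rate_hz) {
    x <- as.numeric(signal::resample(x, expected_rate_hz, rate))
    prov <- c(prov, sprintf("resampled %d->%d Hz", rate, as.integer(expected_rate_hz)))
  }
  pcg_record(x, expected_rate_hz, record_id = record_id, label = label,
             provenance = prov)
}

#' Write a PCG record as 16-bit PCM mono WAV
#'
#' Amplitudes outside \[-1, 1\] are saturated with a warning. Round-trip
#' through [read_wav] reproduces samples within one 16-bit quantization step.
#'
#' @param record a [pcg_record].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(record, path) {
  x <- record$samples
  if (any(abs(x) > 1)) {
    warning("samples exceed [-1, 1]; saturating before quantization")
    x <- pmin(1, pmax(-1, x))
  }
  q <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
  n <- length(q)
  con <- file(path, "wb")
  on.exit(close(con))
  le <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  writeChar("RIFF", con, eos = NULL); le(36L + 2L * n, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); le(16L, 4)
  le(1L, 2); le(1L, 2)                       # PCM, mono
  le(record$sample_rate_hz, 4)
  le(record$sample_rate_hz * 2L, 4)          # byte rate
  le(2L, 2); le(16L, 2)                      # block align, bits
  writeChar("data", con, eos = NULL); le(2L * n, 4)
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with header `record_id,path,label` describing a set of
#' labelled recordings. Relative paths are resolved against the manifest's
#' directory. PhysioNet-style numeric labels (-1 = normal, 1 = abnormal) are
#' mapped to the internal tokens at read time.
#'
#' @param path CSV path.
#' @return A `pcg_manifest`: list with `entries` (data.frame) and
#'   `class_counts` (named integer vector).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("manifest is empty: ", path)
  need <- c("record_id", "path", "label")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns record_id,path,label")
  }
  df$label <- map_label(df$label)
  bad <- which(!df$label %in% c("normal", "abnormal"))
  if (length(bad)) {
    stop("unknown label token in manifest row(s) ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$record_id)) {
    stop("duplicate record_id in manifest: ",
         paste(unique(df$record_id[duplicated(df$record_id)]), collapse = ", "))
  }
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  manifest_from_entries(df)
}

map_label <- function(lab) {
  lab <- trimws(as.character(lab))
  lab[lab %in% c("-1")] <- "normal"
  lab[lab %in% c("1")] <- "abnormal"
  lab
}

manifest_from_entries <- function(df) {
  counts <- table(factor(df$label, levels = c("normal", "abnormal")))
  structure(list(entries = df[, c("record_id", "path", "label")],
                 class_counts = stats::setNames(as.integer(counts), names(counts))),
            class = "pcg_manifest")
}

#' @export
print.pcg_manifest <- function(x, ...) {
  cat(sprintf("<pcg_manifest> %d records (normal: %d, abnormal: %d)\n",
              nrow(x$entries), x$class_counts[["normal"]],
              x$class_counts[["abnormal"]]))
  invisible(x)
}

#' Write a dataset manifest CSV
#' @param manifest a `pcg_manifest`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest$entries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
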