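#' Read an EEG trace from EDF or CSV
#'
#' EDF (European Data Format) files carry the sampling rate and physical
#' dimension in their header; voltages are converted to microvolts (a
#' physical dimension of `mV` is multiplied by 1000). The CSV dialect is a
#' single column of microvolt values with either a JSON sidecar
#' (`<path>.json` holding `sampling_rate`, optionally `start_time` and
#' `channel_label`) or an explicit `sampling_rate` argument.
#'
#' @param path Path to the file.
#' @param format `"edf"` or `"csv"`; guessed from the extension by default.
#' @param sampling_rate Required for CSV input without a sidecar (Hz).
#' @param channel For multi-signal EDF files, the index of the signal to
#'   return.
#' @return An [eeg_record()].
#' @seealso [write_eeg()]
#' @export
read_eeg <- function(path, format = c("auto", "edf", "csv"),
                     sampling_rate = NULL, channel = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edf") {
    return(.read_edf(path, channel))
  }
  sidecar <- paste0(path, ".json")
  meta <- list()
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar)
  if (is.null(sampling_rate)) sampling_rate <- meta$sampling_rate
  if (is.null(sampling_rate)) {
    stop("CSV input needs a `sampling_rate` argument or a `", sidecar,
         "` sidecar")
  }
  x <- utils::read.csv(path, header = TRUE)
  if (ncol(x) < 1L) stop("malformed CSV trace: ", path)
  eeg_record(x[[1]], sampling_rate,
             start_time = meta$start_time %||% 0,
             channel_label = meta$channel_label %||% "EEG")
}

#' Write an EEG trace to EDF or CSV
#'
#' The EDF writer uses one data record per second (so the sampling rate
#' must be a whole number of samples per second), a symmetric physical
#' range covering the data, and 16-bit samples; a trailing partial second
#' is dropped with a warning. The CSV writer emits one `uV` column plus a
#' JSON sidecar with the sampling rate.
#'
#' @param record An [eeg_record()].
#' @param path Output path.
#' @param format `"edf"` or `"csv"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(record, path, format = c("auto", "edf", "csv")) {
  stopifnot(inherits(record, "eeg_record"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") {
    .write_edf(record, path)
  } else {
    utils::write.csv(data.frame(uV = record$samples), path, row.names = FALSE)
    jsonlite::write_json(
      list(sampling_rate = record$sampling_rate,
           start_time = record$start_time,
           channel_label = record$channel_label),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- minimal EDF layer ------------------------------------------------------
# Fixed-layout ASCII header (256 bytes + 256 per signal) followed by
# little-endian int16 data records. Only what this package needs: uniform
# rate, uV/mV physical dimensions, contiguous records.

.edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

.edf_num <- function(x, width) {
  s <- formatC(signif(x, 7), format = "g", width = -1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = width - 2)
  .edf_pad(s, width)
}

.write_edf <- function(record, path) {
  fs <- record$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF output requires an integer number of samples per second; ",
         "sampling rate ", fs, " Hz is not supported")
  }
  fs <- as.integer(round(fs))
  x <- record$samples
  n_rec <- length(x) %/% fs
  if (n_rec < 1L) stop("record shorter than one EDF data record (1 s)")
  dropped <- length(x) - n_rec * fs
  if (dropped > 0L) {
    warning("dropping trailing partial EDF record (", dropped, " samples)")
    x <- x[seq_len(n_rec * fs)]
  }
  # quantize against the range as it is actually written (8 ASCII
  # chars), so reader and writer agree on the scale exactly; bump until
  # the written range covers every sample
  pm <- as.numeric(trimws(.edf_num(max(abs(x), 1e-6) * (1 + 1e-5), 8)))
  while (pm < max(abs(x))) {
    pm <- as.numeric(trimws(.edf_num(pm * 1.001, 8)))
  }
  phys_min <- -pm
  phys_max <- pm
  dig_min <- -32767L
  dig_max <- 32767L
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  digital <- as.integer(round((x - phys_min) * scale) + dig_min)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad("X X X X", 80),
    .edf_pad("Startdate X X X X", 80),
    .edf_pad("01.01.00", 8),
    .edf_pad("00.00.00", 8),
    .edf_pad(256L + 256L, 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad(1L, 8),
    .edf_pad(1L, 4),
    # per-signal fields (one signal)
    .edf_pad(record$channel_label, 16),
    .edf_pad("", 80),
    .edf_pad("uV", 8),
    .edf_num(phys_min, 8),
    .edf_num(phys_max, 8),
    .edf_pad(dig_min, 8),
    .edf_pad(dig_max, 8),
    .edf_pad("", 80),
    .edf_pad(fs, 8),
    .edf_pad("", 32)
  )
  writeChar(hdr, con, eos = NULL)
  writeBin(digital, con, size = 2L, endian = "little")
  invisible(path)
}

.read_edf <- function(path, channel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    out <- readChar(con, n, useBytes = TRUE)
    if (length(out) == 0L || nchar(out, type = "bytes") < n) {
      stop("malformed EDF header: truncated file ", path)
    }
    out
  }
  version <- trimws(rd(8))
  if (version != "0") stop("malformed EDF header: version field is '",
                           version, "', expected '0'")
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- suppressWarnings(as.integer(trimws(rd(8))))
  rd(44)
  n_rec <- suppressWarnings(as.integer(trimws(rd(8))))
  rec_dur <- suppressWarnings(as.numeric(trimws(rd(8))))
  ns <- suppressWarnings(as.integer(trimws(rd(4))))
  if (anyNA(c(header_bytes, n_rec, rec_dur, ns)) || ns < 1L || rec_dur <= 0) {
    stop("malformed EDF header in ", path)
  }
  if (channel < 1L || channel > ns) {
    stop("EDF file has ", ns, " signal(s); channel ", channel, " requested")
  }
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fld(16); fld(80)
  phys_dim <- fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (anyNA(phys_min) || anyNA(phys_max) || anyNA(dig_min) || anyNA(dig_max) ||
      anyNA(spr)) {
    stop("malformed EDF signal header in ", path)
  }
  unit_scale <- vapply(phys_dim, function(d) {
    switch(tolower(d), "uv" = 1, "µv" = 1, "mv" = 1000, "v" = 1e6,
           stop("unknown physical dimension '", d, "' in EDF signal header"))
  }, numeric(1))

  total_per_rec <- sum(spr)
  raw <- readBin(con, "integer", n = n_rec * total_per_rec, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_rec * total_per_rec) {
    stop("malformed EDF: data section shorter than header declares")
  }
  offs <- c(0L, cumsum(spr))
  idx <- unlist(lapply(seq_len(n_rec) - 1L, function(r) {
    r * total_per_rec + offs[channel] + seq_len(spr[channel])
  }))
  dig <- raw[idx]
  gain <- (phys_max[channel] - phys_min[channel]) /
    (dig_max[channel] - dig_min[channel])
  phys <- (dig - dig_min[channel]) * gain + phys_min[channel]
  eeg_record(phys * unit_scale[channel], spr[channel] / rec_dur,
             channel_label = labels[channel])
}

# ---- annotations ------------------------------------------------------------

.annotation_kinds <- c("spike", "seizure", "artifact", "se_onset")

#' Construct an annotation set
#'
#' An event table with a closed vocabulary of kinds (`spike`, `seizure`,
#' `artifact`, `se_onset`) and half-open `[onset, offset)` intervals in
#' seconds. Point events (spikes, SE onset) have `offset == onset`.
#'
#' @param kind Character vector of event kinds.
#' @param onset,offset Numeric vectors of event times (s).
#' @param ... Further per-event columns (recycled by `data.frame`).
#' @return A `data.frame` with class `annotation_set`.
#' @export
annotation_set <- function(kind = character(), onset = numeric(),
                           offset = onset, ...) {
  bad <- setdiff(unique(kind), .annotation_kinds)
  if (length(bad)) {
    stop("unknown annotation kind(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.annotation_kinds, collapse = ", "), ")")
  }
  if (any(offset < onset)) stop("annotation offset before onset")
  out <- data.frame(kind = as.character(kind), onset = as.numeric(onset),
                    offset = as.numeric(offset), ...,
                    stringsAsFactors = FALSE)
  out <- out[order(out$onset), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("annotation_set", "data.frame")
  out
}

#' Write / read annotation tables
#'
#' Lossless CSV round-trip of an event table (columns `kind`, `onset_s`,
#' `offset_s`). Overlapping seizure rows are permitted on read but are
#' reported via a message so they can be audited.
#'
#' @param annotations An [annotation_set()].
#' @param path CSV path.
#' @return `write_annotations` returns `path` invisibly; `read_annotations`
#'   returns an [annotation_set()].
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  out <- as.data.frame(annotations)
  names(out)[names(out) == "onset"] <- "onset_s"
  names(out)[names(out) == "offset"] <- "offset_s"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  x <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("kind", "onset_s", "offset_s")
  if (!all(need %in% names(x))) {
    stop("annotation CSV must have columns ", paste(need, collapse = ", "))
  }
  extra <- x[setdiff(names(x), need)]
  out <- do.call(annotation_set,
                 c(list(kind = x$kind, onset = x$onset_s, offset = x$offset_s),
                   as.list(extra)))
  sz <- out[out$kind == "seizure", , drop = FALSE]
  if (nrow(sz) > 1L && any(sz$onset[-1L] < sz$offset[-nrow(sz)])) {
    message("read_annotations: overlapping seizure intervals in ", path)
  }
  out
}
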