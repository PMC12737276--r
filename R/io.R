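# Shared domain containers and on-disk formats: the native recording bundle
# (flat float64 block + JSON sidecar), a minimal EDF exporter/reader for
# interoperability with sleep tooling, and CSV round-trips for hypnograms
# and event tables.
#
# Conventions used throughout the package: time in seconds from the session
# origin, half-open event intervals [start, end), 0-based sample indices in
# the arithmetic (R vectors are of course accessed 1-based).

STAGE_LEVELS <- c("WAKE", "NREM", "REM")

#' Electrode grid layout
#'
#' Describes how channels map onto a rectangular electrode grid (the device
#' modeled here is an 8x8 surface array with 600 um pitch).
#'
#' @param channel_ids character vector assigned to the grid row-major
#'   (row 1 first). `NA` entries mark unused grid sites.
#' @param n_rows,n_cols grid dimensions.
#' @param pitch_um electrode spacing in micrometers.
#' @return an `ecog_layout` object.
#' @export
electrode_layout <- function(channel_ids = sprintf("ch%02d", 1:64),
                             n_rows = 8, n_cols = 8, pitch_um = 600) {
  if (length(channel_ids) != n_rows * n_cols)
    stop("need one channel id (or NA) per grid site")
  ids <- channel_ids[!is.na(channel_ids)]
  if (anyDuplicated(ids)) stop("channel ids must be unique in the layout")
  grid <- matrix(channel_ids, n_rows, n_cols, byrow = TRUE)
  structure(list(grid = grid, n_rows = n_rows, n_cols = n_cols,
                 pitch_um = pitch_um),
            class = "ecog_layout")
}

#' Grid coordinates of laid-out channels
#'
#' @param layout an `ecog_layout`.
#' @return data.frame with `channel_id`, `row`, `col` (1-based) and
#'   `x_um`, `y_um` physical positions.
#' @export
layout_coords <- function(layout) {
  idx <- which(!is.na(layout$grid), arr.ind = TRUE)
  data.frame(channel_id = layout$grid[idx],
             row = idx[, 1], col = idx[, 2],
             x_um = (idx[, 2] - 1) * layout$pitch_um,
             y_um = (idx[, 1] - 1) * layout$pitch_um,
             stringsAsFactors = FALSE)
}

#' Multichannel recording container
#'
#' @param samples channels x time numeric matrix (amplitude, arbitrary units).
#' @param fs sampling rate in Hz.
#' @param channel_ids one label per row of `samples`.
#' @param layout optional [electrode_layout()].
#' @param start_time seconds from the session origin of the first sample.
#' @return an `ecog_recording` object.
#' @export
recording <- function(samples, fs, channel_ids = NULL, layout = NULL,
                      start_time = 0) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%02d", seq_len(nrow(samples)))
  if (length(channel_ids) != nrow(samples))
    stop("one channel id per row required")
  if (anyDuplicated(channel_ids)) stop("channel ids must be unique")
  if (fs <= 0) stop("fs must be positive")
  rownames(samples) <- channel_ids
  structure(list(samples = samples, fs = fs, channel_ids = channel_ids,
                 layout = layout, start_time = start_time),
            class = "ecog_recording")
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("ecog_recording: %d channels x %d samples (%.1f s at %g Hz)\n",
              nrow(x$samples), ncol(x$samples), ncol(x$samples) / x$fs, x$fs))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$samples)
duration_s <- function(rec) ncol(rec$samples) / rec$fs

#' Hypnogram of per-epoch sleep-stage labels
#'
#' @param labels character or factor over `WAKE`, `NREM`, `REM`.
#' @param epoch_len epoch length in seconds (4 by convention).
#' @param origin seconds from session origin of the first epoch.
#' @export
hypnogram <- function(labels, epoch_len = 4, origin = 0) {
  labels <- as.character(labels)
  if (!length(labels)) stop("hypnogram needs at least one epoch")
  bad <- setdiff(unique(labels), STAGE_LEVELS)
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  structure(list(labels = factor(labels, levels = STAGE_LEVELS),
                 epoch_len = epoch_len, origin = origin),
            class = "ecog_hypnogram")
}

#' @export
print.ecog_hypnogram <- function(x, ...) {
  tb <- table(x$labels)
  cat(sprintf("hypnogram: %d epochs of %g s (%s)\n", length(x$labels),
              x$epoch_len, paste(names(tb), tb, sep = "=", collapse = " ")))
  invisible(x)
}

#' @export
length.ecog_hypnogram <- function(x) length(x$labels)

# epoch start/end times (half-open)
epoch_times <- function(hyp) {
  n <- length(hyp$labels)
  data.frame(epoch = seq_len(n),
             start_s = hyp$origin + (seq_len(n) - 1) * hyp$epoch_len,
             end_s = hyp$origin + seq_len(n) * hyp$epoch_len,
             stage = as.character(hyp$labels), stringsAsFactors = FALSE)
}

# boolean sample mask of epochs in `stages`, for a signal at rate fs
stage_sample_mask <- function(hyp, stages, fs, n) {
  mask <- logical(n)
  et <- epoch_times(hyp)
  for (i in which(et$stage %in% stages)) {
    a <- floor(et$start_s[i] * fs) + 1
    b <- min(n, ceiling(et$end_s[i] * fs))
    if (a <= n) mask[a:min(b, n)] <- TRUE
  }
  mask
}

validate_events <- function(events) {
  need <- c("channel_id", "start_s", "end_s")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("event table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(events$end_s <= events$start_s)
  if (length(bad))
    stop("event row(s) with end <= start: ", paste(head(bad, 5), collapse = ", "))
  events
}

# ---- native bundle: float64 block + JSON sidecar ----

#' Write / read a recording bundle
#'
#' The native container is a directory holding `samples.bin` (float64,
#' little-endian, channel-major) plus a `meta.json` sidecar with the
#' sampling rate, channel ids and layout. Round-trips are bit-exact.
#'
#' @param rec an `ecog_recording`.
#' @param path bundle directory (created if needed).
#' @return `path`, invisibly for the writer; an `ecog_recording` for the reader.
#' @export
write_bundle <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "ecogsleep-bundle-v1",
               fs = rec$fs, start_time = rec$start_time,
               n_channels = nrow(rec$samples), n_samples = ncol(rec$samples),
               channel_ids = rec$channel_ids, endianness = "little")
  if (!is.null(rec$layout))
    meta$layout <- list(grid = as.vector(t(rec$layout$grid)),
                        n_rows = rec$layout$n_rows, n_cols = rec$layout$n_cols,
                        pitch_um = rec$layout$pitch_um)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(path, "samples.bin"), "wb")
  on.exit(close(con))
  # channel-major: each channel's full trace contiguous
  writeBin(as.vector(t(rec$samples)), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_bundle
#' @param path bundle directory written by [write_bundle()].
#' @export
read_bundle <- function(path) {
  sidecar <- file.path(path, "meta.json")
  if (!file.exists(sidecar)) stop("missing sidecar meta.json in ", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  binf <- file.path(path, "samples.bin")
  if (!file.exists(binf)) stop("missing samples.bin in ", path)
  nc <- meta$n_channels; ns <- meta$n_samples
  if (length(meta$channel_ids) != nc)
    stop("channel-count mismatch: sidecar lists ", length(meta$channel_ids),
         " ids for ", nc, " channels")
  expect_bytes <- nc * ns * 8
  if (file.info(binf)$size != expect_bytes)
    stop("corrupt block: samples.bin has ", file.info(binf)$size,
         " bytes, expected ", expect_bytes)
  con <- file(binf, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = nc * ns, size = 8, endian = "little")
  samples <- matrix(v, nrow = nc, byrow = TRUE)
  layout <- NULL
  if (!is.null(meta$layout))
    layout <- electrode_layout(unlist(meta$layout$grid),
                               n_rows = meta$layout$n_rows,
                               n_cols = meta$layout$n_cols,
                               pitch_um = meta$layout$pitch_um)
  recording(samples, fs = as.numeric(meta$fs),
            channel_ids = as.character(meta$channel_ids),
            layout = layout, start_time = as.numeric(meta$start_time))
}

# ---- EDF export (16-bit, 1-s data records) ----

pad_ascii <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = -width)
}

#' Export a recording to EDF
#'
#' Writes a European Data Format file with one 16-bit signal per channel and
#' 1-s data records; the last record is zero-padded if the recording length
#' is not a whole number of seconds. Amplitude round-trip error is bounded
#' by the 16-bit quantization of the per-channel physical range.
#'
#' @param rec an `ecog_recording` with finite samples and integer `fs`.
#' @param path output `.edf` file.
#' @return `path`, invisibly.
#' @export
export_edf <- function(rec, path) {
  if (!ncol(rec$samples)) stop("cannot export an empty recording")
  if (!all(is.finite(rec$samples))) stop("non-finite samples cannot be exported")
  if (rec$fs != round(rec$fs)) stop("EDF export requires an integer sampling rate")
  nch <- nrow(rec$samples)
  spr <- as.integer(rec$fs)            # samples per 1-s record
  nrec <- as.integer(ceiling(ncol(rec$samples) / spr))
  # the physical range must match its 8-char ASCII serialization exactly,
  # or reader-side rescaling would break the quantization bound; nudge up
  # so serialization rounding cannot put samples outside the range
  phys_max <- as.numeric(sprintf("%.6g",
    pmax(apply(abs(rec$samples), 1, max), 1e-6) * (1 + 1e-5)))
  dig_max <- 32767L; dig_min <- -32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad_ascii("0", 8), pad_ascii("synthetic", 80),
                pad_ascii("ecogsleep export", 80),
                pad_ascii("01.01.26", 8), pad_ascii("00.00.00", 8),
                pad_ascii(256 * (1 + nch), 8), pad_ascii("", 44),
                pad_ascii(nrec, 8), pad_ascii("1", 8), pad_ascii(nch, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, pad_ascii, "", width = width), collapse = ""),
              con, eos = NULL)
  field(rec$channel_ids, 16)
  field(rep("", nch), 80)
  field(rep("uV", nch), 8)
  field(sprintf("%.6g", -phys_max), 8)
  field(sprintf("%.6g", phys_max), 8)
  field(rep(dig_min, nch), 8)
  field(rep(dig_max, nch), 8)
  field(rep("", nch), 80)
  field(rep(spr, nch), 8)
  field(rep("", nch), 32)
  scale <- dig_max / phys_max
  padded <- cbind(rec$samples,
                  matrix(0, nch, nrec * spr - ncol(rec$samples)))
  for (r in seq_len(nrec)) {
    block <- padded[, ((r - 1) * spr + 1):(r * spr), drop = FALSE]
    dig <- matrix(pmax(dig_min, pmin(dig_max, as.integer(round(block * scale)))),
                  nrow = nch)
    writeBin(as.vector(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [export_edf()] (minimal reader)
#'
#' Supports the plain-EDF subset this package writes: identical sampling
#' rate across signals and 1-s records.
#'
#' @param path `.edf` file.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8); rd(80); rd(80); rd(8); rd(8)
  hbytes <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8)); recdur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(1:nch, function(i) rd(16), "")
  for (w in c(80, 8)) for (i in 1:nch) rd(w)
  pmin <- as.numeric(vapply(1:nch, function(i) rd(8), ""))
  pmax <- as.numeric(vapply(1:nch, function(i) rd(8), ""))
  dmin <- as.numeric(vapply(1:nch, function(i) rd(8), ""))
  dmax <- as.numeric(vapply(1:nch, function(i) rd(8), ""))
  for (i in 1:nch) rd(80)
  spr <- as.integer(vapply(1:nch, function(i) rd(8), ""))
  for (i in 1:nch) rd(32)
  if (length(unique(spr)) != 1) stop("mixed sampling rates not supported")
  fs <- spr[1] / recdur
  samples <- matrix(0, nch, nrec * spr[1])
  for (r in seq_len(nrec)) {
    block <- readBin(con, "integer", n = nch * spr[1], size = 2,
                     endian = "little", signed = TRUE)
    m <- matrix(block, nrow = spr[1])
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    samples[, idx] <- t(m)
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  samples <- samples * scale + (pmax + pmin) / 2
  recording(samples, fs = fs, channel_ids = make.unique(labels))
}

# ---- CSV round-trips ----

#' Hypnogram CSV round-trip
#'
#' Fixed header `epoch,start_s,stage`; stages must be WAKE/NREM/REM.
#'
#' @param hyp an `ecog_hypnogram`; `path` a CSV file.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  et <- epoch_times(hyp)
  utils::write.csv(et[, c("epoch", "start_s", "stage")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @param path CSV written by [write_hypnogram_csv()].
#' @param epoch_len epoch length in seconds.
#' @export
read_hypnogram_csv <- function(path, epoch_len = 4) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("hypnogram CSV has no epochs")
  bad <- which(!df$stage %in% STAGE_LEVELS)
  if (length(bad))
    stop("unknown stage label '", df$stage[bad[1]], "' at row ", bad[1])
  origin <- if ("start_s" %in% names(df)) df$start_s[1] else 0
  hypnogram(df$stage, epoch_len = epoch_len, origin = origin)
}

#' Event-table CSV round-trip
#'
#' Fixed leading columns `channel_id,start_s,end_s`; any further metric
#' columns are preserved. Intervals are half-open `[start_s, end_s)`.
#'
#' @param events data.frame of events; `path` a CSV file.
#' @export
write_events_csv <- function(events, path) {
  validate_events(events)
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @param path CSV written by [write_events_csv()].
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    need <- c("channel_id", "start_s", "end_s")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("event table lacks column(s): ", paste(miss, collapse = ", "))
    return(df)
  }
  validate_events(df)
}
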