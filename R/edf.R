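# Minimal EDF (European Data Format) reader/writer.
#
# No EDF package ships with the target environment, so the 16-bit format is
# implemented directly: fixed-width ASCII header (256 bytes + 256 per
# signal) followed by little-endian int16 data records. The writer emits a
# single data record holding the whole recording (every signal shares one
# sampling rate here), which any spec-conforming reader accepts.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, digits = 8)
  if (nchar(s) > width) s <- substr(formatC(x, format = "g", digits = 6), 1, width)
  edf_pad(s, width)
}

#' Write an EEG recording to an EDF file
#'
#' Samples are quantised to 16 bits over the physical range; the default
#' range of plus/minus 500 microvolts gives a quantisation step of about
#' 0.015 uV. Data exceeding the range widens it automatically.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @param physical_range length-2 numeric, physical min/max in uV.
#' @return `path`, invisibly.
#' @keywords internal
write_edf <- function(rec, path, physical_range = c(-500, 500)) {
  validate_recording(rec)
  nc <- nrow(rec$data); ns <- ncol(rec$data)
  pmin <- physical_range[1]; pmax <- physical_range[2]
  rng <- range(rec$data)
  if (rng[1] < pmin || rng[2] > pmax) {
    pad <- 0.01 * max(abs(rng), 1)
    pmin <- min(pmin, rng[1] - pad); pmax <- max(pmax, rng[2] + pad)
  }
  dmin <- -32768L; dmax <- 32767L
  scale <- (pmax - pmin) / (dmax - dmin)
  dig <- round((rec$data - pmin) / scale) + dmin
  dig <- pmin(pmax(dig, dmin), dmax)
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    edf_pad("0", 8),                                   # version
    edf_pad(if (is.null(rec$subject_id)) "X" else rec$subject_id, 80),
    edf_pad(if (is.null(rec$trial_id)) "X" else rec$trial_id, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),    # start date/time
    edf_pad(256 + 256 * nc, 8),                        # header bytes
    edf_pad("", 44),
    edf_pad(1, 8),                                     # n data records
    edf_num(ns / rec$fs, 8),                           # record duration, s
    edf_pad(nc, 4)), con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(rec$channel_names, 16)
  field(rep("", nc), 80)                               # transducer
  field(rep("uV", nc), 8)                              # physical dimension
  field(rep(edf_num(pmin, 8), nc), 8)
  field(rep(edf_num(pmax, 8), nc), 8)
  field(rep(dmin, nc), 8)
  field(rep(dmax, nc), 8)
  field(rep("", nc), 80)                               # prefiltering
  field(rep(ns, nc), 8)                                # samples per record
  field(rep("", nc), 32)
  # one record: all samples of signal 1, then signal 2, ...
  writeBin(as.vector(t(dig)), con, size = 2L, endian = "little")
  invisible(path)
}

edf_read_field <- function(con, width, n = 1L) {
  trimws(vapply(seq_len(n), function(i) readChar(con, width, useBytes = TRUE), ""))
}

#' Read an EDF file into an EEG recording
#' @param path EDF file path.
#' @return an [eeg_recording()].
#' @keywords internal
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_read_field(con, 8)
  if (version != "0")
    stop("not an EDF file (version field ", sQuote(version), "): ", path)
  subject <- edf_read_field(con, 80)
  trial <- edf_read_field(con, 80)
  edf_read_field(con, 8); edf_read_field(con, 8)       # date, time
  header_bytes <- as.integer(edf_read_field(con, 8))
  edf_read_field(con, 44)
  n_records <- as.integer(edf_read_field(con, 8))
  rec_dur <- as.numeric(edf_read_field(con, 8))
  nc <- as.integer(edf_read_field(con, 4))
  if (is.na(nc) || nc < 1L) stop("EDF header: bad signal count")
  labels <- edf_read_field(con, 16, nc)
  edf_read_field(con, 80, nc)
  edf_read_field(con, 8, nc)
  pmin <- as.numeric(edf_read_field(con, 8, nc))
  pmax <- as.numeric(edf_read_field(con, 8, nc))
  dmin <- as.numeric(edf_read_field(con, 8, nc))
  dmax <- as.numeric(edf_read_field(con, 8, nc))
  if (anyNA(c(pmin, pmax, dmin, dmax)))
    stop("EDF header: unparseable physical/digital range")
  edf_read_field(con, 80, nc)
  spr <- as.integer(edf_read_field(con, 8, nc))
  edf_read_field(con, 32, nc)
  if (length(unique(spr)) != 1L)
    stop("EDF: signals with differing sampling rates are not supported")
  seek(con, header_bytes)
  data <- matrix(0, nc, spr[1] * n_records)
  for (r in seq_len(n_records)) {
    block <- readBin(con, "integer", n = nc * spr[1], size = 2L,
                     endian = "little")
    if (length(block) < nc * spr[1]) stop("EDF: truncated data record")
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    data[, cols] <- t(matrix(block, nrow = spr[1]))
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  data <- sweep(sweep(data - dmin, 1, scale, "*"), 1, pmin, "+")
  if (is.na(rec_dur) || rec_dur <= 0) stop("EDF header: bad record duration")
  fs <- spr[1] / rec_dur
  eeg_recording(data, fs, labels,
                subject_id = if (identical(subject, "X")) NULL else subject,
                trial_id = if (identical(trial, "X")) NULL else trial)
}
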