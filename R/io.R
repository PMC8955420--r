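#' Read an EEG recording from EDF, CSV or HDF5
#'
#' Formats:
#' \describe{
#'   \item{`edf`}{European Data Format, 16-bit; see [write_recording()] for
#'     the quantisation.}
#'   \item{`csv`}{first line `# fs=<Hz>`, second line a header of channel
#'     names, then one sample per row (human-inspectable fixtures).}
#'   \item{`hdf5`}{datasets `data` (float64, channels x samples), `fs`
#'     (scalar) and `channel_names` (string array); lossless.}
#' }
#' `format = "auto"` dispatches on the file extension
#' (`.edf` / `.csv` / `.h5`, `.hdf5`).
#'
#' @param path input file.
#' @param format one of `"auto"`, `"edf"`, `"csv"`, `"hdf5"`.
#' @return an [eeg_recording()]; channel order preserved as stored.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(400), 2), 100, c("F3", "F4"))
#' f <- tempfile(fileext = ".h5")
#' write_recording(rec, f)
#' rec2 <- read_recording(f)
#' stopifnot(identical(rec$data, rec2$data))
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         edf = read_edf(path),
         csv = read_recording_csv(path),
         hdf5 = read_recording_h5(path))
}

#' Write an EEG recording to EDF, CSV or HDF5
#'
#' HDF5 round trips are bit-identical; CSV stores 9 significant digits; EDF
#' quantises to the 16-bit grid over the physical range (default plus/minus
#' 500 uV, widened automatically when the data exceed it).
#'
#' @param rec an [eeg_recording()].
#' @param path output file.
#' @param format as in [read_recording()].
#' @param physical_range EDF-only: physical min/max in uV.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "csv", "hdf5"),
                            physical_range = c(-500, 500)) {
  validate_recording(rec)
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         edf = write_edf(rec, path, physical_range),
         csv = write_recording_csv(rec, path),
         hdf5 = write_recording_h5(rec, path))
  invisible(path)
}

guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         edf = "edf", csv = "csv", h5 = "hdf5", hdf5 = "hdf5",
         stop("cannot guess format from extension of ", path,
              "; pass format= explicitly"))
}

read_recording_csv <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*fs\\s*=\\s*([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2L)
    stop("CSV recording: first line must be '# fs=<Hz>', got ", sQuote(first))
  fs <- as.numeric(m[2])
  dt <- data.table::fread(path, skip = 1L, header = TRUE, sep = ",",
                          check.names = FALSE)
  # take channel names from the raw header line: fread may mangle duplicates
  hdr <- trimws(strsplit(readLines(path, n = 2L)[2], ",", fixed = TRUE)[[1]])
  if (anyDuplicated(hdr))
    stop("CSV recording: duplicate channel name in header: ",
         hdr[duplicated(hdr)][1])
  eeg_recording(t(as.matrix(dt)), fs, hdr)
}

write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  writeLines(sprintf("# fs=%.10g", rec$fs), con)
  close(con)
  dt <- data.table::as.data.table(signif(t(rec$data), 9))
  data.table::setnames(dt, rec$channel_names)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

read_recording_h5 <- function(path) {
  need <- c("data", "fs", "channel_names")
  have <- tryCatch(rhdf5::h5ls(path)$name, error = function(e)
    stop("not a readable HDF5 file: ", path))
  missing <- setdiff(need, have)
  if (length(missing))
    stop("HDF5 recording lacks dataset(s): ", paste(missing, collapse = ", "))
  data <- rhdf5::h5read(path, "data")
  fs <- as.numeric(rhdf5::h5read(path, "fs"))
  ch <- as.character(rhdf5::h5read(path, "channel_names"))
  sub <- if ("subject_id" %in% have)
    as.character(rhdf5::h5read(path, "subject_id")) else NULL
  tri <- if ("trial_id" %in% have)
    as.character(rhdf5::h5read(path, "trial_id")) else NULL
  eeg_recording(data, fs, ch, subject_id = sub, trial_id = tri)
}

write_recording_h5 <- function(rec, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(rec$data, path, "data")
  rhdf5::h5write(rec$fs, path, "fs")
  rhdf5::h5write(rec$channel_names, path, "channel_names")
  if (!is.null(rec$subject_id)) rhdf5::h5write(rec$subject_id, path, "subject_id")
  if (!is.null(rec$trial_id)) rhdf5::h5write(rec$trial_id, path, "trial_id")
  rhdf5::h5closeAll()
  invisible(path)
}
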