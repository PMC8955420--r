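#' EEG recording container
#'
#' A validated multichannel EEG recording: a channels x samples numeric
#' matrix in microvolts plus sampling rate and channel names (10-20 system
#' labels). All readers return this container and all feature extractors
#' consume it.
#'
#' @param data numeric matrix, `n_channels x n_samples`, microvolts.
#' @param fs sampling rate in Hz, positive scalar.
#' @param channel_names character vector of unique channel labels, one per
#'   row of `data`.
#' @param subject_id,trial_id optional identifier strings carried as
#'   provenance.
#' @return an object of class `eeg_recording` with fields `data`, `fs`,
#'   `channel_names`, `subject_id`, `trial_id`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(400), 2), fs = 100,
#'                      channel_names = c("F3", "F4"))
#' rec
#' @export
eeg_recording <- function(data, fs, channel_names,
                          subject_id = NULL, trial_id = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  rec <- structure(
    list(data = data, fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         subject_id = subject_id, trial_id = trial_id),
    class = "eeg_recording")
  validate_recording(rec)
  rec
}

#' @rdname eeg_recording
#' @param rec an `eeg_recording`.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || rec$fs <= 0)
    stop("fs must be a positive scalar")
  if (nrow(rec$data) < 2L)
    stop("a recording needs at least 2 channels, got ", nrow(rec$data))
  if (ncol(rec$data) < 1L)
    stop("a recording needs at least 1 sample")
  if (length(rec$channel_names) != nrow(rec$data))
    stop("channel_names length (", length(rec$channel_names),
         ") does not match channel count (", nrow(rec$data), ")")
  dup <- rec$channel_names[duplicated(rec$channel_names)]
  if (length(dup))
    stop("duplicate channel names: ", paste(unique(dup), collapse = ", "))
  if (!all(is.finite(rec$data)))
    stop("recording contains non-finite samples (NaN/Inf)")
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(head(x$channel_names, 8), collapse = " "),
      if (length(x$channel_names) > 8) "..." else "", "\n")
  if (!is.null(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  if (!is.null(x$trial_id))   cat("  trial:  ", x$trial_id, "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Reorder recording channels to a montage's channel order
#'
#' Channel order is authoritative from the montage, not the file: AsMap rows
#' and columns must mean the same channel across files, so loaders and
#' pipelines reorder by name. Matching is case-insensitive (SEED labels are
#' upper-case, DEAP labels mixed-case).
#'
#' @param rec an [eeg_recording()].
#' @param montage a [montage()].
#' @return the recording with rows permuted to `montage$channel_order`.
#' @export
reorder_channels <- function(rec, montage) {
  validate_recording(rec)
  idx <- match(toupper(montage$channel_order), toupper(rec$channel_names))
  if (anyNA(idx))
    stop("recording is missing montage channels: ",
         paste(montage$channel_order[is.na(idx)], collapse = ", "))
  eeg_recording(rec$data[idx, , drop = FALSE], rec$fs,
                montage$channel_order,
                subject_id = rec$subject_id, trial_id = rec$trial_id)
}
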