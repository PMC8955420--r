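#' Segment a recording into non-overlapping epochs
#'
#' Contiguous, non-overlapping epochs of fixed length; a trailing partial
#' epoch is discarded (floor rule).
#'
#' @param rec an [eeg_recording()].
#' @param epoch_len_s epoch length in seconds (default 1).
#' @return object of class `epoch_grid`: list with `epoch_len_s`,
#'   `samples_per_epoch`, `n_epochs`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 2100), 2), 200, c("C3", "C4"))
#' segment_epochs(rec)$n_epochs  # 10: the trailing 0.5 s is discarded
#' @export
segment_epochs <- function(rec, epoch_len_s = 1) {
  validate_recording(rec)
  spe <- round(epoch_len_s * rec$fs)
  if (spe < 2) stop("epoch_len_s * fs must be at least 2 samples")
  n_epochs <- floor(ncol(rec$data) / spe)
  if (n_epochs < 1L)
    stop("recording (", ncol(rec$data), " samples) shorter than one epoch (",
         spe, " samples)")
  structure(list(epoch_len_s = epoch_len_s, samples_per_epoch = as.integer(spe),
                 n_epochs = as.integer(n_epochs)),
            class = "epoch_grid")
}

#' Hann window of length n (periodic form used for spectral estimation)
#' @keywords internal
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

#' Per-epoch band power from the short-time Fourier transform
#'
#' Each epoch is the analysis frame: Hann-windowed, zero-padded to `n_fft`
#' points, and turned into a one-sided periodogram normalised by the window
#' power so that the sum over all frequency bins estimates the signal
#' variance (Parseval-consistent). Band power is the sum of the bin powers
#' whose frequencies `f` satisfy `low <= f <= high` (inclusive edges; bins
#' falling in gaps between bands belong to no band). Epochs longer than
#' `n_fft` samples are split into length-`n_fft` frames whose periodograms
#' are averaged.
#'
#' @param rec an [eeg_recording()].
#' @param grid an `epoch_grid` from [segment_epochs()].
#' @param bands a [band_set()]; every band must lie within the Nyquist
#'   frequency.
#' @param n_fft FFT length (default 256).
#' @return numeric array `n_channels x n_bands x n_epochs` of band powers in
#'   uV^2, dimnames set to channel and band names.
#' @export
epoch_band_power <- function(rec, grid, bands = default_bands(), n_fft = 256) {
  validate_recording(rec)
  stopifnot(inherits(grid, "epoch_grid"))
  nyq <- rec$fs / 2
  too_high <- bands$high_hz > nyq
  if (any(too_high))
    stop("band ", bands$name[too_high][1], " exceeds the Nyquist frequency (",
         nyq, " Hz)")
  spe <- grid$samples_per_epoch
  frame_len <- min(spe, n_fft)
  n_frames <- max(1L, floor(spe / frame_len))
  w <- hann_window(frame_len)
  wnorm <- sum(w^2)  # window power; makes the periodogram sum to ~var(x)
  freqs <- (seq_len(n_fft) - 1) * rec$fs / n_fft
  half <- floor(n_fft / 2) + 1L          # bins 0 .. Nyquist
  band_bins <- lapply(seq_len(nrow(bands)), function(b)
    which(freqs[seq_len(half)] >= bands$low_hz[b] &
          freqs[seq_len(half)] <= bands$high_hz[b]))

  nc <- nrow(rec$data)
  out <- array(0, dim = c(nc, nrow(bands), grid$n_epochs),
               dimnames = list(rec$channel_names, bands$name, NULL))
  for (e in seq_len(grid$n_epochs)) {
    seg <- rec$data[, ((e - 1L) * spe + 1L):(e * spe), drop = FALSE]
    p_acc <- matrix(0, nc, half)
    for (fr in seq_len(n_frames)) {
      frame <- seg[, ((fr - 1L) * frame_len + 1L):(fr * frame_len),
                   drop = FALSE]
      xw <- sweep(frame, 2, w, "*")
      if (frame_len < n_fft)
        xw <- cbind(xw, matrix(0, nc, n_fft - frame_len))
      # row-wise FFT: mvfft works on columns
      X <- t(stats::mvfft(t(xw)))
      p2 <- Mod(X)^2 / (n_fft * wnorm)   # two-sided, sums to ~var(frame)
      p1 <- p2[, seq_len(half), drop = FALSE]
      if (n_fft %% 2 == 0) {
        if (half > 2L)
          p1[, 2:(half - 1L)] <- p1[, 2:(half - 1L)] +
            p2[, n_fft:(half + 1L), drop = FALSE]
      } else if (half > 1L) {
        p1[, 2:half] <- p1[, 2:half] + p2[, n_fft:(half + 1L), drop = FALSE]
      }
      p_acc <- p_acc + p1
    }
    p_acc <- p_acc / n_frames
    for (b in seq_along(band_bins))
      out[, b, e] <- if (length(band_bins[[b]]))
        rowSums(p_acc[, band_bins[[b]], drop = FALSE]) else 0
  }
  out
}

#' Differential entropy of a band-limited Gaussian signal
#'
#' For a Gaussian signal with band power (variance) P, the differential
#' entropy is `0.5 * log(2 * pi * e * P)` nats — a log band-power feature.
#' Powers below the floor `eps` are clamped before the logarithm so silent
#' fixtures do not produce `-Inf`.
#'
#' @param power non-negative band power(s), uV^2; any numeric array.
#' @param eps power floor (default 1e-12 uV^2).
#' @return differential entropy in nats, same shape as `power`.
#' @examples
#' differential_entropy(1)            # 0.5 * log(2 * pi * e) ~ 1.4189
#' differential_entropy(1 / (2 * pi * exp(1)))  # 0
#' @export
differential_entropy <- function(power, eps = 1e-12) {
  if (any(power < 0, na.rm = TRUE))
    stop("negative band power: upstream power estimate violated its contract")
  0.5 * log(2 * pi * exp(1) * pmax(power, eps))
}

#' Compute per-epoch, per-band differential-entropy features
#'
#' The manual feature-extraction stage: segment into 1-s epochs, estimate
#' band power per epoch via the windowed FFT, take the Gaussian
#' differential-entropy closed form, and optionally smooth along the epoch
#' axis with a centred moving average.
#'
#' @param rec an [eeg_recording()].
#' @param bands a [band_set()] (default: the five canonical bands).
#' @param epoch_len_s epoch length in seconds (default 1).
#' @param n_fft FFT length (default 256).
#' @param smooth_span odd moving-average span in epochs, or `NULL` to skip
#'   smoothing (default `NULL`; the pipeline default used by
#'   [run_benchmark()] and the CLI is 5).
#' @return object of class `de_features`: list with `values`
#'   (`n_channels x n_bands x n_epochs` array, nats), `band_set`,
#'   `channel_names`, `epoch_len_s`, `smoothed`, `span`.
#' @export
compute_de_features <- function(rec, bands = default_bands(), epoch_len_s = 1,
                                n_fft = 256, smooth_span = NULL) {
  grid <- segment_epochs(rec, epoch_len_s)
  p <- epoch_band_power(rec, grid, bands, n_fft)
  de <- structure(list(values = differential_entropy(p),
                       band_set = bands,
                       channel_names = rec$channel_names,
                       epoch_len_s = epoch_len_s,
                       smoothed = FALSE, span = NA_integer_),
                  class = "de_features")
  if (!is.null(smooth_span)) de <- smooth_moving_average(de, smooth_span)
  de
}

#' @export
print.de_features <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<de_features> %d channels x %d bands x %d epochs (%g s)%s\n",
              d[1], d[2], d[3], x$epoch_len_s,
              if (isTRUE(x$smoothed)) sprintf(", smoothed span %d", x$span) else ""))
  invisible(x)
}

#' Centred moving-average smoothing along the epoch axis
#'
#' Window shrinks symmetrically at the series edges (the first value of a
#' span-3 smooth averages epochs 1-2, etc. — no padding, no phase shift).
#' Never smooths across recording boundaries: it operates on one feature
#' array at a time.
#'
#' @param features a `de_features` object from [compute_de_features()].
#' @param span odd window length in epochs; span 1 is the identity.
#' @return the smoothed `de_features` (flag and span recorded).
#' @export
smooth_moving_average <- function(features, span) {
  stopifnot(inherits(features, "de_features"))
  span <- as.integer(span)
  if (span < 1L || span %% 2L == 0L)
    stop("span must be a positive odd integer, got ", span)
  v <- features$values
  if (span > 1L) {
    ne <- dim(v)[3]
    half <- span %/% 2L
    sm <- array(0, dim(v), dimnames = dimnames(v))
    for (e in seq_len(ne)) {
      lo <- max(1L, e - half); hi <- min(ne, e + half)
      k <- min(e - lo, hi - e)        # symmetric shrink at the edges
      idx <- (e - k):(e + k)
      sm[, , e] <- if (length(idx) > 1L)
        apply(v[, , idx, drop = FALSE], c(1, 2), mean) else v[, , e]
    }
    v <- sm
  }
  features$values <- v
  features$smoothed <- TRUE
  features$span <- span
  features
}

#' Serialize / load differential-entropy features (HDF5)
#'
#' Layout: datasets `values`, `band_names`, `band_low_hz`, `band_high_hz`,
#' `channel_names`, `epoch_len_s`, `smoothed`, `span`.
#'
#' @param features a `de_features` object.
#' @param path HDF5 file path.
#' @return `write_de_features`: `path` invisibly; `read_de_features`: the
#'   `de_features` object.
#' @export
write_de_features <- function(features, path) {
  stopifnot(inherits(features, "de_features"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(features$values, path, "values")
  rhdf5::h5write(features$band_set$name, path, "band_names")
  rhdf5::h5write(features$band_set$low_hz, path, "band_low_hz")
  rhdf5::h5write(features$band_set$high_hz, path, "band_high_hz")
  rhdf5::h5write(features$channel_names, path, "channel_names")
  rhdf5::h5write(features$epoch_len_s, path, "epoch_len_s")
  rhdf5::h5write(as.integer(features$smoothed), path, "smoothed")
  rhdf5::h5write(as.integer(if (is.na(features$span)) -1L else features$span),
                 path, "span")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_de_features
#' @export
read_de_features <- function(path) {
  v <- rhdf5::h5read(path, "values")
  bands <- band_set(as.character(rhdf5::h5read(path, "band_names")),
                    as.numeric(rhdf5::h5read(path, "band_low_hz")),
                    as.numeric(rhdf5::h5read(path, "band_high_hz")))
  ch <- as.character(rhdf5::h5read(path, "channel_names"))
  dimnames(v) <- list(ch, bands$name, NULL)
  span <- as.integer(rhdf5::h5read(path, "span"))
  structure(list(values = v, band_set = bands, channel_names = ch,
                 epoch_len_s = as.numeric(rhdf5::h5read(path, "epoch_len_s")),
                 smoothed = as.logical(as.integer(rhdf5::h5read(path, "smoothed"))),
                 span = if (span < 0L) NA_integer_ else span),
            class = "de_features")
}
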