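#' Configure the synthetic-EEG simulator
#'
#' The simulator is the package's test bed standing in for the
#' access-restricted emotional-EEG datasets. Each channel is a sum of
#' band-limited Gaussian noise components — white noise brick-wall
#' band-passed in the frequency domain (zero-phase) and rescaled to an
#' exact target variance per band — plus a broadband noise floor. A class
#' effect multiplies the power of one band on a channel subset, producing
#' the hemispheric band-power asymmetry the AsMap is designed to expose:
#' an affected (left, right) pair's expected raw AsMap entry in that band
#' is `0.5 * log(gain)` by the differential-entropy closed form.
#'
#' Defaults state the simulated world: 200 Hz sampling, 60-s trials, base
#' band powers delta 20, theta 10, alpha 8, beta 4, gamma 2 uV^2
#' (decreasing with frequency as in scalp EEG), 1 uV^2 broadband floor,
#' and a gamma-band effect on the left-hemisphere channels with gains
#' 0.5 / 1.0 / 2.0 for the negative / neutral / positive classes —
#' mirroring the finding that gamma carries the discriminative asymmetry.
#'
#' @param montage a [montage()] (default: the packaged 62-channel one).
#' @param fs sampling rate, Hz.
#' @param duration_s seconds per trial.
#' @param bands a [band_set()].
#' @param base_band_power named numeric vector, uV^2 per band.
#' @param noise_power broadband white-noise floor, uV^2.
#' @param effects data.frame with columns `class_name`, `band`, `gain` and
#'   a list-column `channels`; `NULL` builds the default gamma-asymmetry
#'   template from the montage's left-hemisphere channels.
#' @param classes class names (scheme `seed3` by default ordering).
#' @param scheme label scheme for the generated labels.
#' @param n_trials_per_class trials per class.
#' @param seed master seed; per-trial seeds are derived by counter.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(montage = default_montage("seed62"), fs = 200,
                         duration_s = 60, bands = default_bands(),
                         base_band_power = c(delta = 20, theta = 10, alpha = 8,
                                             beta = 4, gamma = 2),
                         noise_power = 1,
                         effects = NULL,
                         classes = c("negative", "neutral", "positive"),
                         scheme = "seed3",
                         n_trials_per_class = 5, seed = 1L) {
  stopifnot(inherits(montage, "montage"), fs > 0, duration_s > 0,
            noise_power >= 0, n_trials_per_class >= 1)
  if (!setequal(names(base_band_power), bands$name))
    stop("base_band_power must name every band exactly once")
  if (any(base_band_power <= 0)) stop("band powers must be positive")
  if (is.null(effects)) {
    left <- montage$hemispheric_pairs[, 1]
    gains <- c(0.5, 1.0, 2.0)[seq_along(classes)]
    gains[is.na(gains)] <- 1.0
    effects <- data.frame(class_name = classes, band = "gamma",
                          gain = gains, stringsAsFactors = FALSE)
    effects$channels <- rep(list(left), length(classes))
  }
  stopifnot(all(c("class_name", "band", "gain", "channels") %in% names(effects)))
  if (any(effects$gain <= 0)) stop("effect gains must be positive")
  unknown_band <- setdiff(effects$band, bands$name)
  if (length(unknown_band)) stop("effect names unknown band: ",
                                 paste(unknown_band, collapse = ", "))
  unknown_ch <- setdiff(unlist(effects$channels), montage$channel_order)
  if (length(unknown_ch)) stop("effect names unknown channel(s): ",
                               paste(unknown_ch, collapse = ", "))
  if (is.null(label_schemes[[scheme]]))
    stop("unknown label scheme: ", scheme)
  structure(list(montage = montage, fs = fs, duration_s = duration_s,
                 bands = bands, base_band_power = base_band_power,
                 noise_power = noise_power, effects = effects,
                 classes = classes, scheme = scheme,
                 n_trials_per_class = as.integer(n_trials_per_class),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %d ch @ %g Hz, %g s/trial, %d trials x %d classes (%s), seed %d\n",
              length(x$montage$channel_order), x$fs, x$duration_s,
              x$n_trials_per_class, length(x$classes),
              paste(x$classes, collapse = "/"), x$seed))
  invisible(x)
}

# brick-wall zero-phase band-pass of white noise, rescaled to exact variance
band_limited_noise <- function(n, fs, low, high, target_var) {
  z <- rnorm(n)
  Z <- fft(z)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)       # mirrored half-spectrum
  Z[freqs < low | freqs > high] <- 0
  x <- Re(fft(Z, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) stop("degenerate band (no FFT bins) in ", low, "-", high, " Hz")
  x / s * sqrt(target_var)
}

#' Derive the deterministic per-trial seed
#'
#' `hash(master, class index, trial index)` by affine counter, kept inside
#' the 32-bit integer range so no seed collides across a run.
#' @keywords internal
trial_seed <- function(master, class_index, trial_index) {
  as.integer((as.numeric(master) * 7919 + class_index * 104729 +
                trial_index * 131) %% 2147483647)
}

#' Generate one synthetic EEG trial
#'
#' @param cfg a [synth_config()].
#' @param class_name which class's effect template to apply (a gain of 1.0
#'   is a null effect).
#' @param trial_seed integer seed for this trial (derive via the master
#'   seed for dataset generation).
#' @return an [eeg_recording()] in the montage's channel order, `trial_id`
#'   recording class and seed.
#' @export
generate_trial <- function(cfg, class_name, trial_seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!class_name %in% cfg$classes)
    stop("unknown class: ", class_name, " (classes: ",
         paste(cfg$classes, collapse = ", "), ")")
  set.seed(as.integer(trial_seed))
  chans <- cfg$montage$channel_order
  n <- round(cfg$fs * cfg$duration_s)
  eff <- cfg$effects[cfg$effects$class_name == class_name, , drop = FALSE]
  data <- matrix(0, length(chans), n)
  for (ci in seq_along(chans)) {
    x <- if (cfg$noise_power > 0) rnorm(n, 0, sqrt(cfg$noise_power)) else numeric(n)
    for (bi in seq_len(nrow(cfg$bands))) {
      bname <- cfg$bands$name[bi]
      pow <- cfg$base_band_power[[bname]]
      if (nrow(eff)) {
        hit <- eff$band == bname &
          vapply(eff$channels, function(cc) chans[ci] %in% cc, TRUE)
        for (g in eff$gain[hit]) pow <- pow * g
      }
      x <- x + band_limited_noise(n, cfg$fs, cfg$bands$low_hz[bi],
                                  cfg$bands$high_hz[bi], pow)
    }
    data[ci, ] <- x
  }
  eeg_recording(data, cfg$fs, chans,
                subject_id = "synthetic",
                trial_id = sprintf("%s_seed%d", class_name, as.integer(trial_seed)))
}

#' Generate a balanced labelled synthetic dataset
#'
#' `n_trials_per_class` trials per class; per-trial seeds derived from the
#' master seed by counter, so the whole dataset is reproducible and no two
#' trials share a seed.
#'
#' @param cfg a [synth_config()].
#' @return list with `recordings` (list of [eeg_recording()]),
#'   `labels` (data.frame `trial_id`, `class_name`, `class_index`), and
#'   `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  recs <- list(); labs <- list()
  i <- 0L
  for (k in seq_along(cfg$classes)) {
    for (t in seq_len(cfg$n_trials_per_class)) {
      i <- i + 1L
      ts <- trial_seed(cfg$seed, k, t)
      rec <- generate_trial(cfg, cfg$classes[k], ts)
      rec$trial_id <- sprintf("trial%03d_%s", i, cfg$classes[k])
      recs[[i]] <- rec
      lab <- emotion_label(cfg$scheme, cfg$classes[k])
      labs[[i]] <- data.frame(trial_id = rec$trial_id,
                              class_name = lab$class_name,
                              class_index = lab$class_index,
                              stringsAsFactors = FALSE)
    }
  }
  list(recordings = recs, labels = do.call(rbind, labs), config = cfg)
}
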