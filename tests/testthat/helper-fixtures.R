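# Fixtures are built in code: no binary test data ships with the package.

# white-noise recording
noise_recording <- function(n_channels = 2, fs = 200, duration_s = 60,
                            sd = 1, seed = 1,
                            channel_names = paste0("CH", seq_len(n_channels))) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_channels * round(fs * duration_s), 0, sd),
                       n_channels),
                fs, channel_names)
}

# pure sinusoid on every channel
sine_recording <- function(freq, amplitude, n_channels = 2, fs = 200,
                           duration_s = 60) {
  t <- seq_len(round(fs * duration_s)) / fs
  x <- amplitude * sin(2 * pi * freq * t)
  eeg_recording(matrix(rep(x, each = n_channels), n_channels), fs,
                paste0("CH", seq_len(n_channels)))
}

# 4-channel toy montage: two hemispheric pairs, one frontal-posterior pair
toy_montage <- function() {
  montage(channel_order = c("L1", "R1", "L2", "R2"),
          hemispheric_pairs = rbind(c("L1", "R1"), c("L2", "R2")),
          frontal_posterior_pairs = rbind(c("L1", "L2")),
          name = "toy4")
}

# windowed_de object with hand-chosen DE values (channels x bands x windows)
toy_windowed <- function(values, channel_names, band_names = NULL,
                         window_len_s = 3) {
  if (is.null(band_names)) band_names <- dimnames(values)[[2]]
  if (is.null(band_names)) band_names <- paste0("b", seq_len(dim(values)[2]))
  edges <- seq_len(length(band_names))
  structure(list(values = values,
                 band_set = band_set(band_names, edges, edges + 0.5),
                 channel_names = channel_names,
                 window_len_s = window_len_s, epoch_len_s = 1,
                 smoothed = FALSE, span = NA_integer_),
            class = "windowed_de")
}

# small synthetic config on the toy montage (fast to generate)
toy_synth_config <- function(duration_s = 60, ..., seed = 1) {
  synth_config(montage = toy_montage(), duration_s = duration_s,
               n_trials_per_class = 1, seed = seed, ...)
}
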