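#' Assemble per-window feature examples from windowed DE features
#'
#' Expands a list of per-trial `windowed_de` objects into a feature set:
#' normalised AsMap stacks for `method = "asmap"` (a `C x C x K x N`
#' array) or baseline vectors for `"de"`, `"dasm"`, `"rasm"`, `"dcau"` (an
#' `N x D` matrix). The trial label is assigned to every window of the
#' trial; `trial` records window provenance for group-aware splits.
#'
#' @param windowed_list list of `windowed_de`, one per trial.
#' @param labels character vector of per-trial class names, parallel to
#'   `windowed_list`.
#' @param method `"asmap"`, `"de"`, `"dasm"`, `"rasm"` or `"dcau"`.
#' @param montage a [montage()] (needed for the pair-based baselines).
#' @param band_subset band names or `"all"`.
#' @return list with `x`, `y` (class name per window), `trial` (trial index
#'   per window), `method`, `band_subset`.
#' @export
assemble_features <- function(windowed_list, labels,
                              method = c("asmap", "de", "dasm", "rasm", "dcau"),
                              montage = NULL, band_subset = "all") {
  method <- match.arg(tolower(method),
                      c("asmap", "de", "dasm", "rasm", "dcau"))
  stopifnot(length(windowed_list) == length(labels))
  xs <- list(); ys <- list(); trials <- list()
  for (i in seq_along(windowed_list)) {
    wd <- windowed_list[[i]]
    nw <- dim(wd$values)[3]
    if (method == "asmap") {
      xs[[i]] <- build_asmap_stack(wd, band_subset)
    } else {
      mth <- toupper(method)
      xs[[i]] <- t(vapply(seq_len(nw), function(wi)
        baseline_features(wd, wi, mth, montage, band_subset)$values,
        numeric(baseline_features(wd, 1L, mth, montage, band_subset)$length)))
    }
    ys[[i]] <- rep(labels[i], nw)
    trials[[i]] <- rep(i, nw)
  }
  x <- if (method == "asmap") {
    d <- dim(xs[[1]])
    total <- sum(vapply(xs, function(a) dim(a)[4], 0L))
    out <- array(0, c(d[1:3], total))
    at <- 0L
    for (a in xs) {
      n <- dim(a)[4]
      out[, , , (at + 1L):(at + n)] <- a
      at <- at + n
    }
    out
  } else do.call(rbind, xs)
  list(x = x, y = unlist(ys), trial = unlist(trials),
       method = method, band_subset = band_subset)
}

#' Hold out a test set over windows
#'
#' `"stratified"` samples windows per class (ratios preserved within one
#' example); `"grouped"` holds out whole trials per class, so no trial
#' contributes windows to both sides — the subject/trial-independent
#' protocol.
#'
#' @param y class name per window.
#' @param trial trial index per window.
#' @param fraction test fraction.
#' @param type `"stratified"` or `"grouped"`.
#' @return integer vector of test window indices.
#' @export
holdout_split <- function(y, trial, fraction = 0.2,
                          type = c("stratified", "grouped")) {
  type <- match.arg(type)
  if (type == "stratified") return(stratified_split(y, fraction))
  test <- integer(0)
  tl <- tapply(y, trial, function(v) v[1])
  for (cl in unique(tl)) {
    tr_ids <- as.integer(names(tl)[tl == cl])
    n_hold <- max(1L, round(length(tr_ids) * fraction))
    if (n_hold >= length(tr_ids)) n_hold <- length(tr_ids) - 1L
    held <- sample(tr_ids, n_hold)
    test <- c(test, which(trial %in% held))
  }
  sort(test)
}

#' Run the feature-method x band x window-size benchmark
#'
#' The end-to-end experiment grid: for every combination, DE features are
#' windowed, turned into AsMap stacks (fed to the CNN) or baseline vectors
#' (fed directly to the dense softmax head), split into held-out test
#' windows and a training set, trained, and scored. Returns one accuracy
#' per cell.
#'
#' @param recordings list of [eeg_recording()], one per trial.
#' @param labels data.frame with `class_name` per trial (as produced by
#'   [generate_dataset()]), or a character vector.
#' @param methods subset of `c("asmap", "de", "dasm", "rasm", "dcau")`.
#' @param band_subsets list of band selections (band names, or `"all"`).
#' @param window_sizes window lengths in seconds.
#' @param montage a [montage()].
#' @param bands a [band_set()].
#' @param epoch_len_s,n_fft,smooth_span manual feature-extraction settings
#'   (defaults: 1-s epochs, 256-point FFT, span-5 smoothing).
#' @param seed master seed: determines the test split and the training
#'   seed of every cell.
#' @param test_fraction held-out fraction of windows (or trials).
#' @param split_type `"stratified"` or `"grouped"` (see [holdout_split()]).
#' @param train_cfg a [train_config()]; its seed field is overridden per
#'   cell from `seed`.
#' @return data.frame with columns `method`, `band`, `window_s`, `seed`,
#'   `accuracy`, `n_test`.
#' @export
run_benchmark <- function(recordings, labels,
                          methods = c("asmap", "de"),
                          band_subsets = list("gamma", "all"),
                          window_sizes = 3,
                          montage = default_montage("seed62"),
                          bands = default_bands(),
                          epoch_len_s = 1, n_fft = 256, smooth_span = 5,
                          seed = 1L, test_fraction = 0.2,
                          split_type = c("stratified", "grouped"),
                          train_cfg = train_config()) {
  split_type <- match.arg(split_type)
  if (is.data.frame(labels)) labels <- labels$class_name
  stopifnot(length(recordings) == length(labels))
  de_list <- lapply(recordings, compute_de_features, bands = bands,
                    epoch_len_s = epoch_len_s, n_fft = n_fft,
                    smooth_span = smooth_span)
  rows <- list()
  for (ws in window_sizes) {
    wd_list <- lapply(de_list, window_average, window_len_s = ws)
    for (band in band_subsets) for (method in methods) {
      fs <- assemble_features(wd_list, labels, method, montage, band)
      set.seed(seed)
      test_idx <- holdout_split(fs$y, fs$trial, test_fraction, split_type)
      train_idx <- setdiff(seq_along(fs$y), test_idx)
      classes <- sort(unique(fs$y))
      head <- head_config(n_classes = length(classes))
      model <- if (method == "asmap")
        build_model(cnn_config(), head, input_shape = dim(fs$x)[1:3])
      else
        build_dense_model(head, input_dim = ncol(fs$x))
      cfg <- train_cfg
      cfg$seed <- as.integer(seed)
      model <- train_model(model, slice_examples(fs$x, train_idx),
                           fs$y[train_idx], cfg)
      rep <- evaluate_model(model, slice_examples(fs$x, test_idx),
                            fs$y[test_idx])
      band_name <- if (length(band) == 1L) band else paste(band, collapse = "+")
      if (toupper(band_name) %in% c("ALL", "ALL BAND")) band_name <- "ALL"
      rows[[length(rows) + 1L]] <- data.frame(
        method = if (method == "asmap") "AsMap+CNN" else toupper(method),
        band = band_name, window_s = ws, seed = seed,
        accuracy = rep$accuracy, n_test = rep$n_test,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
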