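#' Average differential-entropy features over fixed windows
#'
#' Consecutive epochs are grouped into non-overlapping windows of
#' `window_len_s` seconds (an integer multiple of the epoch length; the
#' canonical choices are 3, 6, 12 and 30 s) and the DE values are averaged
#' within each window, per channel and band. A trailing partial window is
#' discarded.
#'
#' @param features a `de_features` object from [compute_de_features()].
#' @param window_len_s window length in seconds.
#' @return object of class `windowed_de`: list with `values`
#'   (`n_channels x n_bands x n_windows`), `band_set`, `channel_names`,
#'   `window_len_s`, `epoch_len_s`, `smoothed`, `span`.
#' @export
window_average <- function(features, window_len_s) {
  stopifnot(inherits(features, "de_features"))
  ratio <- window_len_s / features$epoch_len_s
  if (window_len_s <= 0 || abs(ratio - round(ratio)) > 1e-9)
    stop("window_len_s (", window_len_s,
         ") must be a positive integer multiple of epoch_len_s (",
         features$epoch_len_s, ")")
  epw <- as.integer(round(ratio))
  ne <- dim(features$values)[3]
  nw <- ne %/% epw
  if (nw < 1L)
    stop("no complete window: ", ne, " epochs of ", features$epoch_len_s,
         " s cannot fill a ", window_len_s, " s window")
  v <- features$values[, , seq_len(nw * epw), drop = FALSE]
  d <- dim(v)
  # mean over blocks of epw consecutive epochs
  dim(v) <- c(d[1] * d[2], epw, nw)
  out <- apply(v, c(1, 3), mean)
  dim(out) <- c(d[1], d[2], nw)
  dimnames(out) <- list(features$channel_names, features$band_set$name, NULL)
  structure(list(values = out, band_set = features$band_set,
                 channel_names = features$channel_names,
                 window_len_s = window_len_s,
                 epoch_len_s = features$epoch_len_s,
                 smoothed = features$smoothed, span = features$span),
            class = "windowed_de")
}

#' @export
print.windowed_de <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<windowed_de> %d channels x %d bands x %d windows (%g s windows)\n",
              d[1], d[2], d[3], x$window_len_s))
  invisible(x)
}

#' Build the raw AsMap for one analysis window
#'
#' The AsMap is the channels x channels x bands tensor of all pairwise
#' inter-channel DE differences, `A[i, j, k] = DE(i, k) - DE(j, k)`: a
#' quantitative picture of band-power asymmetry between every pair of
#' channels, independent of their scalp location. The raw tensor has an
#' exactly zero diagonal and is antisymmetric in its first two axes.
#'
#' @param windowed a `windowed_de` from [window_average()].
#' @param window_index which window, 1-based.
#' @param band_subset character vector of band names, or `"all"` for every
#'   band in the set.
#' @return object of class `asmap`: list with `values`
#'   (`C x C x n_selected_bands`), `band_names`, `channel_names`,
#'   `window_index`, `normalized = FALSE`.
#' @examples
#' # a 3-channel toy: DE column (2, 1, 0) gives rows (0,1,2), (-1,0,1), (-2,-1,0)
#' @export
build_asmap <- function(windowed, window_index, band_subset = "all") {
  stopifnot(inherits(windowed, "windowed_de"))
  nw <- dim(windowed$values)[3]
  if (window_index < 1L || window_index > nw)
    stop("window_index ", window_index, " out of range 1..", nw)
  sel <- resolve_bands(band_subset, windowed$band_set)
  k <- match(sel, windowed$band_set$name)
  de <- windowed$values[, k, window_index, drop = FALSE]
  nc <- dim(de)[1]
  vals <- array(0, c(nc, nc, length(k)),
                dimnames = list(windowed$channel_names,
                                windowed$channel_names, sel))
  for (b in seq_along(k)) {
    col <- de[, b, 1]
    vals[, , b] <- outer(col, col, "-")
  }
  structure(list(values = vals, band_names = sel,
                 channel_names = windowed$channel_names,
                 window_index = as.integer(window_index),
                 normalized = FALSE),
            class = "asmap")
}

#' @export
print.asmap <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<asmap%s> %d x %d x %d (bands: %s), window %d\n",
              if (x$normalized) " normalized" else " raw",
              d[1], d[2], d[3], paste(x$band_names, collapse = ", "),
              x$window_index))
  invisible(x)
}

#' Min-max normalise an AsMap to the unit interval
#'
#' Each band slice is scaled independently to `[0, 1]` via
#' `(v - min) / (max - min)`; a constant slice (e.g. perfectly symmetric
#' DE) maps to 0.5, the midpoint, preserving the complementarity
#' `v[i, j] + v[j, i] = 1` that the antisymmetric raw map induces.
#' Per-slice scope keeps single-band and all-band runs consistent and
#' preserves inter-band contrast for the CNN.
#'
#' @param asmap a raw `asmap` from [build_asmap()].
#' @return the `asmap` with values in `[0, 1]` and `normalized = TRUE`.
#' @export
normalize_asmap <- function(asmap) {
  stopifnot(inherits(asmap, "asmap"))
  if (asmap$normalized) return(asmap)
  v <- asmap$values
  for (b in seq_len(dim(v)[3])) {
    s <- v[, , b]
    rng <- range(s)
    v[, , b] <- if (rng[2] > rng[1]) (s - rng[1]) / (rng[2] - rng[1])
                else array(0.5, dim(s))
  }
  asmap$values <- v
  asmap$normalized <- TRUE
  asmap
}

#' Classic DE-based baseline feature vectors
#'
#' The four manual feature families the AsMap generalises:
#' \describe{
#'   \item{DE}{all channel x band DE values, flattened channel-major,
#'     band-minor (62 channels x 5 bands = 310 values).}
#'   \item{DASM}{differential asymmetry, `DE(left) - DE(right)` over the
#'     montage's hemispheric pairs (27 pairs x 5 bands = 135).}
#'   \item{RASM}{relative asymmetry, `DE(left) / DE(right)` over the same
#'     pairs (135); a divisor within `1e-9` of zero yields a sign-preserving
#'     cap of `1e9`, flagged in the result's `capped` field.}
#'   \item{DCAU}{differential caudality, `DE(frontal) - DE(posterior)` over
#'     the frontal-posterior pairs (23 pairs x 5 bands = 115).}
#' }
#' Pair features are ordered pair-major, band-minor, following the montage's
#' pair list order. Every DASM/DCAU entry equals the raw AsMap entry at the
#' corresponding pair indices.
#'
#' @param windowed a `windowed_de` from [window_average()].
#' @param window_index which window, 1-based.
#' @param method `"DE"`, `"DASM"`, `"RASM"` or `"DCAU"`.
#' @param montage a [montage()] whose pair lists cover the method.
#' @param band_subset band names or `"all"`.
#' @return object of class `baseline_features`: list with `method`, `values`
#'   (named numeric vector), `length`, `band_names`, `capped` (RASM only).
#' @export
baseline_features <- function(windowed, window_index,
                              method = c("DE", "DASM", "RASM", "DCAU"),
                              montage, band_subset = "all") {
  stopifnot(inherits(windowed, "windowed_de"))
  method <- match.arg(method)
  nw <- dim(windowed$values)[3]
  if (window_index < 1L || window_index > nw)
    stop("window_index ", window_index, " out of range 1..", nw)
  sel <- resolve_bands(band_subset, windowed$band_set)
  kb <- match(sel, windowed$band_set$name)
  de <- windowed$values[, kb, window_index, drop = FALSE]  # C x K x 1
  dim(de) <- dim(de)[1:2]
  rownames(de) <- windowed$channel_names
  capped <- FALSE

  if (method == "DE") {
    # channel-major, band-minor: all bands of channel 1, then channel 2, ...
    vals <- as.vector(t(de))
    names(vals) <- as.vector(outer(sel, rownames(de),
                                   function(b, c) paste0(c, ".", b)))
  } else {
    pairs <- if (method == "DCAU") montage$frontal_posterior_pairs
             else montage$hemispheric_pairs
    if (nrow(pairs) == 0L)
      stop("montage has no pair list for method ", method)
    ia <- match(pairs[, 1], windowed$channel_names)
    ib <- match(pairs[, 2], windowed$channel_names)
    if (anyNA(ia) || anyNA(ib))
      stop("montage pair channel absent from features: ",
           paste(unique(c(pairs[, 1][is.na(ia)], pairs[, 2][is.na(ib)])),
                 collapse = ", "))
    a <- de[ia, , drop = FALSE]  # pairs x bands
    b <- de[ib, , drop = FALSE]
    m <- switch(method,
                DASM = a - b,
                DCAU = a - b,
                RASM = {
                  small <- abs(b) < 1e-9
                  if (any(small)) {
                    capped <- TRUE
                    b[small] <- ifelse(b[small] < 0, -1e-9, 1e-9)
                  }
                  r <- a / b
                  pmin(pmax(r, -1e9), 1e9)
                })
    # pair-major, band-minor
    vals <- as.vector(t(m))
    names(vals) <- as.vector(outer(sel, paste0(pairs[, 1], "-", pairs[, 2]),
                                   function(band, p) paste0(p, ".", band)))
  }
  structure(list(method = method, values = vals, length = length(vals),
                 band_names = sel, capped = capped),
            class = "baseline_features")
}

#' @export
print.baseline_features <- function(x, ...) {
  cat(sprintf("<baseline_features %s> length %d (bands: %s)%s\n", x$method,
              x$length, paste(x$band_names, collapse = ", "),
              if (isTRUE(x$capped)) " [RASM divisor cap hit]" else ""))
  invisible(x)
}

#' Stack normalised AsMaps over all windows of a recording
#'
#' Convenience for the classifier: builds and normalises one AsMap per
#' window and stacks them on a fourth axis in CNN input order
#' (row-channel, column-channel, band, example).
#'
#' @inheritParams build_asmap
#' @return numeric array `C x C x K x n_windows` of values in `[0, 1]`.
#' @export
build_asmap_stack <- function(windowed, band_subset = "all") {
  stopifnot(inherits(windowed, "windowed_de"))
  nw <- dim(windowed$values)[3]
  sel <- resolve_bands(band_subset, windowed$band_set)
  nc <- length(windowed$channel_names)
  out <- array(0, c(nc, nc, length(sel), nw))
  for (wi in seq_len(nw))
    out[, , , wi] <- normalize_asmap(build_asmap(windowed, wi, sel))$values
  out
}

#' Serialize an AsMap (HDF5) or export a band slice as a PGM image
#'
#' HDF5 layout: `values`, `band_names`, `channel_names`, `window_index`,
#' `normalized`. `export_asmap_pgm` writes one band slice as a plain-text
#' PGM (P2) grayscale image, values scaled to 0-255 — the package's
#' stand-in for PNG rendering of asymmetry maps.
#'
#' @param asmap an `asmap`.
#' @param path output file path.
#' @param band band name to export (PGM only).
#' @return `path`, invisibly.
#' @export
write_asmap <- function(asmap, path) {
  stopifnot(inherits(asmap, "asmap"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(asmap$values, path, "values")
  rhdf5::h5write(asmap$band_names, path, "band_names")
  rhdf5::h5write(asmap$channel_names, path, "channel_names")
  rhdf5::h5write(asmap$window_index, path, "window_index")
  rhdf5::h5write(as.integer(asmap$normalized), path, "normalized")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_asmap
#' @export
read_asmap <- function(path) {
  v <- rhdf5::h5read(path, "values")
  bn <- as.character(rhdf5::h5read(path, "band_names"))
  ch <- as.character(rhdf5::h5read(path, "channel_names"))
  dimnames(v) <- list(ch, ch, bn)
  structure(list(values = v, band_names = bn, channel_names = ch,
                 window_index = as.integer(rhdf5::h5read(path, "window_index")),
                 normalized = as.logical(as.integer(rhdf5::h5read(path, "normalized")))),
            class = "asmap")
}

#' @rdname write_asmap
#' @export
export_asmap_pgm <- function(asmap, path, band = asmap$band_names[1]) {
  stopifnot(inherits(asmap, "asmap"))
  if (!band %in% asmap$band_names) stop("unknown band: ", band)
  s <- asmap$values[, , match(band, asmap$band_names)]
  rng <- range(s)
  g <- if (rng[2] > rng[1]) round(255 * (s - rng[1]) / (rng[2] - rng[1]))
       else array(128, dim(s))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(g), nrow(g)), "255"), con)
  write(t(g), con, ncolumns = ncol(g))
  invisible(path)
}
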