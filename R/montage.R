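#' Electrode montage with asymmetry pair lists
#'
#' A montage fixes the channel ordering used for AsMap rows/columns and
#' carries the two pair lists the baseline features are defined on:
#' left-right homologous (hemispheric) pairs for DASM/RASM and
#' frontal-posterior pairs for DCAU.
#'
#' @param channel_order character vector of channel names, the authoritative
#'   ordering.
#' @param hemispheric_pairs two-column character matrix (left, right), one
#'   row per left-right pair.
#' @param frontal_posterior_pairs two-column character matrix
#'   (frontal, posterior).
#' @param name optional montage identifier.
#' @return object of class `montage`.
#' @seealso [default_montage()], [load_montage()]
#' @export
montage <- function(channel_order, hemispheric_pairs,
                    frontal_posterior_pairs, name = NULL) {
  channel_order <- as.character(channel_order)
  if (anyDuplicated(channel_order))
    stop("duplicate names in channel_order")
  hp <- as_pair_matrix(hemispheric_pairs, "hemispheric_pairs")
  fp <- as_pair_matrix(frontal_posterior_pairs, "frontal_posterior_pairs")
  m <- structure(list(channel_order = channel_order,
                      hemispheric_pairs = hp,
                      frontal_posterior_pairs = fp,
                      name = name),
                 class = "montage")
  validate_montage(m)
  m
}

as_pair_matrix <- function(p, what) {
  if (is.matrix(p)) {
    if (ncol(p) != 2L) stop(what, " must have two columns")
    return(matrix(as.character(p), ncol = 2L,
                  dimnames = list(NULL, c("a", "b"))))
  }
  if (is.list(p))
    return(do.call(rbind, lapply(p, function(x) {
      if (length(x) != 2L) stop(what, ": each pair needs exactly 2 names")
      matrix(as.character(x), ncol = 2L, dimnames = list(NULL, c("a", "b")))
    })))
  stop(what, " must be a 2-column matrix or a list of pairs")
}

validate_montage <- function(m) {
  for (what in c("hemispheric_pairs", "frontal_posterior_pairs")) {
    p <- m[[what]]
    if (nrow(p) == 0L) next
    unknown <- setdiff(as.vector(p), m$channel_order)
    if (length(unknown))
      stop(what, " references unknown channel(s): ",
           paste(unknown, collapse = ", "))
    same <- p[, 1] == p[, 2]
    if (any(same))
      stop(what, " pairs a channel with itself: ", p[same, 1][1])
    key <- paste(p[, 1], p[, 2])
    if (anyDuplicated(key))
      stop("duplicate pair in ", what, ": ", key[duplicated(key)][1])
  }
  invisible(m)
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage%s> %d channels, %d hemispheric pairs, %d frontal-posterior pairs\n",
              if (!is.null(x$name)) paste0(" ", x$name) else "",
              length(x$channel_order), nrow(x$hemispheric_pairs),
              nrow(x$frontal_posterior_pairs)))
  invisible(x)
}

#' Load a montage from a configuration file
#'
#' The config lists `channel_order` plus the two pair lists, pairs written
#' `LEFT-RIGHT` (see the packaged files under
#' `system.file("extdata", package = "asmapr")` for the dialect).
#'
#' @param config_path path to a montage config file.
#' @return a [montage()].
#' @export
load_montage <- function(config_path) {
  cfg <- parse_config(config_path)
  order <- config_get(cfg, "channel_order")
  if (is.null(order)) stop("montage config lacks channel_order")
  split_pairs <- function(tokens, what) {
    if (is.null(tokens)) return(matrix(character(0), ncol = 2))
    parts <- strsplit(tokens, "-", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop(what, ": malformed pair ", tokens[bad][1])
    do.call(rbind, parts)
  }
  montage(order,
          split_pairs(config_get(cfg, "hemispheric_pairs"), "hemispheric_pairs"),
          split_pairs(config_get(cfg, "frontal_posterior_pairs"),
                      "frontal_posterior_pairs"),
          name = config_get(cfg, "name"))
}

#' Packaged default montages
#'
#' Two montages ship with the package as configuration files (not code):
#' `"seed62"`, a 62-channel montage in the SEED distribution order with 27
#' hemispheric and 23 frontal-posterior pairs (so that with five bands the
#' baseline feature dimensions are DE 310, DASM/RASM 135, DCAU 115), and
#' `"deap32"`, a 32-channel montage in DEAP order with 14 hemispheric and 11
#' frontal-posterior pairs. No authoritative printed channel ordering or
#' pair list exists for these dimensions; the files follow the datasets'
#' distribution conventions and are flagged as an assumption in the config
#' comments.
#'
#' @param which `"seed62"` or `"deap32"`.
#' @return a [montage()].
#' @examples
#' m <- default_montage("seed62")
#' nrow(m$hemispheric_pairs)  # 27
#' @export
default_montage <- function(which = c("seed62", "deap32")) {
  which <- match.arg(which)
  load_montage(system.file("extdata", paste0("montage_", which, ".txt"),
                           package = "asmapr", mustWork = TRUE))
}

#' Frequency band set
#'
#' Ordered named frequency bands. The default is the five canonical EEG
#' bands with inclusive edges delta (1-3 Hz), theta (4-7), alpha (8-13),
#' beta (14-30), gamma (31-50); frequencies in the gaps between printed
#' edges (e.g. 3.5 Hz) belong to no band.
#'
#' @param names character vector of band names.
#' @param low_hz,high_hz numeric vectors of band edges, Hz.
#' @return object of class `band_set`: data.frame with columns `name`,
#'   `low_hz`, `high_hz`.
#' @export
band_set <- function(names, low_hz, high_hz) {
  stopifnot(length(names) == length(low_hz),
            length(low_hz) == length(high_hz))
  if (anyDuplicated(names)) stop("duplicate band names")
  if (any(low_hz <= 0) || any(high_hz <= low_hz))
    stop("bands need 0 < low_hz < high_hz")
  structure(data.frame(name = as.character(names),
                       low_hz = as.numeric(low_hz),
                       high_hz = as.numeric(high_hz),
                       stringsAsFactors = FALSE),
            class = c("band_set", "data.frame"))
}

#' @rdname band_set
#' @export
default_bands <- function() {
  band_set(c("delta", "theta", "alpha", "beta", "gamma"),
           c(1, 4, 8, 14, 31),
           c(3, 7, 13, 30, 50))
}

#' Resolve a band-subset argument against a band set
#'
#' `"all"` (case-insensitive, also `"ALL BAND"`) selects every band.
#' @keywords internal
resolve_bands <- function(band_subset, bands) {
  if (is.null(band_subset)) return(bands$name)
  band_subset <- as.character(band_subset)
  if (length(band_subset) == 1L &&
      toupper(band_subset) %in% c("ALL", "ALL BAND", "ALLBAND"))
    return(bands$name)
  unknown <- setdiff(band_subset, bands$name)
  if (length(unknown))
    stop("unknown band name(s): ", paste(unknown, collapse = ", "))
  band_subset
}
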