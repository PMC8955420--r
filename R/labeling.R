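#' Emotion label schemes
#'
#' Labels are represented as `emotion_label` objects carrying the scheme,
#' the class name, and a stable 0-based class index in the scheme's listed
#' order:
#' \describe{
#'   \item{seed3}{negative (0), neutral (1), positive (2).}
#'   \item{deap_valence}{LV (0), HV (1).}
#'   \item{deap_arousal}{LA (0), HA (1).}
#'   \item{deap_quadrant}{HVHA (0), HVLA (1), LVHA (2), LVLA (3).}
#' }
#' @name emotion_label
#' @keywords internal
NULL

label_schemes <- list(
  seed3 = c("negative", "neutral", "positive"),
  deap_valence = c("LV", "HV"),
  deap_arousal = c("LA", "HA"),
  deap_quadrant = c("HVHA", "HVLA", "LVHA", "LVLA"))

emotion_label <- function(scheme, class_name) {
  classes <- label_schemes[[scheme]]
  if (is.null(classes)) stop("unknown label scheme: ", scheme)
  idx <- match(class_name, classes)
  if (is.na(idx)) stop("class ", sQuote(class_name),
                       " not in scheme ", scheme)
  structure(list(scheme = scheme, class_name = class_name,
                 class_index = idx - 1L),
            class = "emotion_label")
}

#' @export
print.emotion_label <- function(x, ...) {
  cat(sprintf("<emotion_label %s> %s (index %d)\n",
              x$scheme, x$class_name, x$class_index))
  invisible(x)
}

#' Binarize a 1-9 affective rating into low/high classes
#'
#' Ratings from `threshold` (default 5.5) to 9 map to the high class and
#' ratings below the threshold to the low class. Both printed rating
#' intervals of the DEAP scheme contain 5.5; the boundary is assigned to
#' the high class (`>=` rule).
#'
#' @param rating numeric rating in `[1, 9]`.
#' @param dimension `"valence"` or `"arousal"`.
#' @param threshold split point, default 5.5.
#' @return an [emotion_label] in scheme `deap_valence` or `deap_arousal`.
#' @examples
#' binarize_rating(6, "valence")$class_name   # "HV"
#' binarize_rating(5.5, "valence")$class_name # "HV" (boundary -> high)
#' @export
binarize_rating <- function(rating, dimension = c("valence", "arousal"),
                            threshold = 5.5) {
  dimension <- match.arg(dimension)
  if (!is.numeric(rating) || length(rating) != 1L || is.na(rating) ||
      rating < 1 || rating > 9)
    stop("rating must be a number in [1, 9], got ", rating)
  high <- rating >= threshold
  if (dimension == "valence")
    emotion_label("deap_valence", if (high) "HV" else "LV")
  else
    emotion_label("deap_arousal", if (high) "HA" else "LA")
}

#' Combine valence and arousal ratings into a quadrant label
#'
#' The four-class scheme is the cross-product of the two independent
#' binarizations: HVHA, HVLA, LVHA, LVLA.
#'
#' @param valence,arousal ratings in `[1, 9]`.
#' @param threshold split point, default 5.5.
#' @return an [emotion_label] in scheme `deap_quadrant`.
#' @examples
#' quadrant_label(7, 2)$class_name  # "HVLA"
#' @export
quadrant_label <- function(valence, arousal, threshold = 5.5) {
  v <- binarize_rating(valence, "valence", threshold)
  a <- binarize_rating(arousal, "arousal", threshold)
  emotion_label("deap_quadrant",
                paste0(v$class_name, a$class_name))
}

#' Map a SEED-style numeric code to its 3-class label
#'
#' Follows the dataset distribution convention: -1 negative, 0 neutral,
#' 1 positive. The mapping is configurable via `codes`.
#'
#' @param code integer in `{-1, 0, 1}` (under the default mapping).
#' @param codes named integer vector mapping class names to codes.
#' @return an [emotion_label] in scheme `seed3`.
#' @export
seed_label <- function(code, codes = c(negative = -1, neutral = 0, positive = 1)) {
  hit <- names(codes)[match(code, codes)]
  if (is.na(hit) || length(code) != 1L)
    stop("unknown SEED label code ", code, "; expected one of ",
         paste(codes, collapse = ", "))
  emotion_label("seed3", hit)
}

#' Read per-trial labels from a delimited table
#'
#' Accepts either a DEAP-style ratings table with columns `trial_id`,
#' `valence`, `arousal` (labels derived by binarization / quadrant
#' construction) or a SEED-style table with columns `trial_id`, `code`.
#'
#' @param path CSV/TSV file path.
#' @param scheme one of `"seed3"`, `"deap_valence"`, `"deap_arousal"`,
#'   `"deap_quadrant"`.
#' @param threshold rating split point for the DEAP schemes.
#' @return data.frame with columns `trial_id`, `class_name`, `class_index`.
#' @export
read_labels_table <- function(path, scheme = c("seed3", "deap_valence",
                                               "deap_arousal", "deap_quadrant"),
                              threshold = 5.5) {
  scheme <- match.arg(scheme)
  dt <- data.table::fread(path)
  if (!"trial_id" %in% names(dt)) stop("labels table lacks column trial_id")
  lab <- if (scheme == "seed3") {
    if ("class_name" %in% names(dt))
      lapply(dt$class_name, emotion_label, scheme = "seed3")
    else {
      if (!"code" %in% names(dt)) stop("seed3 labels need column code or class_name")
      lapply(dt$code, seed_label)
    }
  } else {
    if (scheme != "deap_arousal" && !"valence" %in% names(dt))
      stop("labels table lacks column valence")
    if (scheme != "deap_valence" && !"arousal" %in% names(dt))
      stop("labels table lacks column arousal")
    switch(scheme,
      deap_valence = lapply(dt$valence, binarize_rating, dimension = "valence",
                            threshold = threshold),
      deap_arousal = lapply(dt$arousal, binarize_rating, dimension = "arousal",
                            threshold = threshold),
      deap_quadrant = Map(quadrant_label, dt$valence, dt$arousal,
                          threshold = threshold))
  }
  data.frame(trial_id = as.character(dt$trial_id),
             class_name = vapply(lab, `[[`, "", "class_name"),
             class_index = vapply(lab, `[[`, 0L, "class_index"),
             stringsAsFactors = FALSE)
}
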