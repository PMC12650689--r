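#' Emotion categories
#'
#' The seven discrete emotion categories used throughout the package: six
#' target emotions plus a neutral state. Any other string is rejected at
#' parse time.
#'
#' @format A character vector of length 7.
#' @export
EMOTIONS <- c("happy", "sad", "disgust", "fear", "surprise", "anger", "neutral")

#' Validate emotion labels
#'
#' @param x character vector of candidate emotion labels.
#' @return `x`, unchanged, if every element is one of the seven admissible
#'   emotions; otherwise an error naming the offending values.
#' @export
as_emotion <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), EMOTIONS)
  if (length(bad) > 0L) {
    stop("unknown emotion label(s): ", paste(sQuote(bad), collapse = ", "),
         "; admissible values are: ", paste(EMOTIONS, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Map an emotion to the binary arousal classes
#'
#' Happy, disgust, fear, surprise and anger are high-arousal (`"HA"`); sad
#' and neutral are low-arousal (`"LA"`). Neutral is grouped with low arousal,
#' following the convention of earlier work on this dataset family.
#'
#' @param e character vector of emotion labels.
#' @return character vector of `"HA"` / `"LA"` labels.
#' @seealso [to_quadrant()], [task_scheme()]
#' @export
#' @examples
#' to_binary(c("happy", "sad", "neutral"))
to_binary <- function(e) {
  e <- as_emotion(e)
  ifelse(e %in% c("sad", "neutral"), "LA", "HA")
}

#' Map an emotion to the four Russell-model quadrants
#'
#' Quadrants of the valence/arousal circumplex: happy and surprise are
#' high-arousal high-valence (HAHV); disgust, anger and fear are high-arousal
#' low-valence (HALV); sad is low-arousal low-valence (LALV); neutral is
#' low-arousal high-valence (LAHV).
#'
#' @param e character vector of emotion labels.
#' @return character vector of quadrant labels.
#' @export
#' @examples
#' to_quadrant(c("surprise", "anger", "neutral"))
to_quadrant <- function(e) {
  e <- as_emotion(e)
  q <- character(length(e))
  q[e %in% c("happy", "surprise")] <- "HAHV"
  q[e %in% c("disgust", "anger", "fear")] <- "HALV"
  q[e == "sad"] <- "LALV"
  q[e == "neutral"] <- "LAHV"
  q
}

#' Classification task schemes
#'
#' Builds one of the three labelling schemes: the full seven-emotion task,
#' the binary arousal split, or the four Russell quadrants. Class labels are
#' ordered alphabetically within a scheme so that confusion matrices and
#' one-hot encodings are reproducible. For the binary scheme the positive
#' class (used for precision/recall/F1) is `"HA"`.
#'
#' @param name one of `"seven"`, `"binary"`, `"quadrant"`.
#' @return an object of class `task_scheme`: a list with elements `name`,
#'   `classes` (ordered class labels), `map` (named character vector mapping
#'   each of the 7 emotions to its class) and, for the binary scheme,
#'   `positive`.
#' @export
#' @examples
#' sc <- task_scheme("quadrant")
#' sc$map[["fear"]]
task_scheme <- function(name = c("seven", "binary", "quadrant")) {
  name <- match.arg(name)
  map <- switch(name,
    seven    = stats::setNames(EMOTIONS, EMOTIONS),
    binary   = stats::setNames(to_binary(EMOTIONS), EMOTIONS),
    quadrant = stats::setNames(to_quadrant(EMOTIONS), EMOTIONS)
  )
  out <- list(name = name, classes = sort(unique(unname(map))), map = map)
  if (name == "binary") out$positive <- "HA"
  class(out) <- "task_scheme"
  out
}

#' @export
print.task_scheme <- function(x, ...) {
  cat("task scheme:", x$name, "(", length(x$classes), "classes )\n")
  for (cl in x$classes) {
    cat(" ", cl, "<-", paste(names(x$map)[x$map == cl], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Apply a task scheme to emotion labels
#'
#' @param scheme a [task_scheme()].
#' @param e character vector of emotion labels.
#' @return factor of class labels with levels `scheme$classes`.
#' @export
scheme_labels <- function(scheme, e) {
  stopifnot(inherits(scheme, "task_scheme"))
  factor(unname(scheme$map[as_emotion(e)]), levels = scheme$classes)
}

#' Class distribution of a corpus under a task scheme
#'
#' @param corpus an [eeg_corpus] (or any trial set with an `emotion` column).
#' @param scheme a [task_scheme()].
#' @return named numeric vector of class proportions (sums to 1).
#' @export
class_distribution <- function(corpus, scheme) {
  e <- trial_meta(corpus)$emotion
  if (length(e) == 0L) stop("empty corpus: no trials to tabulate", call. = FALSE)
  y <- scheme_labels(scheme, e)
  tab <- table(y)
  stats::setNames(as.numeric(tab) / length(y), names(tab))
}
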