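#' Frequency-band specification
#'
#' An ordered set of named frequency bands. Bands must be non-overlapping and
#' listed in ascending order of their lower edge.
#'
#' @param name character vector of band names.
#' @param low_hz,high_hz numeric vectors of band edges in Hz.
#' @return a `band_spec` data frame with columns `name`, `low_hz`, `high_hz`.
#' @export
#' @examples
#' default_band_spec()
band_spec <- function(name, low_hz, high_hz) {
  stopifnot(length(name) == length(low_hz), length(low_hz) == length(high_hz))
  if (any(low_hz <= 0) || any(high_hz <= low_hz)) {
    stop("band edges must satisfy 0 < low_hz < high_hz", call. = FALSE)
  }
  if (is.unsorted(low_hz, strictly = TRUE) ||
      any(low_hz[-1] < high_hz[-length(high_hz)])) {
    stop("bands must be ascending in low_hz and non-overlapping", call. = FALSE)
  }
  out <- data.frame(name = as.character(name), low_hz = low_hz, high_hz = high_hz,
                    stringsAsFactors = FALSE)
  class(out) <- c("band_spec", "data.frame")
  out
}

#' @rdname band_spec
#' @details `default_band_spec()` returns the five conventional EEG bands used
#'   for the 310-dimensional differential-entropy layout: delta 1-4, theta 4-8,
#'   alpha 8-14, beta 14-31, gamma 31-50 Hz.
#' @export
default_band_spec <- function() {
  band_spec(c("delta", "theta", "alpha", "beta", "gamma"),
            c(1, 4, 8, 14, 31), c(4, 8, 14, 31, 50))
}

new_trials <- function(meta, features, sources = NULL, raw = NULL) {
  n <- nrow(meta)
  if (is.null(sources)) sources <- as.list(meta$participant_id)
  stopifnot(is.matrix(features), nrow(features) == n, length(sources) == n)
  if (!is.null(raw)) stopifnot(length(raw) == n)
  structure(list(meta = meta, features = features, sources = sources, raw = raw),
            class = "eeg_trials")
}

#' Trial metadata, features and counts
#'
#' Accessors shared by trial sets and corpora. `trial_meta()` returns the
#' per-trial data frame (`participant_id`, `clip_id`, `emotion`, `score`,
#' `is_synthetic`); `trial_features()` the feature matrix (one row per trial);
#' `trial_sources()` the list of contributing participant ids per trial
#' (a singleton for measured trials); `n_trials()` the trial count.
#'
#' @param x an `eeg_trials` or `eeg_corpus` object.
#' @return see description.
#' @export
trial_meta <- function(x) x$meta

#' @rdname trial_meta
#' @export
trial_features <- function(x) x$features

#' @rdname trial_meta
#' @export
trial_sources <- function(x) x$sources

#' @rdname trial_meta
#' @export
n_trials <- function(x) nrow(x$meta)

#' Subset a trial set
#'
#' @param x an `eeg_trials` or `eeg_corpus` object.
#' @param i integer or logical index over trials.
#' @param ... unused.
#' @return an object of the same class containing the selected trials (corpus
#'   metadata is preserved when subsetting a corpus).
#' @export
`[.eeg_trials` <- function(x, i, ...) {
  i <- seq_len(n_trials(x))[i]
  x$meta <- x$meta[i, , drop = FALSE]
  rownames(x$meta) <- NULL
  x$features <- x$features[i, , drop = FALSE]
  x$sources <- x$sources[i]
  if (!is.null(x$raw)) x$raw <- x$raw[i]
  if (!is.null(attr(x, "generation"))) {
    gen <- attr(x, "generation")
    gen$engaged <- gen$engaged[i]
    attr(x, "generation") <- gen
  }
  x
}

#' Concatenate trial sets
#'
#' @param ... `eeg_trials` objects with identical feature dimension.
#' @return a single `eeg_trials` object (plain trial set; corpus metadata of
#'   the inputs is dropped).
#' @export
bind_trials <- function(...) {
  xs <- list(...)
  xs <- xs[vapply(xs, Negate(is.null), logical(1))]
  stopifnot(length(xs) > 0L)
  meta <- do.call(rbind, lapply(xs, trial_meta))
  rownames(meta) <- NULL
  feats <- do.call(rbind, lapply(xs, trial_features))
  srcs <- do.call(c, lapply(xs, trial_sources))
  raws <- lapply(xs, function(x) x$raw)
  raw <- if (all(vapply(raws, is.null, logical(1)))) NULL else {
    do.call(c, lapply(seq_along(xs), function(j) {
      if (is.null(raws[[j]])) vector("list", n_trials(xs[[j]])) else raws[[j]]
    }))
  }
  new_trials(meta, feats, srcs, raw)
}

#' Construct and validate an EEG trial corpus
#'
#' A corpus is a set of viewing trials (one per participant x clip), each
#' carrying an emotion label, a self-report intensity score in \[0, 1\] and a
#' differential-entropy feature vector of length
#' `n_channels * nrow(band_spec)` (channel-major: all bands of channel 1,
#' then channel 2, ...). Raw multichannel signals are optional and only
#' required for time-domain augmentation and feature re-extraction.
#'
#' @param meta data frame with columns `participant_id` (integer >= 1),
#'   `clip_id` (integer >= 1), `emotion`, `score`, and optionally
#'   `is_synthetic` (default all `FALSE`).
#' @param features numeric matrix, one row per trial.
#' @param clip_emotion_map named character vector mapping clip id to emotion;
#'   derived from `meta` when `NULL`.
#' @param n_participants number of participants; defaults to the maximum
#'   participant id present.
#' @param sampling_rate_hz sampling rate of the raw signals in Hz.
#' @param bands a [band_spec()].
#' @param n_channels channel count; defaults to
#'   `ncol(features) / nrow(bands)`.
#' @param raw optional list of `n_channels x n_samples` matrices, one per
#'   trial.
#' @param sources optional list of integer vectors of contributing
#'   participants (defaults to each trial's own participant).
#' @return an object of class `eeg_corpus`.
#' @export
eeg_corpus <- function(meta, features, clip_emotion_map = NULL,
                       n_participants = NULL, sampling_rate_hz = 200,
                       bands = default_band_spec(), n_channels = NULL,
                       raw = NULL, sources = NULL) {
  stopifnot(is.data.frame(meta), is.matrix(features))
  req <- c("participant_id", "clip_id", "emotion", "score")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("meta lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (is.null(meta$is_synthetic)) meta$is_synthetic <- FALSE
  meta$participant_id <- as.integer(meta$participant_id)
  meta$clip_id <- as.integer(meta$clip_id)
  meta$emotion <- as_emotion(meta$emotion)
  meta <- meta[, c(req, "is_synthetic")]
  storage.mode(features) <- "double"

  n_bands <- nrow(bands)
  if (is.null(n_channels)) {
    if (ncol(features) %% n_bands != 0L) {
      stop("feature length ", ncol(features), " is not a multiple of the ",
           n_bands, " bands", call. = FALSE)
    }
    n_channels <- ncol(features) %/% n_bands
  }
  if (is.null(clip_emotion_map)) {
    first <- !duplicated(meta$clip_id)
    clip_emotion_map <- stats::setNames(meta$emotion[first],
                                        as.character(meta$clip_id[first]))
  }
  if (is.null(n_participants)) {
    n_participants <- max(meta$participant_id[!meta$is_synthetic], 0L)
  }
  x <- new_trials(meta, features, sources, raw)
  x$clip_emotion_map <- clip_emotion_map
  x$n_participants <- as.integer(n_participants)
  x$sampling_rate_hz <- sampling_rate_hz
  x$band_spec <- bands
  x$n_channels <- as.integer(n_channels)
  class(x) <- c("eeg_corpus", "eeg_trials")
  validate_corpus(x)
  x
}

#' Check all corpus invariants
#'
#' Verifies score bounds, feature dimensions, raw-signal shapes, uniqueness of
#' non-synthetic (participant, clip) pairs, label consistency with the
#' clip-to-emotion map, participant-id bounds, and source-provenance
#' consistency. Errors name the offending trial row.
#'
#' @param x an `eeg_corpus`.
#' @return `x`, invisibly, if valid.
#' @export
validate_corpus <- function(x) {
  meta <- x$meta
  n <- nrow(meta)
  bad <- which(!is.finite(meta$score) | meta$score < 0 | meta$score > 1)
  if (length(bad)) stop("trial row ", bad[1], ": score ", meta$score[bad[1]],
                        " outside [0, 1]", call. = FALSE)
  d_expect <- x$n_channels * nrow(x$band_spec)
  if (ncol(x$features) != d_expect) {
    stop("feature length ", ncol(x$features), " != n_channels * n_bands = ",
         d_expect, call. = FALSE)
  }
  if (any(!is.finite(x$features))) {
    stop("trial row ", which(rowSums(!is.finite(x$features)) > 0)[1],
         ": non-finite feature value", call. = FALSE)
  }
  real <- !meta$is_synthetic
  key <- paste(meta$participant_id, meta$clip_id)
  if (anyDuplicated(key[real])) {
    d <- key[real][duplicated(key[real])][1]
    stop("duplicated non-synthetic (participant, clip) pair: (", d, ")",
         call. = FALSE)
  }
  mapped <- unname(x$clip_emotion_map[as.character(meta$clip_id)])
  bad <- which(is.na(mapped) | mapped != meta$emotion)
  if (length(bad)) stop("trial row ", bad[1], ": emotion ", meta$emotion[bad[1]],
                        " disagrees with clip_emotion_map", call. = FALSE)
  if (any(meta$participant_id < 1L)) {
    stop("participant ids must be >= 1", call. = FALSE)
  }
  if (any(meta$participant_id[real] > x$n_participants)) {
    stop("non-synthetic participant id exceeds n_participants = ",
         x$n_participants, call. = FALSE)
  }
  for (i in seq_len(n)) {
    if (!meta$is_synthetic[i] &&
        !identical(sort(unique(x$sources[[i]])), meta$participant_id[i])) {
      stop("trial row ", i, ": non-synthetic trial must have itself as sole ",
           "source participant", call. = FALSE)
    }
  }
  if (!is.null(x$raw)) {
    for (i in seq_len(n)) {
      r <- x$raw[[i]]
      if (is.null(r)) next
      if (!is.matrix(r) || nrow(r) != x$n_channels || ncol(r) < 1L) {
        stop("trial row ", i, ": raw signal must be an n_channels x n_samples ",
             "matrix", call. = FALSE)
      }
    }
  }
  invisible(x)
}

#' @export
print.eeg_corpus <- function(x, ...) {
  cat("eeg_corpus:", n_trials(x), "trials,", x$n_participants, "participants,",
      length(x$clip_emotion_map), "clips\n")
  cat("  features:", ncol(x$features), "(", x$n_channels, "channels x",
      nrow(x$band_spec), "bands ),",
      if (is.null(x$raw)) "no raw signals" else "with raw signals", "\n")
  tab <- table(x$meta$emotion[!x$meta$is_synthetic])
  cat("  emotions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.eeg_trials <- function(x, ...) {
  cat("eeg_trials:", n_trials(x), "trials (",
      sum(x$meta$is_synthetic), "synthetic ),", ncol(x$features), "features\n")
  invisible(x)
}

fmt_num <- function(v) {
  out <- sprintf("%.17g", v)
  # canonical short form when exact (keeps files readable and round-trippable)
  short <- sprintf("%.15g", v)
  ok <- as.numeric(short) == v
  out[ok] <- short[ok]
  out
}

#' Write a corpus to disk
#'
#' Two on-disk formats are supported. `"table"` is a plain CSV with header
#' `participant_id,clip_id,emotion,score,f_0001,...` and one row per trial,
#' deterministically ordered by participant then clip; it stores features but
#' not raw signals and only accepts fully non-synthetic corpora. `"container"`
#' is a single RDS file holding the complete corpus object, including any raw
#' signals and corpus metadata.
#'
#' @param corpus an `eeg_corpus`.
#' @param path output file path.
#' @param format `"table"` or `"container"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("table", "container")) {
  format <- match.arg(format)
  validate_corpus(corpus)
  if (format == "container") {
    saveRDS(corpus, path)
    return(invisible(path))
  }
  if (any(corpus$meta$is_synthetic)) {
    stop("table format stores measured trials only; corpus contains synthetic ",
         "trials (use format = \"container\")", call. = FALSE)
  }
  d <- ncol(corpus$features)
  header <- paste(c("participant_id", "clip_id", "emotion", "score",
                    sprintf("f_%04d", seq_len(d))), collapse = ",")
  o <- order(corpus$meta$participant_id, corpus$meta$clip_id)
  meta <- corpus$meta[o, , drop = FALSE]
  feats <- corpus$features[o, , drop = FALSE]
  featstr <- apply(feats, 1L, function(r) paste(fmt_num(r), collapse = ","))
  rows <- paste(meta$participant_id, meta$clip_id, meta$emotion,
                fmt_num(meta$score), featstr, sep = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}

#' Read a corpus from disk
#'
#' Inverse of [write_corpus()]. Table files are validated field by field:
#' malformed headers, scores outside \[0, 1\], unknown emotion strings and
#' feature-length mismatches raise errors naming the offending row or field.
#'
#' @param path input file path.
#' @param format `"table"` or `"container"`.
#' @param sampling_rate_hz,bands,n_channels corpus metadata not stored in the
#'   table format (ignored for containers). `n_channels` defaults to the
#'   feature count divided by the number of bands.
#' @return an `eeg_corpus`.
#' @export
read_corpus <- function(path, format = c("table", "container"),
                        sampling_rate_hz = 200, bands = default_band_spec(),
                        n_channels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "container") {
    x <- readRDS(path)
    if (!inherits(x, "eeg_corpus")) stop("container does not hold an eeg_corpus",
                                         call. = FALSE)
    return(validate_corpus(x))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  fcols <- grep("^f_[0-9]+$", names(df), value = TRUE)
  lead <- c("participant_id", "clip_id", "emotion", "score")
  if (!identical(names(df)[1:4], lead)) {
    stop("malformed header: expected columns ", paste(lead, collapse = ","),
         ",f_0001,... but found ", paste(utils::head(names(df), 5), collapse = ","),
         call. = FALSE)
  }
  if (length(fcols) == 0L && nrow(df) > 0L) {
    stop("malformed header: no feature columns f_0001,...", call. = FALSE)
  }
  if (!identical(fcols, sprintf("f_%04d", seq_along(fcols)))) {
    stop("malformed header: feature columns must be f_0001..f_",
         sprintf("%04d", length(fcols)), " in order", call. = FALSE)
  }
  bad <- which(!df$score >= 0 | !df$score <= 1)
  if (length(bad)) stop("row ", bad[1], ", field 'score': value ",
                        df$score[bad[1]], " outside [0, 1]", call. = FALSE)
  feats <- as.matrix(df[, fcols, drop = FALSE])
  dimnames(feats) <- NULL
  if (nrow(df) == 0L) feats <- matrix(numeric(0), 0L,
                                      if (is.null(n_channels)) 310L
                                      else n_channels * nrow(bands))
  eeg_corpus(df[, lead, drop = FALSE], feats,
             sampling_rate_hz = sampling_rate_hz, bands = bands,
             n_channels = n_channels)
}

#' Read a SEED-VII feature export
#'
#' Optional adapter for the real SEED-VII dataset (registration-gated; never
#' downloaded or shipped by this package). The dataset is distributed as
#' MAT-style containers; this adapter reads a one-time plain-text export of
#' the time-averaged differential-entropy features, laid out as:
#'
#' * `clips.csv` — columns `clip_id`, `emotion` (80 rows);
#' * `participant_<k>.csv` — columns `clip_id`, `score`, `f_0001`..`f_0310`,
#'   one row per viewed clip, features already averaged over time and ordered
#'   channel-major (channel 1 delta..gamma, channel 2, ...).
#'
#' @param dir directory containing the export.
#' @param sampling_rate_hz,bands corpus metadata (the export stores features
#'   only).
#' @return an `eeg_corpus`.
#' @export
read_seedvii <- function(dir, sampling_rate_hz = 200, bands = default_band_spec()) {
  if (!dir.exists(dir)) {
    stop("SEED-VII directory not found: ", dir, "\n",
         "The SEED-VII dataset is registration-gated and optional; this ",
         "adapter reads a plain-text export of its DE features (see ",
         "?read_seedvii for the expected layout).", call. = FALSE)
  }
  clips_path <- file.path(dir, "clips.csv")
  if (!file.exists(clips_path)) {
    stop("missing ", clips_path, ": the export must provide the clip-to-",
         "emotion table", call. = FALSE)
  }
  clips <- utils::read.csv(clips_path, stringsAsFactors = FALSE)
  cmap <- stats::setNames(as_emotion(clips$emotion), as.character(clips$clip_id))
  pfiles <- list.files(dir, pattern = "^participant_[0-9]+\\.csv$",
                       full.names = TRUE)
  if (length(pfiles) == 0L) {
    stop("no participant_<k>.csv files found in ", dir, call. = FALSE)
  }
  pids <- as.integer(sub("^participant_([0-9]+)\\.csv$", "\\1", basename(pfiles)))
  o <- order(pids)
  pfiles <- pfiles[o]; pids <- pids[o]
  metas <- list(); feats <- list()
  for (j in seq_along(pfiles)) {
    df <- utils::read.csv(pfiles[j], stringsAsFactors = FALSE, check.names = FALSE)
    fcols <- grep("^f_[0-9]+$", names(df), value = TRUE)
    emo <- unname(cmap[as.character(df$clip_id)])
    if (anyNA(emo)) stop(basename(pfiles[j]), ": clip id missing from clips.csv",
                         call. = FALSE)
    metas[[j]] <- data.frame(participant_id = pids[j], clip_id = df$clip_id,
                             emotion = emo, score = df$score)
    f <- as.matrix(df[, fcols, drop = FALSE]); dimnames(f) <- NULL
    feats[[j]] <- f
  }
  eeg_corpus(do.call(rbind, metas), do.call(rbind, feats),
             clip_emotion_map = cmap, n_participants = max(pids),
             sampling_rate_hz = sampling_rate_hz, bands = bands)
}
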