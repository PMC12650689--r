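#' Augmentation specification
#'
#' Exactly one label-preserving augmentation operator is used per pipeline
#' run; the operators are never combined.
#'
#' @param kind one of `"none"`, `"average"` (element-wise mean of `k`
#'   same-emotion feature vectors), `"gaussian"` (feature-space noise at a
#'   nominal SNR), `"time"` (sample-wise averaging of two participants' raw
#'   responses to the same clip, with feature re-extraction).
#' @param k averaging group size (default 5).
#' @param snr_db nominal signal-to-noise ratio of Gaussian augmentation in
#'   dB (default 15).
#' @param modulation `(low, high)` range of the uniform noise-variance
#'   modulation factor (default `c(0.5, 1.5)`).
#' @param pairing `"matching"` (one seeded random perfect matching of train
#'   participants per clip) or `"all_pairs"` (every unordered pair).
#' @param groups `"sliding"` (width-`k` window, stride 1, over a seeded
#'   shuffle) or `"disjoint"` (consecutive non-overlapping groups) for the
#'   averaging operator.
#' @param seed integer seed for the operator's randomness.
#' @return an object of class `augment_spec`.
#' @export
augment_spec <- function(kind = c("none", "average", "gaussian", "time"),
                         k = 5, snr_db = 15, modulation = c(0.5, 1.5),
                         pairing = c("matching", "all_pairs"),
                         groups = c("sliding", "disjoint"), seed = 1) {
  if (length(kind) > 1L && !identical(kind, eval(formals(augment_spec)$kind))) {
    stop("exactly one augmentation kind per pipeline run; operators are ",
         "never combined", call. = FALSE)
  }
  kind <- match.arg(kind)
  structure(list(kind = kind, k = as.integer(k), snr_db = snr_db,
                 modulation = modulation, pairing = match.arg(pairing),
                 groups = match.arg(groups), seed = as.integer(seed)),
            class = "augment_spec")
}

#' Participant-score-guided noise filtering
#'
#' Removes training trials whose self-reported emotion-intensity score is at
#' or below the cleaning ratio `tau`; trials with `score > tau` are retained
#' in their original order. `tau = NULL` disables filtering entirely (distinct
#' from `tau = 0`, which still drops exact-zero scores).
#'
#' @param trials an `eeg_trials` or `eeg_corpus` object.
#' @param tau cleaning ratio in \[0, 1\], or `NULL` for no filtering.
#' @return the retained trials (same class as the input).
#' @export
#' @examples
#' # tau = 0.2 removes scores <= 0.2 and keeps 0.21
clean_by_score <- function(trials, tau) {
  if (is.null(tau) || (length(tau) == 1L && is.na(tau))) return(trials)
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1) {
    stop("cleaning ratio must be a single value in [0, 1] or NULL",
         call. = FALSE)
  }
  trials[trial_meta(trials)$score > tau]
}

#' Averaging-based augmentation
#'
#' For each emotion with at least `k` trials, orders that emotion's trials by
#' a seeded shuffle, slides a width-`k` window with stride 1 (or steps in
#' disjoint groups), and emits one synthetic trial per group whose features
#' and score are the element-wise means of the members. Synthetic trials keep
#' the members' emotion, are flagged `is_synthetic`, and record the union of
#' member participants as sources. The returned set is the originals followed
#' by the synthetics. Emotions with fewer than `k` trials contribute none.
#'
#' @param trials an `eeg_trials` or `eeg_corpus` object.
#' @param k group size (>= 2, default 5).
#' @param seed seed for the per-emotion shuffle.
#' @param groups `"sliding"` or `"disjoint"`.
#' @return an `eeg_trials` set: originals + synthetics.
#' @export
augment_average <- function(trials, k = 5, seed = 1,
                            groups = c("sliding", "disjoint")) {
  groups <- match.arg(groups)
  if (k < 2) stop("averaging group size k must be >= 2", call. = FALSE)
  meta <- trial_meta(trials)
  feats <- trial_features(trials)
  syn_meta <- list(); syn_feat <- list(); syn_src <- list()
  for (e in unique(meta$emotion)) {
    idx <- which(meta$emotion == e)
    if (length(idx) < k) next
    ord <- with_seed_(derive_seed(seed, paste0("avg-", e)),
                      idx[sample.int(length(idx))])
    starts <- if (groups == "sliding") seq_len(length(ord) - k + 1L)
              else seq(1L, length(ord) - k + 1L, by = k)
    for (s in starts) {
      mem <- ord[s:(s + k - 1L)]
      syn_feat[[length(syn_feat) + 1L]] <- colMeans(feats[mem, , drop = FALSE])
      syn_meta[[length(syn_meta) + 1L]] <-
        data.frame(participant_id = meta$participant_id[mem[1]],
                   clip_id = meta$clip_id[mem[1]], emotion = e,
                   score = mean(meta$score[mem]), is_synthetic = TRUE,
                   stringsAsFactors = FALSE)
      syn_src[[length(syn_src) + 1L]] <-
        sort(unique(unlist(trial_sources(trials)[mem])))
    }
  }
  if (length(syn_meta) == 0L) return(trials)
  syn <- new_trials(do.call(rbind, syn_meta),
                    do.call(rbind, syn_feat), syn_src,
                    raw = if (is.null(trials$raw)) NULL
                          else vector("list", length(syn_meta)))
  bind_trials(trials, syn)
}

#' Gaussian feature-noise augmentation
#'
#' Adds zero-mean Gaussian noise to each trial's feature vector and appends
#' the noisy copy, exactly doubling the set. The nominal noise variance is
#' scaled to each trial's signal power `P = mean(features^2)`:
#' `sigma0^2 = P / 10^(snr_db / 10)`; every copy draws a modulation factor
#' `m ~ Uniform(low, high)` and uses variance `m * sigma0^2`. Labels and
#' scores of copies equal their originals.
#'
#' @param trials an `eeg_trials` or `eeg_corpus` object (non-empty).
#' @param snr_db nominal SNR in dB (default 15).
#' @param modulation `(low, high)` modulation range with `low > 0`.
#' @param seed seed for modulation factors and noise.
#' @return an `eeg_trials` set of exactly `2 * n_trials(trials)` trials:
#'   originals followed by their noisy copies.
#' @export
augment_gaussian <- function(trials, snr_db = 15, modulation = c(0.5, 1.5),
                             seed = 1) {
  n <- n_trials(trials)
  if (n == 0L) stop("augment_gaussian needs a non-empty trial set",
                    call. = FALSE)
  if (modulation[1] <= 0 || modulation[2] < modulation[1]) {
    stop("modulation range must satisfy 0 < low <= high", call. = FALSE)
  }
  feats <- trial_features(trials)
  power <- rowMeans(feats^2)
  sigma0_sq <- power / 10^(snr_db / 10)
  noisy <- with_seed_(derive_seed(seed, "gaussian-aug"), {
    m <- stats::runif(n, modulation[1], modulation[2])
    feats + matrix(stats::rnorm(length(feats)), nrow(feats), ncol(feats)) *
      sqrt(m * sigma0_sq)
  })
  meta <- trial_meta(trials)
  meta$is_synthetic <- TRUE
  syn <- new_trials(meta, noisy, trial_sources(trials),
                    raw = if (is.null(trials$raw)) NULL
                          else vector("list", n))
  bind_trials(trials, syn)
}

# internal: pairs of train participants per clip
time_aug_pairs <- function(corpus, train_participants, pairing, seed) {
  meta <- trial_meta(corpus)
  real <- !meta$is_synthetic
  out <- list()
  for (cl in sort(unique(meta$clip_id[real]))) {
    pids <- sort(intersect(meta$participant_id[real & meta$clip_id == cl],
                           train_participants))
    if (length(pids) < 2L) next
    if (pairing == "matching") {
      ord <- with_seed_(derive_seed(seed, paste0("time-", cl)),
                        pids[sample.int(length(pids))])
      np <- length(ord) %/% 2L
      prs <- lapply(seq_len(np), function(j) ord[c(2L * j - 1L, 2L * j)])
    } else {
      cmb <- utils::combn(pids, 2L)
      prs <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
    }
    out[[as.character(cl)]] <- prs
  }
  out
}

#' Time-domain augmentation across participants
#'
#' For each clip, pairs distinct training participants who viewed it, averages
#' their raw signals sample-wise (after truncating both to the shorter length
#' for frame-level alignment), re-extracts differential-entropy features from
#' the averaged signal, and assigns the mean of the two self-report scores and
#' the clip's emotion. Pairing defaults to one seeded random perfect matching
#' per clip (about half as many synthetics as training trials); `"all_pairs"`
#' enumerates every unordered pair. Participants outside `train_participants`
#' never contribute; an explicitly requested pair containing one raises a
#' leakage error.
#'
#' @param corpus an `eeg_corpus` whose trials carry raw signals.
#' @param train_participants integer vector of training participant ids.
#' @param seed seed for the per-clip matching.
#' @param pairing `"matching"` or `"all_pairs"`.
#' @param pairs optional explicit pair list: each element
#'   `list(clip_id =, participants = c(p1, p2))`. Validated strictly.
#' @param window_s feature-extraction window length in seconds.
#' @return an `eeg_trials` set: the training participants' original trials
#'   followed by the synthetic trials.
#' @export
augment_time <- function(corpus, train_participants, seed = 1,
                         pairing = c("matching", "all_pairs"), pairs = NULL,
                         window_s = 1) {
  pairing <- match.arg(pairing)
  if (is.null(corpus$raw)) {
    stop("time-domain augmentation requires raw signals on the corpus",
         call. = FALSE)
  }
  meta <- trial_meta(corpus)
  real_train <- !meta$is_synthetic & meta$participant_id %in% train_participants
  originals <- corpus[which(real_train)]

  if (is.null(pairs)) {
    byclip <- time_aug_pairs(corpus, train_participants, pairing, seed)
    pairs <- list()
    for (cl in names(byclip)) {
      for (pr in byclip[[cl]]) {
        pairs[[length(pairs) + 1L]] <- list(clip_id = as.integer(cl),
                                            participants = pr)
      }
    }
  } else {
    for (pr in pairs) {
      outside <- setdiff(pr$participants, train_participants)
      if (length(outside)) {
        stop("leakage: requested pair includes participant(s) ",
             paste(outside, collapse = ", "), " outside the training set",
             call. = FALSE)
      }
      if (length(unique(pr$participants)) != 2L) {
        stop("a time-augmentation pair needs two distinct participants",
             call. = FALSE)
      }
    }
  }
  if (length(pairs) == 0L) return(originals)

  row_of <- function(p, cl) {
    which(!meta$is_synthetic & meta$participant_id == p & meta$clip_id == cl)
  }
  syn_meta <- list(); syn_feat <- list(); syn_src <- list(); syn_raw <- list()
  for (pr in pairs) {
    i1 <- row_of(pr$participants[1], pr$clip_id)
    i2 <- row_of(pr$participants[2], pr$clip_id)
    if (length(i1) != 1L || length(i2) != 1L) {
      stop("pair (", paste(pr$participants, collapse = ", "), ") x clip ",
           pr$clip_id, ": trial not found", call. = FALSE)
    }
    r1 <- corpus$raw[[i1]]; r2 <- corpus$raw[[i2]]
    if (is.null(r1) || is.null(r2)) {
      stop("pair member lacks a raw signal (clip ", pr$clip_id, ")",
           call. = FALSE)
    }
    len <- min(ncol(r1), ncol(r2))
    avg <- (r1[, seq_len(len), drop = FALSE] +
              r2[, seq_len(len), drop = FALSE]) / 2
    syn_feat[[length(syn_feat) + 1L]] <-
      extract_de_features(avg, corpus$sampling_rate_hz, corpus$band_spec,
                          window_s = window_s)
    syn_meta[[length(syn_meta) + 1L]] <-
      data.frame(participant_id = pr$participants[1], clip_id = pr$clip_id,
                 emotion = unname(corpus$clip_emotion_map[as.character(pr$clip_id)]),
                 score = mean(c(meta$score[i1], meta$score[i2])),
                 is_synthetic = TRUE, stringsAsFactors = FALSE)
    syn_src[[length(syn_src) + 1L]] <- sort(pr$participants)
    syn_raw[[length(syn_raw) + 1L]] <- avg
  }
  syn <- new_trials(do.call(rbind, syn_meta), do.call(rbind, syn_feat),
                    syn_src, syn_raw)
  bind_trials(originals, syn)
}

#' Curate a training set: augment, then clean
#'
#' Applies exactly one augmentation operator to the training trials and then
#' score-based noise filtering to the union of originals and synthetics —
#' augmentation first, cleaning second, so aggressive cleaning also filters
#' synthetic trials whose (inherited or averaged) scores fall at or below the
#' threshold. The test fold must never pass through this function.
#'
#' @param train_trials training trials (subset of `corpus` restricted to
#'   `train_participants` in subject mode).
#' @param corpus the parent corpus (needed for time-domain augmentation).
#' @param augment an [augment_spec()].
#' @param tau cleaning ratio (see [clean_by_score()]).
#' @param train_participants participant ids allowed to contribute.
#' @return the curated `eeg_trials` set.
#' @export
apply_curation <- function(train_trials, corpus, augment = augment_spec("none"),
                           tau = NULL, train_participants = NULL) {
  stopifnot(inherits(augment, "augment_spec"))
  if (is.null(train_participants)) {
    train_participants <- sort(unique(trial_meta(train_trials)$participant_id))
  }
  augmented <- switch(augment$kind,
    none = train_trials,
    average = augment_average(train_trials, k = augment$k, seed = augment$seed,
                              groups = augment$groups),
    gaussian = augment_gaussian(train_trials, snr_db = augment$snr_db,
                                modulation = augment$modulation,
                                seed = augment$seed),
    time = augment_time(corpus, train_participants, seed = augment$seed,
                        pairing = augment$pairing)
  )
  clean_by_score(augmented, tau)
}
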