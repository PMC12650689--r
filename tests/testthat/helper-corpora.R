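# Shared fixtures, built in code. Generated corpora and cross-validation runs
# are memoised so the suite pays for each expensive object once.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# full study-size corpus (20 participants x 80 clips, 30% corrupted trials)
default_corpus <- function(seed) {
  memo(paste0("default-", seed),
       generate_corpus(gen_params(seed = seed), keep_raw = FALSE))
}

# small corpus for structural tests: 5 participants x 14 clips, 8 channels,
# 4 s trials, raw signals kept (needed for time-domain augmentation)
small_params <- function(seed = 7, ...) {
  gen_params(n_participants = 5, clips_per_emotion = 2, neutral_clips = 2,
             n_channels = 8, trial_duration_s = 4, seed = seed, ...)
}

small_corpus <- function(seed = 7, ...) {
  key <- paste0("small-", seed, "-", paste(c(...), collapse = "_"))
  memo(key, generate_corpus(small_params(seed = seed, ...)))
}

# memoised study-size cross-validation cell (binary task, variant 1)
cv_cell <- function(seed, tau, pca = FALSE) {
  key <- paste0("cv-", seed, "-", if (is.null(tau)) "none" else tau, "-", pca)
  memo(key, run_cv(default_corpus(seed),
                   pipeline_config(task = "binary", clean_ratio = tau,
                                   pca = pca, seed = 1)))
}

# hand-built trial set (bypasses corpus invariants deliberately)
toy_trials <- function(scores, emotions = "happy", features = NULL,
                       participants = NULL, clips = 1L, d = 4L) {
  n <- length(scores)
  emotions <- rep_len(emotions, n)
  if (is.null(features)) features <- matrix(seq_len(n * d) / 10, n, d)
  if (is.null(participants)) participants <- seq_len(n)
  meta <- data.frame(participant_id = as.integer(rep_len(participants, n)),
                     clip_id = as.integer(rep_len(clips, n)),
                     emotion = emotions, score = scores, is_synthetic = FALSE,
                     stringsAsFactors = FALSE)
  eegcurate:::new_trials(meta, features)
}

# random invariant-satisfying corpus for round-trip properties
random_corpus <- function(seed, n_participants = 3, n_clips = 4, d = 10) {
  withr_seed <- function(expr) eegcurate:::with_seed_(seed, expr)
  withr_seed({
    emo <- sample(EMOTIONS, n_clips, replace = TRUE)
    meta <- expand.grid(clip_id = seq_len(n_clips),
                        participant_id = seq_len(n_participants))
    meta <- data.frame(participant_id = meta$participant_id,
                       clip_id = meta$clip_id,
                       emotion = emo[meta$clip_id],
                       score = round(runif(nrow(meta)), 6))
    feats <- matrix(rnorm(nrow(meta) * d), nrow(meta), d)
    eeg_corpus(meta, feats, bands = band_spec("all", 1, 50), n_channels = d)
  })
}
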