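#' Parameters of the synthetic corpus generator
#'
#' Defines a SEED-VII-shaped study: 20 participants each viewing 80 clips
#' (12 per emotion for six emotions plus 8 neutral clips), 62-channel raw
#' signals of band-limited Gaussian noise whose per-channel, per-band
#' standard deviations carry an emotion-specific template, and self-report
#' scores tied to signal integrity. A seeded fraction of trials is
#' "corrupted": their class-specific template component is attenuated toward
#' the grand mean (the intended emotion was barely elicited) and their score
#' is drawn from a low-scoring distribution, mirroring the premise that low
#' self-reports flag unreliable labels.
#'
#' @param n_participants number of participants (default 20).
#' @param clips_per_emotion clips per non-neutral emotion (default 12).
#' @param neutral_clips neutral clips (default 8).
#' @param sampling_rate_hz raw-signal sampling rate (default 200 Hz).
#' @param trial_duration_s raw-signal duration per trial (default 10 s).
#' @param n_channels EEG channel count (default 62).
#' @param bands a [band_spec()].
#' @param base_sigma baseline signal standard deviation (arbitrary units).
#' @param class_effect log-standard-deviation scale of the emotion templates
#'   (nats); per-feature effects are small so that class separation comes
#'   from pooling all channels and bands, as with real band features.
#' @param participant_sd standard deviation of the per-participant common
#'   log-amplitude offset (nats).
#' @param corrupt_frac fraction of trials drawn as corrupted (default 0.3).
#' @param corrupt_attenuation multiplier in \[0, 1\] applied to the
#'   class-specific template component of corrupted trials (default 0.2;
#'   0 erases the class signal entirely).
#' @param score_high `(alpha, beta)` of the Beta score distribution for
#'   engaged trials (default `c(8, 2)`, ~98% of mass above 0.5).
#' @param score_low `(alpha, beta)` for corrupted trials (default `c(2, 12)`,
#'   ~94% of mass below 0.3).
#' @param seed integer seed for the whole corpus.
#' @return an object of class `gen_params`.
#' @export
gen_params <- function(n_participants = 20, clips_per_emotion = 12,
                       neutral_clips = 8, sampling_rate_hz = 200,
                       trial_duration_s = 10, n_channels = 62,
                       bands = default_band_spec(), base_sigma = 1,
                       class_effect = 0.012, participant_sd = 0.05,
                       corrupt_frac = 0.3, corrupt_attenuation = 0.2,
                       score_high = c(8, 2), score_low = c(2, 12),
                       seed = 1) {
  if (sampling_rate_hz <= 0 || trial_duration_s <= 0) {
    stop("sampling rate and trial duration must be positive", call. = FALSE)
  }
  if (n_participants < 1 || clips_per_emotion < 1 || neutral_clips < 0 ||
      n_channels < 1) {
    stop("counts must be positive", call. = FALSE)
  }
  if (class_effect < 0 || participant_sd < 0) {
    stop("class_effect and participant_sd must be >= 0", call. = FALSE)
  }
  if (corrupt_frac < 0 || corrupt_frac > 1 ||
      corrupt_attenuation < 0 || corrupt_attenuation > 1) {
    stop("corrupt_frac and corrupt_attenuation must be in [0, 1]",
         call. = FALSE)
  }
  structure(list(n_participants = as.integer(n_participants),
                 clips_per_emotion = as.integer(clips_per_emotion),
                 neutral_clips = as.integer(neutral_clips),
                 sampling_rate_hz = sampling_rate_hz,
                 trial_duration_s = trial_duration_s,
                 n_channels = as.integer(n_channels), bands = bands,
                 base_sigma = base_sigma, class_effect = class_effect,
                 participant_sd = participant_sd, corrupt_frac = corrupt_frac,
                 corrupt_attenuation = corrupt_attenuation,
                 score_high = score_high, score_low = score_low,
                 seed = as.integer(seed)),
            class = "gen_params")
}

# internal: positive-frequency FFT bin range [first, last] per band, 0-based
band_bins <- function(bands, fs, n) {
  k0 <- ceiling(bands$low_hz * n / fs)
  k1 <- ceiling(bands$high_hz * n / fs) - 1
  if (any(k1 < k0)) stop("trial too short to resolve band ",
                         bands$name[which(k1 < k0)[1]], call. = FALSE)
  if (any(k1 >= n / 2)) stop("band edge at or above Nyquist", call. = FALSE)
  cbind(as.integer(k0), as.integer(k1))
}

# internal: clip table of a generated design (clip_id, emotion)
design_clips <- function(params) {
  emo <- c(rep(EMOTIONS[1:6], each = params$clips_per_emotion),
           rep("neutral", params$neutral_clips))
  data.frame(clip_id = seq_along(emo), emotion = emo, stringsAsFactors = FALSE)
}

#' Generate a synthetic SEED-VII-shaped corpus
#'
#' Every (participant, clip) pair yields one trial. For emotion `e`, the
#' per-channel, per-band signal standard deviation template is
#' `base_sigma * exp(class_effect * u[c, b, e])` with fixed unit-normal draws
#' `u` made once per corpus; participant `p` multiplies all sigmas by
#' `exp(participant_sd * v_p)`. Each band component is band-limited Gaussian
#' noise at its sigma (drawn directly in the frequency domain over the
#' band's FFT bins) and components are summed across bands per channel.
#' Corrupted trials (an exact-count seeded draw of
#' `floor(corrupt_frac * n)` trials) replace `u[c, b, e]` by
#' `ubar[c, b] + corrupt_attenuation * (u[c, b, e] - ubar[c, b])`, shrinking
#' the class-specific component toward the grand mean across emotions, and
#' draw their score from `score_low` instead of `score_high`.
#'
#' Differential-entropy features are produced by [extract_de_features()] on
#' the synthesized raw signal, so every downstream stage exercises the real
#' feature path.
#'
#' @param params a [gen_params()] object.
#' @param keep_raw keep the raw signals on the corpus (default `TRUE`;
#'   a full default-size corpus holds ~1.6 GB of raw signal, so pass
#'   `FALSE` when only features are needed).
#' @return an `eeg_corpus` with `n_participants * (6 * clips_per_emotion +
#'   neutral_clips)` trials and a hidden generation record for
#'   [ground_truth()].
#' @export
#' @examples
#' p <- gen_params(n_participants = 2, clips_per_emotion = 1,
#'                 neutral_clips = 1, n_channels = 4, trial_duration_s = 2,
#'                 seed = 7)
#' corp <- generate_corpus(p)
#' corp
generate_corpus <- function(params = gen_params(), keep_raw = TRUE) {
  stopifnot(inherits(params, "gen_params"))
  clips <- design_clips(params)
  n_clip <- nrow(clips)
  P <- params$n_participants
  n <- P * n_clip
  nb <- nrow(params$bands)
  ch <- params$n_channels
  nsamp <- as.integer(round(params$sampling_rate_hz * params$trial_duration_s))
  bins <- band_bins(params$bands, params$sampling_rate_hz, nsamp)

  # fixed templates and participant offsets (one substream each)
  u <- with_seed_(derive_seed(params$seed, "templates"),
                  array(stats::rnorm(ch * nb * 7), dim = c(ch, nb, 7)))
  dimnames(u) <- list(NULL, NULL, EMOTIONS)
  ubar <- apply(u, c(1, 2), mean)
  v <- with_seed_(derive_seed(params$seed, "participants"), stats::rnorm(P))

  meta <- data.frame(participant_id = rep(seq_len(P), each = n_clip),
                     clip_id = rep(clips$clip_id, P),
                     emotion = rep(clips$emotion, P),
                     score = NA_real_, is_synthetic = FALSE,
                     stringsAsFactors = FALSE)

  n_corrupt <- floor(params$corrupt_frac * n)
  corrupted <- logical(n)
  corrupted[with_seed_(derive_seed(params$seed, "assignment"),
                       sample.int(n, n_corrupt))] <- TRUE

  meta$score <- with_seed_(derive_seed(params$seed, "scores"), {
    s <- numeric(n)
    s[!corrupted] <- stats::rbeta(sum(!corrupted), params$score_high[1],
                                  params$score_high[2])
    s[corrupted] <- stats::rbeta(sum(corrupted), params$score_low[1],
                                 params$score_low[2])
    s
  })

  features <- matrix(0, n, ch * nb)
  raw <- if (keep_raw) vector("list", n) else NULL
  with_seed_(derive_seed(params$seed, "noise"), {
    for (i in seq_len(n)) {
      e <- meta$emotion[i]
      ue <- u[, , e]
      if (corrupted[i]) ue <- ubar + params$corrupt_attenuation * (ue - ubar)
      sigma <- params$base_sigma *
        exp(params$participant_sd * v[meta$participant_id[i]]) *
        exp(params$class_effect * ue)
      x <- synth_trial_cpp(sigma, bins, nsamp)
      features[i, ] <- extract_de_features(x, params$sampling_rate_hz,
                                           params$bands)
      if (keep_raw) raw[[i]] <- x
    }
  })

  corp <- eeg_corpus(meta, features,
                     clip_emotion_map = stats::setNames(clips$emotion,
                                                        as.character(clips$clip_id)),
                     n_participants = P,
                     sampling_rate_hz = params$sampling_rate_hz,
                     bands = params$bands, n_channels = ch, raw = raw)
  attr(corp, "generation") <- list(params = params, engaged = !corrupted,
                                   template_u = u, participant_v = v)
  corp
}

#' Hidden engagement flags of a generated corpus
#'
#' Returns the generator's hidden trial status, for recovery tests only: a
#' factor with levels `engaged` / `corrupted`, one entry per trial.
#'
#' @param corpus an `eeg_corpus` produced by [generate_corpus()].
#' @return factor of length `n_trials(corpus)`.
#' @export
ground_truth <- function(corpus) {
  gen <- attr(corpus, "generation")
  if (is.null(gen)) {
    stop("corpus carries no generator provenance; ground_truth() only ",
         "applies to corpora from generate_corpus()", call. = FALSE)
  }
  factor(ifelse(gen$engaged, "engaged", "corrupted"),
         levels = c("engaged", "corrupted"))
}

#' Closed-form feature templates of a generated corpus
#'
#' The population differential entropy of band-limited Gaussian noise with
#' standard deviation sigma is `0.5 * log(2 * pi * e * sigma^2)`. This helper
#' returns that closed form for each trial of a generated corpus (channel-major
#' layout, same as the extracted features), before filter-response and
#' finite-window effects.
#'
#' @param corpus an `eeg_corpus` produced by [generate_corpus()].
#' @return numeric matrix, trials x features, of template differential
#'   entropies in nats.
#' @export
template_de <- function(corpus) {
  gen <- attr(corpus, "generation")
  if (is.null(gen)) stop("corpus carries no generator provenance", call. = FALSE)
  p <- gen$params
  ubar <- apply(gen$template_u, c(1, 2), mean)
  out <- matrix(0, n_trials(corpus), p$n_channels * nrow(p$bands))
  meta <- trial_meta(corpus)
  for (i in seq_len(nrow(out))) {
    ue <- gen$template_u[, , meta$emotion[i]]
    if (!gen$engaged[i]) ue <- ubar + p$corrupt_attenuation * (ue - ubar)
    sigma <- p$base_sigma * exp(p$participant_sd *
                                  gen$participant_v[meta$participant_id[i]]) *
      exp(p$class_effect * ue)
    out[i, ] <- as.numeric(t(0.5 * log(2 * pi * exp(1) * sigma^2)))
  }
  out
}
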