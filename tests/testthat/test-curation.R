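test_that("score cleaning removes at-or-below-threshold trials only", {
  tr <- toy_trials(c(0.0, 0.2, 0.21, 0.9))
  kept <- clean_by_score(tr, 0.2)
  expect_equal(trial_meta(kept)$score, c(0.21, 0.9))
  expect_equal(n_trials(clean_by_score(tr, NULL)), 4L)
  # tau = 0 is distinct from no filtering: it drops exact-zero scores
  expect_equal(n_trials(clean_by_score(tr, 0)), 3L)
  strong <- toy_trials(c(0.96, 0.5, 0.94))
  expect_equal(n_trials(clean_by_score(strong, 0.95)), 1L)
  expect_error(clean_by_score(tr, 1.5), "\\[0, 1\\]")
})

test_that("cleaning is monotone: higher thresholds retain nested subsets", {
  for (seed in 1:5) {
    scores <- eegcurate:::with_seed_(seed, round(runif(40), 3))
    tr <- toy_trials(scores)
    taus <- sort(eegcurate:::with_seed_(seed + 100, runif(4)))
    prev <- trial_meta(clean_by_score(tr, taus[1]))$score
    for (tau in taus[-1]) {
      cur <- trial_meta(clean_by_score(tr, tau))$score
      expect_true(all(cur %in% prev))
      expect_lte(length(cur), length(prev))
      prev <- cur
    }
  }
})

test_that("averaging augmentation emits element-wise mean trials", {
  tr <- toy_trials(c(0.4, 0.8), features = rbind(c(0, 2), c(2, 0)), d = 2)
  out <- augment_average(tr, k = 2, seed = 1)
  expect_equal(n_trials(out), 3L)
  syn <- out[3]
  expect_true(trial_meta(syn)$is_synthetic)
  expect_equal(as.numeric(trial_features(syn)), c(1, 1))
  expect_equal(trial_meta(syn)$score, 0.6)
  expect_equal(trial_sources(syn)[[1]], c(1L, 2L))

  # averaging five identical trials reproduces the trial
  v <- c(1.5, -0.5, 3)
  five <- toy_trials(rep(0.7, 5), features = matrix(v, 5, 3, byrow = TRUE),
                     d = 3)
  out5 <- augment_average(five, k = 5, seed = 2)
  expect_equal(as.numeric(trial_features(out5[6])), v)

  # 6 same-class trials, k = 5, sliding window -> 6 - 5 + 1 = 2 synthetics
  six <- toy_trials(runif(6))
  expect_equal(n_trials(augment_average(six, k = 5, seed = 3)), 8L)
  # classes with fewer than k trials contribute nothing
  few <- toy_trials(c(0.5, 0.6), emotions = c("happy", "sad"))
  expect_equal(n_trials(augment_average(few, k = 5, seed = 1)), 2L)
  expect_error(augment_average(six, k = 1), ">= 2")
})

test_that("averaging groups never mix emotions", {
  tr <- toy_trials(runif(12), emotions = rep(c("happy", "sad"), each = 6))
  out <- augment_average(tr, k = 3, seed = 9)
  syn <- trial_meta(out)[trial_meta(out)$is_synthetic, ]
  expect_equal(nrow(syn), 2 * (6 - 3 + 1))
  expect_setequal(unique(syn$emotion), c("happy", "sad"))
})

test_that("gaussian augmentation doubles the set and preserves labels", {
  tr <- toy_trials(runif(10), emotions = sample(EMOTIONS, 10, TRUE),
                   features = matrix(rnorm(10 * 6), 10, 6), d = 6)
  out <- augment_gaussian(tr, seed = 4)
  expect_equal(n_trials(out), 20L)
  m <- trial_meta(out)
  expect_equal(m$emotion[11:20], m$emotion[1:10])
  expect_equal(m$score[11:20], m$score[1:10])
  expect_true(all(m$is_synthetic[11:20]))
  expect_false(any(m$is_synthetic[1:10]))
  expect_error(augment_gaussian(tr, modulation = c(0, 1)), "0 < low")
  expect_error(augment_gaussian(tr[0]), "non-empty")
})

test_that("gaussian noise variance follows the per-sample SNR scaling", {
  n <- 2000
  feats <- matrix(sample(c(-1, 1), n * 310, TRUE), n, 310)  # unit power
  tr <- toy_trials(rep(0.5, n), features = feats, d = 310)
  out <- augment_gaussian(tr, snr_db = 15, seed = 11)
  noise <- trial_features(out)[(n + 1):(2 * n), ] - feats
  per_copy <- rowMeans(noise^2)
  sigma0_sq <- 10^(-1.5)
  # m in [0.5, 1.5] times chi-square sampling noise over 310 features
  expect_gte(min(per_copy), 0.3 * sigma0_sq)
  expect_lte(max(per_copy), 2.0 * sigma0_sq)
  expect_equal(mean(per_copy), sigma0_sq, tolerance = 0.05)
})

test_that("time augmentation averages raw signals and re-extracts features", {
  corp <- small_corpus()
  meta <- trial_meta(corp)
  # two participants, same clip, identical raw signals -> identity
  i1 <- which(meta$participant_id == 1 & meta$clip_id == 1)
  twin <- corp
  twin$raw[[which(meta$participant_id == 2 & meta$clip_id == 1)]] <-
    twin$raw[[i1]]
  out <- augment_time(twin, train_participants = 1:2,
                      pairs = list(list(clip_id = 1L, participants = c(1L, 2L))))
  syn <- out[n_trials(out)]
  expect_equal(as.numeric(trial_features(syn)),
               as.numeric(trial_features(corp)[i1, ]), tolerance = 1e-9)
  i2 <- which(meta$participant_id == 2 & meta$clip_id == 1)
  expect_equal(trial_meta(syn)$score,
               mean(meta$score[c(i1, i2)]))
  expect_equal(trial_sources(syn)[[1]], c(1L, 2L))

  # a pair touching a participant outside the training set is a hard error
  expect_error(
    augment_time(corp, train_participants = 1:3,
                 pairs = list(list(clip_id = 1L, participants = c(1L, 5L)))),
    "leakage")
  expect_error(augment_time(random_corpus(1), 1:2), "raw signals")
})

test_that("time augmentation differs from feature-space averaging", {
  corp <- small_corpus()
  meta <- trial_meta(corp)
  i1 <- which(meta$participant_id == 1 & meta$clip_id == 2)
  i2 <- which(meta$participant_id == 2 & meta$clip_id == 2)
  out <- augment_time(corp, train_participants = 1:2,
                      pairs = list(list(clip_id = 2L, participants = c(1L, 2L))))
  syn_feat <- as.numeric(trial_features(out[n_trials(out)]))
  feat_mean <- colMeans(trial_features(corp)[c(i1, i2), ])
  # averaging independent signals halves the variance: DE drops by ~log(2)/...
  # whereas the feature mean does not; the two must differ materially
  expect_gt(mean(abs(syn_feat - feat_mean)), 0.1)
})

test_that("matched pairing respects training participants and clip structure", {
  corp <- small_corpus()
  out <- augment_time(corp, train_participants = c(1, 2, 4), seed = 2)
  m <- trial_meta(out)
  syn <- which(m$is_synthetic)
  expect_equal(length(syn), 14L)  # floor(3/2) pair per clip x 14 clips
  src <- unique(unlist(trial_sources(out)[syn]))
  expect_true(all(src %in% c(1, 2, 4)))
  # originals are exactly the training participants' trials
  expect_setequal(unique(m$participant_id[!m$is_synthetic]), c(1, 2, 4))
})

test_that("curation order is augment first, clean second", {
  tr <- toy_trials(c(0.1, 0.1, 0.1, 0.9, 0.9),
                   features = matrix(rnorm(5 * 4), 5, 4))
  # identity when both stages are disabled
  out0 <- apply_curation(tr, NULL, augment_spec("none"), tau = NULL)
  expect_equal(trial_features(out0), trial_features(tr))
  # gaussian doubles with no cleaning
  out1 <- apply_curation(tr, NULL, augment_spec("gaussian"), tau = NULL)
  expect_equal(n_trials(out1), 10L)
  # averaged synthetics inherit member-mean scores, so synthetics built from
  # low-score members are filtered out by the later cleaning stage
  out2 <- apply_curation(tr, NULL, augment_spec("average", k = 3), tau = 0.5)
  m2 <- trial_meta(out2)
  expect_true(all(m2$score > 0.5))
  expect_false(any(m2$is_synthetic & m2$score <= 0.5))
  expect_error(augment_spec(c("average", "gaussian")), "never combined")
})

test_that("every operator preserves the emotion label of every trial", {
  corp <- small_corpus()
  sub <- corp[trial_meta(corp)$participant_id %in% 1:3]
  before <- sort(unique(trial_meta(sub)$emotion))
  for (kind in c("average", "gaussian")) {
    out <- apply_curation(sub, corp, augment_spec(kind), tau = NULL,
                          train_participants = 1:3)
    m <- trial_meta(out)
    expect_true(all(m$emotion %in% before), info = kind)
    # synthetic emotions match the emotions of what they were built from
    expect_true(all(!m$is_synthetic | m$emotion %in% before), info = kind)
  }
  outt <- apply_curation(sub, corp, augment_spec("time"), tau = NULL,
                         train_participants = 1:3)
  mt <- trial_meta(outt)
  expect_equal(unname(corp$clip_emotion_map[as.character(mt$clip_id)]),
               mt$emotion)
})
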