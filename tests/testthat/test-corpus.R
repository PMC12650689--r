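test_that("corpus constructor enforces the type invariants", {
  corp <- random_corpus(1)
  expect_s3_class(corp, "eeg_corpus")
  expect_silent(validate_corpus(corp))

  bad <- trial_meta(corp)
  bad$score[2] <- 1.2
  expect_error(eeg_corpus(bad, trial_features(corp), bands = corp$band_spec,
                          n_channels = corp$n_channels),
               "row 2.*score.*outside")

  dup <- trial_meta(corp)
  dup$clip_id[2] <- dup$clip_id[1]
  dup$emotion[2] <- dup$emotion[1]
  expect_error(eeg_corpus(dup, trial_features(corp), bands = corp$band_spec,
                          n_channels = corp$n_channels),
               "duplicated non-synthetic")

  expect_error(eeg_corpus(trial_meta(corp), trial_features(corp)[, -1],
                          bands = corp$band_spec,
                          n_channels = corp$n_channels),
               "feature length")

  m <- trial_meta(corp); m$emotion[1] <- "bored"
  expect_error(eeg_corpus(m, trial_features(corp), bands = corp$band_spec,
                          n_channels = corp$n_channels), "unknown emotion")
})

test_that("table format round-trips losslessly and deterministically", {
  for (seed in 1:4) {
    corp <- random_corpus(seed)
    f <- withr::local_tempfile(fileext = ".csv")
    write_corpus(corp, f, "table")
    back <- read_corpus(f, "table", bands = corp$band_spec,
                        n_channels = corp$n_channels)
    o <- order(trial_meta(corp)$participant_id, trial_meta(corp)$clip_id)
    expect_equal(trial_meta(back), trial_meta(corp)[o, ],
                 ignore_attr = "row.names")
    expect_equal(trial_features(back), trial_features(corp)[o, ])
    # write(read(f)) byte-compares equal to f, and rewrites are identical
    f2 <- withr::local_tempfile(fileext = ".csv")
    write_corpus(back, f2, "table")
    expect_identical(readBin(f, "raw", file.size(f)),
                     readBin(f2, "raw", file.size(f2)))
  }
})

test_that("table parser rejects malformed input naming the offence", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,clip_id,emotion,score,f_0001,f_0002",
               "1,1,happy,0.5,0.1,0.2",
               "1,2,sad,1.2,0.3,0.4"), f)
  expect_error(read_corpus(f, "table", bands = band_spec("all", 1, 50),
                           n_channels = 2), "row 2.*score")
  writeLines(c("pid,clip,emotion,score", "1,1,happy,0.5"), f)
  expect_error(read_corpus(f, "table"), "malformed header")
  expect_error(read_corpus(file.path(tempdir(), "nope.csv"), "table"),
               "not found")
})

test_that("empty corpus writes a header-only table", {
  corp <- random_corpus(2)[0]
  f <- withr::local_tempfile(fileext = ".csv")
  write_corpus(corp, f, "table")
  expect_equal(length(readLines(f)), 1L)
  expect_match(readLines(f)[1], "^participant_id,clip_id,emotion,score,f_0001")
})

test_that("container format preserves raw signals and provenance", {
  corp <- small_corpus()
  sub <- corp[1:6]
  f <- withr::local_tempfile(fileext = ".rds")
  write_corpus(sub, f, "container")
  back <- read_corpus(f, "container")
  expect_equal(trial_features(back), trial_features(sub))
  expect_equal(back$raw, sub$raw)
  expect_equal(ground_truth(back), ground_truth(sub))
})

test_that("table format refuses synthetic trials", {
  corp <- random_corpus(3)
  aug <- augment_gaussian(corp, seed = 1)
  aug$clip_emotion_map <- corp$clip_emotion_map
  class(aug) <- class(corp)
  aug$n_participants <- corp$n_participants
  aug$sampling_rate_hz <- corp$sampling_rate_hz
  aug$band_spec <- corp$band_spec
  aug$n_channels <- corp$n_channels
  f <- withr::local_tempfile(fileext = ".csv")
  expect_error(write_corpus(aug, f, "table"), "synthetic")
})

test_that("SEED-VII export adapter reads the documented layout", {
  expect_error(read_seedvii(file.path(tempdir(), "no-such-dir")),
               "registration-gated")
  dir <- withr::local_tempdir()
  writeLines(c("clip_id,emotion", "1,happy", "2,sad"),
             file.path(dir, "clips.csv"))
  feat <- paste(sprintf("f_%04d", 1:310), collapse = ",")
  writeLines(c(paste("clip_id,score", feat, sep = ","),
               paste(c(1, 0.8, round(rnorm(310), 4)), collapse = ","),
               paste(c(2, 0.3, round(rnorm(310), 4)), collapse = ",")),
             file.path(dir, "participant_1.csv"))
  corp <- read_seedvii(dir)
  expect_equal(n_trials(corp), 2L)
  expect_equal(trial_meta(corp)$emotion, c("happy", "sad"))
  expect_equal(ncol(trial_features(corp)), 310L)
  expect_error(read_seedvii(withr::local_tempdir()), "clips.csv")
})
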