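test_that("subject folds partition participants evenly and reproducibly", {
  corp <- default_corpus(101)
  plan <- make_folds(corp, "subject", seed = 3)
  expect_equal(unname(tabulate(plan$participant_folds, 5)), rep(4L, 5))
  # every trial in exactly one fold; each participant's trials share a fold
  expect_equal(sort(unique(plan$assignment)), 1:5)
  expect_equal(length(plan$assignment), 1600L)
  meta <- trial_meta(corp)
  for (p in 1:20) {
    expect_equal(length(unique(plan$assignment[meta$participant_id == p])), 1L)
  }
  expect_identical(plan$assignment,
                   make_folds(corp, "subject", seed = 3)$assignment)
  expect_false(identical(plan$assignment,
                         make_folds(corp, "subject", seed = 4)$assignment))
})

test_that("trial folds balance sizes within one trial", {
  corp <- small_corpus()
  plan <- make_folds(corp, "trial", seed = 1)
  sizes <- tabulate(plan$assignment, 5)
  expect_lte(diff(range(sizes)), 1L)
  expect_equal(sum(sizes), n_trials(corp))
  tiny <- random_corpus(1, n_participants = 3)
  expect_error(make_folds(tiny, "subject"), "at least 5")
})

test_that("PCA transform honors rank, centering and full-variance identity", {
  set.seed(6)
  # exact rank-2 data
  u <- matrix(rnorm(20), 10, 2)
  v <- matrix(rnorm(16), 2, 8)
  X <- u %*% v
  pc <- fit_pca(X, 0.99)
  expect_lte(pc$n_components, 2L)
  # the training mean row maps to the origin
  expect_equal(as.numeric(predict(pc, matrix(colMeans(X), 1))),
               rep(0, pc$n_components), tolerance = 1e-10)
  # keep = 1 reconstructs the training data
  Xn <- X + matrix(rnorm(80, sd = 0.1), 10, 8)
  pc1 <- fit_pca(Xn, 1.0)
  recon <- predict(pc1, Xn) %*% t(pc1$rotation) +
    matrix(pc1$center, 10, 8, byrow = TRUE)
  expect_lt(max(abs(recon - Xn)), 1e-8)
  expect_error(fit_pca(Xn, 0), "\\(0, 1\\]")
  expect_error(fit_pca(Xn, 1.2), "\\(0, 1\\]")
})

test_that("binary metrics follow the precision/recall/F1 definitions", {
  # TP = 2, FP = 1, FN = 1 for the positive HA class
  y_true <- c("HA", "HA", "HA", "LA", "LA", "LA")
  y_pred <- c("HA", "HA", "LA", "HA", "LA", "LA")
  m <- precision_recall_f1(y_true, y_pred, task_scheme("binary"))
  expect_equal(m$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(m$recall, 2 / 3, tolerance = 1e-12)
  expect_equal(m$f1, 2 / 3, tolerance = 1e-12)
  expect_equal(m$accuracy, 4 / 6)
  perfect <- precision_recall_f1(y_true, y_true, task_scheme("binary"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_error(precision_recall_f1(character(0), character(0)), "empty")
  expect_error(precision_recall_f1(c("HA"), c("HA", "LA")), "equal length")
})

test_that("metrics agree with a brute-force confusion-matrix oracle", {
  scheme <- task_scheme("quadrant")
  for (seed in 1:6) {
    y <- eegcurate:::with_seed_(seed, {
      list(t = sample(scheme$classes, 25, TRUE),
           p = sample(scheme$classes, 25, TRUE))
    })
    m <- precision_recall_f1(y$t, y$p, scheme)
    # oracle: count the confusion cells directly, class by class
    f1s <- sapply(scheme$classes, function(cl) {
      tp <- sum(y$t == cl & y$p == cl)
      fp <- sum(y$t != cl & y$p == cl)
      fn <- sum(y$t == cl & y$p != cl)
      pr <- if (tp + fp > 0) tp / (tp + fp) else 0
      rc <- if (tp + fn > 0) tp / (tp + fn) else 0
      if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    })
    expect_equal(m$f1, mean(f1s))
    expect_equal(m$accuracy, mean(y$t == y$p))
    expect_equal(m$per_class$f1, unname(f1s))
  }
  # a class absent from truth and prediction scores F1 = 0 by convention
  m0 <- precision_recall_f1(rep("HAHV", 4), rep("HAHV", 4), scheme)
  expect_equal(m0$per_class$f1[m0$per_class$class == "LALV"], 0)
})

test_that("the fold-level confidence interval uses the normal approximation", {
  x <- 74 + 2.6 * c(-1, -1, 0, 1, 1)          # sample SD exactly 2.6, n = 5
  expect_equal(sd(x), 2.6)
  expect_equal(ci95(x), 2.279000, tolerance = 1e-5)
  expect_equal(ci95(c(70, 72, 74, 76, 78)), 1.96 * sqrt(2), tolerance = 1e-9)
  expect_equal(ci95(rep(5, 4)), 0)
  expect_error(ci95(3), "at least 2")
})

test_that("paired t-test matches hand-computed and reference values", {
  b <- c(10, 10, 10, 10, 10)
  a <- b + c(1, 2, 3, 4, 5)
  r <- paired_t(a, b)
  expect_equal(r$t, 4.242641, tolerance = 1e-6)
  expect_equal(r$p, 2 * pt(-4.242641, 4), tolerance = 1e-6)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  same <- paired_t(b, b)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  const <- paired_t(b + 1, b)
  expect_true(const$degenerate)
  expect_equal(const$p, 1)
})

test_that("run_cv produces a complete, bounded, leakage-checked result", {
  corp <- small_corpus()
  cfg <- pipeline_config(task = "binary", epochs = 3, seed = 2)
  res <- run_cv(corp, cfg)
  expect_s3_class(res, "cv_run")
  expect_equal(nrow(res$per_fold), 5L)
  expect_true(all(res$per_fold$accuracy >= 0 & res$per_fold$accuracy <= 1))
  expect_true(all(res$per_fold$f1 >= 0 & res$per_fold$f1 <= 1))
  expect_equal(res$ci95_acc, ci95(res$per_fold$accuracy))
  # test folds are evaluated raw: their sizes never shrink with cleaning
  res_clean <- run_cv(corp, pipeline_config(task = "binary", epochs = 3,
                                            clean_ratio = 0.6, seed = 2))
  expect_equal(res_clean$per_fold$n_test, res$per_fold$n_test)
  expect_true(all(res_clean$per_fold$n_train < res$per_fold$n_train))
})

test_that("gaussian augmentation doubles every fold's curated training set", {
  corp <- small_corpus()
  base <- run_cv(corp, pipeline_config(task = "binary", epochs = 2, seed = 3))
  doub <- run_cv(corp, pipeline_config(task = "binary", epochs = 2, seed = 3,
                                       augment = augment_spec("gaussian")))
  expect_equal(doub$per_fold$n_train, 2L * base$per_fold$n_train)
})

test_that("subject-mode training provenance excludes test participants", {
  corp <- small_corpus()
  plan <- make_folds(corp, "subject", seed = 11)
  meta <- trial_meta(corp)
  for (kind in c("none", "average", "gaussian", "time")) {
    for (fold in 1:5) {
      tr_idx <- which(plan$assignment != fold)
      tr_p <- sort(unique(meta$participant_id[tr_idx]))
      te_p <- setdiff(1:5, tr_p)
      cur <- apply_curation(corp[tr_idx], corp, augment_spec(kind),
                            tau = 0.2, train_participants = tr_p)
      expect_length(intersect(unique(unlist(trial_sources(cur))), te_p), 0)
    }
  }
})

test_that("PCA inside run_cv is fitted on curated training data only", {
  corp <- small_corpus()
  res <- run_cv(corp, pipeline_config(task = "binary", epochs = 2, pca = TRUE,
                                      clean_ratio = 0.4, seed = 5))
  expect_true(all(is.finite(res$per_fold$pca_components)))
  # component count can never exceed curated-training rows minus one
  expect_true(all(res$per_fold$pca_components <= res$per_fold$n_train - 1))
})

test_that("cv reports serialize to JSON with config and per-fold metrics", {
  corp <- small_corpus()
  res <- run_cv(corp, pipeline_config(task = "binary", epochs = 2, seed = 4))
  js <- jsonlite::fromJSON(cv_report_json(res))
  expect_equal(js$config$task, "binary")
  expect_equal(nrow(js$per_fold), 5L)
  expect_equal(js$summary$mean_acc, res$mean_acc, tolerance = 1e-9)
})
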