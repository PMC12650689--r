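#' Build a five-fold cross-validation plan
#'
#' Subject mode assigns whole participants to folds (no individual ever
#' contributes to both train and test; fold participant-counts differ by at
#' most 1). Trial mode deals shuffled trials round-robin (fold sizes differ
#' by at most 1). Plans are seeded and reproducible.
#'
#' @param corpus an `eeg_corpus`.
#' @param mode `"subject"` (default) or `"trial"`.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return an object of class `fold_plan`: list with `mode`, `k`,
#'   `assignment` (fold index per trial) and, in subject mode,
#'   `participant_folds` (named fold index per participant).
#' @export
make_folds <- function(corpus, mode = c("subject", "trial"), k = 5, seed = 1) {
  mode <- match.arg(mode)
  n <- n_trials(corpus)
  meta <- trial_meta(corpus)
  if (mode == "subject") {
    P <- corpus$n_participants
    if (P < k) stop("subject-mode folds need at least ", k, " participants; ",
                    "corpus has ", P, call. = FALSE)
    ord <- with_seed_(derive_seed(seed, "folds"), sample.int(P))
    pf <- integer(P)
    pf[ord] <- rep(seq_len(k), length.out = P)
    assignment <- pf[meta$participant_id]
    participant_folds <- stats::setNames(pf, seq_len(P))
  } else {
    ord <- with_seed_(derive_seed(seed, "folds"), sample.int(n))
    assignment <- integer(n)
    assignment[ord] <- rep(seq_len(k), length.out = n)
    participant_folds <- NULL
  }
  structure(list(mode = mode, k = as.integer(k), assignment = assignment,
                 participant_folds = participant_folds, seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("fold_plan:", x$k, "folds,", x$mode, "mode; fold sizes:",
      paste(tabulate(x$assignment, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Fit a PCA transform on training features
#'
#' Centers the training features and retains the smallest number of principal
#' components whose cumulative explained variance reaches `variance_keep`
#' (component count never exceeds `min(n - 1, d)`). The fitted transform must
#' be applied unchanged to test data via `predict()`.
#'
#' @param train_features numeric matrix (>= 2 rows).
#' @param variance_keep cumulative explained-variance target in (0, 1\]
#'   (default 0.99).
#' @return an object of class `pca_transform` with elements `rotation`,
#'   `center`, `n_components`, `explained`.
#' @export
fit_pca <- function(train_features, variance_keep = 0.99) {
  if (!is.numeric(variance_keep) || variance_keep <= 0 || variance_keep > 1) {
    stop("variance_keep must be in (0, 1]", call. = FALSE)
  }
  stopifnot(is.matrix(train_features), nrow(train_features) >= 2)
  pc <- stats::prcomp(train_features, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  m <- which(cum >= variance_keep - 1e-12)[1]
  if (is.na(m)) m <- length(ev)
  m <- min(m, nrow(train_features) - 1L, ncol(train_features))
  structure(list(rotation = pc$rotation[, seq_len(m), drop = FALSE],
                 center = pc$center, n_components = m,
                 explained = cum[m]),
            class = "pca_transform")
}

#' @export
predict.pca_transform <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  sweep(newdata, 2, object$center) %*% object$rotation
}

#' @export
print.pca_transform <- function(x, ...) {
  cat("pca_transform:", x$n_components, "components,",
      sprintf("%.2f%%", 100 * x$explained), "variance explained\n")
  invisible(x)
}

#' Precision, recall, F1 and accuracy
#'
#' Binary schemes score the positive (high-arousal) class:
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`. Multi-class schemes
#' compute one-vs-rest metrics per class and report the macro-averaged F1.
#' A class with no true and no predicted members has F1 defined as 0.
#'
#' @param y_true,y_pred label vectors of equal length (coerced through the
#'   scheme).
#' @param scheme a [task_scheme()], or `NULL` to infer a generic scheme from
#'   the union of labels (first sorted label positive for 2 classes).
#' @return an object of class `eeg_metrics`: accuracy, precision, recall,
#'   f1 (positive-class for binary, macro otherwise), and a per-class table
#'   with TP/FP/FN/TN counts.
#' @export
precision_recall_f1 <- function(y_true, y_pred, scheme = NULL) {
  if (length(y_true) == 0L) stop("empty label vectors", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (!is.null(scheme)) {
    classes <- scheme$classes
    positive <- if (!is.null(scheme$positive)) scheme$positive else classes[1]
  } else {
    classes <- sort(unique(c(as.character(y_true), as.character(y_pred))))
    positive <- classes[1]
  }
  yt <- factor(as.character(y_true), levels = classes)
  yp <- factor(as.character(y_pred), levels = classes)
  if (anyNA(yt) || anyNA(yp)) stop("labels outside the scheme's classes",
                                   call. = FALSE)
  n <- length(yt)
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(yt == cl & yp == cl)
    fp <- sum(yt != cl & yp == cl)
    fn <- sum(yt == cl & yp != cl)
    tn <- n - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, TP = tp, FP = fp, FN = fn, TN = tn,
               precision = prec, recall = rec, f1 = f1,
               stringsAsFactors = FALSE)
  }))
  acc <- mean(yt == yp)
  if (length(classes) == 2L) {
    row <- per[per$class == positive, ]
    out <- list(accuracy = acc, precision = row$precision, recall = row$recall,
                f1 = row$f1, averaging = "binary", positive = positive,
                per_class = per)
  } else {
    out <- list(accuracy = acc, precision = mean(per$precision),
                recall = mean(per$recall), f1 = mean(per$f1),
                averaging = "macro", positive = NULL, per_class = per)
  }
  structure(out, class = "eeg_metrics")
}

#' @export
print.eeg_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f | f1 %.4f (%s)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$averaging))
  invisible(x)
}

#' 95% confidence-interval half-width across folds
#'
#' Normal approximation: `1.96 * SD / sqrt(n)` with the sample (n-1) standard
#' deviation — the convention for fold-level summaries here.
#'
#' @param values numeric vector of per-fold values (length >= 2).
#' @return half-width of the 95% confidence interval.
#' @export
#' @examples
#' ci95(c(74, 75, 78, 73, 76))
ci95 <- function(values) {
  n <- length(values)
  if (n < 2L) stop("ci95 needs at least 2 values", call. = FALSE)
  1.96 * stats::sd(values) / sqrt(n)
}

#' Paired t-test across folds
#'
#' Two-sided paired t-test on per-fold differences `a - b`. When the
#' differences have zero variance the statistic is undefined; the result is
#' flagged (`degenerate = TRUE`) and `p = 1` is returned (with `t = 0` when
#' all differences are zero).
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return list with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop("paired_t needs two equal-length vectors of length >= 2",
         call. = FALSE)
  }
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t = if (mean(d) == 0) 0 else NaN, p = 1, df = n - 1L,
                mean_diff = mean(d), degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1L,
       mean_diff = mean(d), degenerate = FALSE)
}

#' Pipeline configuration for a cross-validated run
#'
#' @param task `"binary"`, `"quadrant"` or `"seven"`.
#' @param augment an [augment_spec()].
#' @param clean_ratio cleaning ratio in \[0, 1\] or `NULL` (no filtering).
#' @param pca apply PCA fitted on the curated training features
#'   (default `FALSE`).
#' @param pca_keep variance-retention target (default 0.99).
#' @param model_variant CNN variant 1, 2 or 3.
#' @param fold_mode `"subject"` or `"trial"`.
#' @param epochs,learning_rate,batch_size training protocol (defaults 50,
#'   1e-4, 32).
#' @param seed master seed; folds, augmentation, initialization and training
#'   derive named substreams from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(task = c("binary", "quadrant", "seven"),
                            augment = augment_spec("none"), clean_ratio = NULL,
                            pca = FALSE, pca_keep = 0.99, model_variant = 1,
                            fold_mode = c("subject", "trial"), epochs = 50,
                            learning_rate = 1e-4, batch_size = 32, seed = 1) {
  task <- match.arg(task)
  fold_mode <- match.arg(fold_mode)
  stopifnot(inherits(augment, "augment_spec"))
  if (!is.null(clean_ratio) &&
      (!is.numeric(clean_ratio) || clean_ratio < 0 || clean_ratio > 1)) {
    stop("clean_ratio must be in [0, 1] or NULL", call. = FALSE)
  }
  structure(list(task = task, augment = augment, clean_ratio = clean_ratio,
                 pca = isTRUE(pca), pca_keep = pca_keep,
                 model_variant = as.integer(model_variant),
                 fold_mode = fold_mode, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# internal: scheme name from task
task_to_scheme <- function(task) {
  task_scheme(switch(task, binary = "binary", quadrant = "quadrant",
                     seven = "seven"))
}

#' Run the leakage-safe five-fold pipeline
#'
#' For each fold: the training folds are curated (augmented, then cleaned)
#' via [apply_curation()]; PCA (optional) and feature standardization are
#' fitted on the curated training features only; the CNN is trained; the
#' untouched test fold — never cleaned, never augmented — is evaluated. In
#' subject mode, any overlap between the provenance of curated training
#' trials and the test participants aborts the run.
#'
#' @param corpus an `eeg_corpus`.
#' @param config a [pipeline_config()].
#' @return an object of class `cv_run`: per-fold metrics, aggregate mean/SD,
#'   95% CI half-widths, per-fold curated training sizes, the resolved
#'   config and fold plan.
#' @export
run_cv <- function(corpus, config = pipeline_config()) {
  stopifnot(inherits(corpus, "eeg_corpus"), inherits(config, "pipeline_config"))
  if (config$augment$kind == "time" && is.null(corpus$raw)) {
    stop("time-domain augmentation requires raw signals in the corpus",
         call. = FALSE)
  }
  scheme <- task_to_scheme(config$task)
  plan <- make_folds(corpus, mode = config$fold_mode, k = 5,
                     seed = derive_seed(config$seed, "cv-folds"))
  meta <- trial_meta(corpus)
  per_fold <- vector("list", plan$k)
  for (fold in seq_len(plan$k)) {
    test_idx <- which(plan$assignment == fold)
    train_idx <- which(plan$assignment != fold)
    train_participants <- sort(unique(meta$participant_id[train_idx]))
    test_participants <- sort(unique(meta$participant_id[test_idx]))
    aug <- config$augment
    aug$seed <- derive_seed(config$seed, paste0("augment-", fold))
    curated <- apply_curation(corpus[train_idx], corpus, augment = aug,
                              tau = config$clean_ratio,
                              train_participants = train_participants)
    if (plan$mode == "subject") {
      leaked <- intersect(unique(unlist(trial_sources(curated))),
                          test_participants)
      if (length(leaked)) {
        stop("leakage: curated training set draws on test participant(s) ",
             paste(leaked, collapse = ", "), call. = FALSE)
      }
    }
    x_train <- trial_features(curated)
    y_train <- scheme_labels(scheme, trial_meta(curated)$emotion)
    x_test <- trial_features(corpus)[test_idx, , drop = FALSE]
    y_test <- scheme_labels(scheme, meta$emotion[test_idx])
    pca <- NULL
    if (config$pca) {
      pca <- fit_pca(x_train, config$pca_keep)
      x_train <- predict(pca, x_train)
      x_test <- predict(pca, x_test)
    }
    model <- cnn_fit(x_train, y_train, variant = config$model_variant,
                     epochs = config$epochs,
                     learning_rate = config$learning_rate,
                     batch_size = config$batch_size,
                     seed = derive_seed(config$seed, paste0("fit-", fold)),
                     positive = scheme$positive)
    pred <- predict(model, x_test)
    m <- precision_recall_f1(y_test, pred, scheme)
    per_fold[[fold]] <- data.frame(fold = fold, accuracy = m$accuracy,
                                   f1 = m$f1, n_train = n_trials(curated),
                                   n_test = length(test_idx),
                                   pca_components = if (is.null(pca)) NA_integer_
                                                    else pca$n_components)
  }
  pf <- do.call(rbind, per_fold)
  res <- list(per_fold = pf,
              mean_acc = mean(pf$accuracy), sd_acc = stats::sd(pf$accuracy),
              mean_f1 = mean(pf$f1), sd_f1 = stats::sd(pf$f1),
              ci95_acc = ci95(pf$accuracy), ci95_f1 = ci95(pf$f1),
              config = config, fold_plan = plan)
  class(res) <- "cv_run"
  res
}

#' @export
print.cv_run <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("cv_run: task=%s augment=%s clean=%s pca=%s variant=%d (%s folds)\n",
              cfg$task, cfg$augment$kind,
              if (is.null(cfg$clean_ratio)) "none" else cfg$clean_ratio,
              cfg$pca, cfg$model_variant, cfg$fold_mode))
  cat(sprintf("  accuracy %.1f%% +/- %.1f (CI95 +/- %.1f) | F1 %.1f%% +/- %.1f (CI95 +/- %.1f)\n",
              100 * x$mean_acc, 100 * x$sd_acc, 100 * x$ci95_acc,
              100 * x$mean_f1, 100 * x$sd_f1, 100 * x$ci95_f1))
  invisible(x)
}

#' @export
summary.cv_run <- function(object, ...) {
  print(object)
  cat("per fold:\n")
  print(object$per_fold, row.names = FALSE)
  invisible(object)
}

#' Serialize a cross-validation run to JSON
#'
#' @param run a `cv_run`.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
cv_report_json <- function(run, path = NULL) {
  stopifnot(inherits(run, "cv_run"))
  cfg <- run$config
  payload <- list(
    config = list(task = cfg$task, augment = cfg$augment$kind,
                  clean_ratio = if (is.null(cfg$clean_ratio)) "none"
                                else cfg$clean_ratio,
                  pca = cfg$pca, pca_keep = cfg$pca_keep,
                  model_variant = cfg$model_variant,
                  fold_mode = cfg$fold_mode, epochs = cfg$epochs,
                  learning_rate = cfg$learning_rate,
                  batch_size = cfg$batch_size, seed = cfg$seed),
    per_fold = run$per_fold,
    summary = list(mean_acc = run$mean_acc, sd_acc = run$sd_acc,
                   ci95_acc = run$ci95_acc, mean_f1 = run$mean_f1,
                   sd_f1 = run$sd_f1, ci95_f1 = run$ci95_f1))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
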