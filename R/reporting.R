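#' Improvement arithmetic for summary tables
#'
#' Point mode returns `best - baseline`; relative mode returns
#' `100 * (best - baseline) / baseline`. Both are rounded half away from zero
#' to one decimal, the convention used for printed percentage tables.
#'
#' @param best,baseline numeric scalars (percent scale).
#' @param mode `"points"` or `"relative"`.
#' @return the rounded improvement.
#' @export
#' @examples
#' improvement(38.6, 27.8, "relative") # 38.8
#' improvement(82.5, 74.2, "points")   # 8.3
improvement <- function(best, baseline, mode = c("points", "relative")) {
  mode <- match.arg(mode)
  if (mode == "relative") {
    if (baseline == 0) stop("relative improvement undefined for baseline 0",
                            call. = FALSE)
    return(round_half_away(100 * (best - baseline) / baseline, 1))
  }
  round_half_away(best - baseline, 1)
}

#' Sample retention by cleaning threshold
#'
#' Tabulates, for each cleaning ratio, how many trials survive
#' [clean_by_score()], the surviving per-class counts under a task scheme,
#' and the retained percentage of the full corpus.
#'
#' @param corpus an `eeg_corpus` (or `eeg_trials`) with scores.
#' @param thresholds numeric vector of cleaning ratios; use `NA` for the
#'   no-filtering row.
#' @param scheme a [task_scheme()] for the class split (default binary).
#' @return a data frame with columns `tau`, `retained`, one count column per
#'   class, and `percent`.
#' @export
retention_table <- function(corpus, thresholds = c(NA, 0, 0.2, 0.4, 0.6, 0.8, 0.95),
                            scheme = task_scheme("binary")) {
  total <- n_trials(corpus)
  rows <- lapply(thresholds, function(tau) {
    kept <- clean_by_score(corpus, if (is.na(tau)) NULL else tau)
    y <- scheme_labels(scheme, trial_meta(kept)$emotion)
    counts <- as.integer(table(y))
    df <- data.frame(tau = tau, retained = n_trials(kept))
    for (j in seq_along(scheme$classes)) df[[scheme$classes[j]]] <- counts[j]
    df$percent <- round_half_away(100 * n_trials(kept) / total, 2)
    df
  })
  do.call(rbind, rows)
}

#' Sweep grid
#'
#' The default grid reproduces the row/column structure of the cleaning-by-
#' augmentation result tables: cleaning ratios none, 0, 0.2, 0.4, 0.6, 0.8,
#' 0.95 crossed with the augmentation kinds and PCA on/off.
#'
#' @param cleaning_ratios list of cleaning ratios (`NA` = no filtering).
#' @param augmentations character vector of augmentation kinds.
#' @param pca logical vector (PCA off/on).
#' @param tasks character vector of task names.
#' @return an object of class `sweep_grid`.
#' @export
sweep_grid <- function(cleaning_ratios = c(NA, 0, 0.2, 0.4, 0.6, 0.8, 0.95),
                       augmentations = c("none", "average", "gaussian", "time"),
                       pca = c(FALSE, TRUE), tasks = "binary") {
  structure(list(cleaning_ratios = cleaning_ratios,
                 augmentations = augmentations, pca = pca, tasks = tasks),
            class = "sweep_grid")
}

#' Run a cleaning-by-augmentation sweep
#'
#' Runs [run_cv()] once per grid cell and collects a long-format table
#' (one row per task x cleaning ratio x augmentation x PCA cell) plus a
#' best-cell summary per task: the cell with the highest mean F1, the
#' unfiltered no-augmentation baseline, and their relative improvement.
#' Failing cells are recorded and skipped; the sweep continues.
#'
#' @param corpus an `eeg_corpus`.
#' @param grid a [sweep_grid()].
#' @param base_config a [pipeline_config()] supplying everything the grid
#'   does not vary (model variant, seeds, training protocol).
#' @return an object of class `sweep_result`: `results` (long data frame,
#'   metrics on the percent scale), `best` (per-task summary), `failures`.
#' @export
run_sweep <- function(corpus, grid = sweep_grid(), base_config = pipeline_config()) {
  stopifnot(inherits(grid, "sweep_grid"))
  cells <- expand.grid(task = grid$tasks, tau = grid$cleaning_ratios,
                       augment = grid$augmentations, pca = grid$pca,
                       stringsAsFactors = FALSE)
  rows <- list(); failures <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    cfg <- base_config
    cfg$task <- cell$task
    cfg$clean_ratio <- if (is.na(cell$tau)) NULL else cell$tau
    cfg$augment <- augment_spec(cell$augment, seed = base_config$augment$seed)
    cfg$pca <- cell$pca
    res <- tryCatch(run_cv(corpus, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(task = cell$task, tau = cell$tau, augment = cell$augment,
                   pca = cell$pca, error = conditionMessage(res))
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(task = cell$task, tau = cell$tau, augment = cell$augment,
                 pca = cell$pca,
                 mean_acc = 100 * res$mean_acc, sd_acc = 100 * res$sd_acc,
                 mean_f1 = 100 * res$mean_f1, sd_f1 = 100 * res$sd_f1,
                 ci95_acc = 100 * res$ci95_acc, ci95_f1 = 100 * res$ci95_f1)
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  best <- NULL
  if (!is.null(results)) {
    best <- do.call(rbind, lapply(unique(results$task), function(tk) {
      sub <- results[results$task == tk, ]
      b <- sub[which.max(sub$mean_f1), ]
      base <- sub[is.na(sub$tau) & sub$augment == "none" & !sub$pca, ]
      if (nrow(base) == 0L) base <- sub[which.min(sub$mean_f1), ]
      data.frame(task = tk, best_f1 = b$mean_f1, best_tau = b$tau,
                 best_augment = b$augment, best_pca = b$pca,
                 baseline_f1 = base$mean_f1[1],
                 improvement_rel = improvement(b$mean_f1, base$mean_f1[1],
                                               "relative"))
    }))
  }
  structure(list(results = results, best = best,
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result:", if (is.null(x$results)) 0 else nrow(x$results),
      "cells completed,",
      if (is.null(x$failures)) 0 else nrow(x$failures), "failed\n")
  if (!is.null(x$best)) {
    cat("best cells:\n")
    print(x$best, row.names = FALSE)
  }
  invisible(x)
}

#' Write / read a sweep's long-format table
#'
#' The CSV schema is stable (`task, tau, augment, pca, mean_acc, sd_acc,
#' mean_f1, sd_f1, ci95_acc, ci95_f1`) and round-trips losslessly; the rows
#' are heat-map ready (cleaning ratio by augmentation).
#'
#' @param sweep a `sweep_result` (or its `results` data frame).
#' @param path CSV file path.
#' @return `path` invisibly; `read_sweep_csv()` returns the data frame.
#' @export
write_sweep_csv <- function(sweep, path) {
  df <- if (inherits(sweep, "sweep_result")) sweep$results else sweep
  stopifnot(is.data.frame(df))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
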