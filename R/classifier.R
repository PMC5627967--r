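#' Kernel classifier specification
#'
#' Settings for the binary max-margin classifier used per window: kernel
#' family, box constraint (regularization), Gaussian kernel scale
#' (bandwidth sigma; the kernel is `exp(-|u - v|^2 / sigma^2)`), and the
#' cross-validation tuning grid. A custom trainer can be plugged in via
#' `trainer`: a `function(x, y, spec)` returning any object with a
#' `predict(object, newdata)` method (this is the slot where alternative
#' classifiers such as discriminative regression machines attach).
#'
#' @param kernel `"linear"` or `"gaussian"`.
#' @param box_constraint Positive regularization constant C.
#' @param kernel_scale Positive Gaussian bandwidth (ignored for linear).
#' @param cv_folds Folds for hyperparameter cross-validation.
#' @param box_grid Candidate box constraints for tuning.
#' @param scale_grid Candidate kernel-scale multipliers; multiplied by the
#'   median pairwise distance of the tuning windows.
#' @param trainer Optional plug-in training function.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(kernel = c("linear", "gaussian"),
                            box_constraint = 1, kernel_scale = 1,
                            cv_folds = 5,
                            box_grid = 10^(-2:2),
                            scale_grid = c(0.1, 1, 10, 100),
                            trainer = NULL) {
  kernel <- match.arg(kernel)
  stopifnot(box_constraint > 0, kernel_scale > 0, cv_folds >= 2)
  structure(list(kernel = kernel, box_constraint = box_constraint,
                 kernel_scale = kernel_scale, cv_folds = as.integer(cv_folds),
                 box_grid = box_grid, scale_grid = scale_grid,
                 trainer = trainer),
            class = "classifier_spec")
}

# Fit one binary classifier on a window matrix (rows = examples).
.fit_classifier <- function(x, y, spec) {
  if (!is.null(spec$trainer)) return(spec$trainer(x, y, spec))
  if (spec$kernel == "linear") {
    e1071::svm(x = x, y = y, kernel = "linear", cost = spec$box_constraint,
               scale = FALSE)
  } else {
    e1071::svm(x = x, y = y, kernel = "radial",
               cost = spec$box_constraint,
               gamma = 1 / spec$kernel_scale^2, scale = FALSE)
  }
}

#' Tune hyperparameters by k-fold cross-validation
#'
#' Grid-searches the box constraint (and, for the Gaussian kernel, the
#' kernel scale, on a grid of multiples of the median pairwise distance
#' between training windows) by stratified k-fold cross-validated accuracy.
#' Ties break towards the smaller box constraint, then the smaller kernel
#' scale; fold assignment is deterministic given `fold_seed`.
#'
#' @param x Matrix of training windows (rows = examples).
#' @param y Factor (or vector) of two class labels.
#' @param spec A [classifier_spec()] template.
#' @param fold_seed Integer seed for fold assignment.
#' @return The spec with `box_constraint`/`kernel_scale` set to the winning
#'   grid point and an added `cv_accuracy` field.
#' @export
tune_hyperparameters <- function(x, y, spec = classifier_spec(),
                                 fold_seed = 1L) {
  y <- factor(y)
  if (nlevels(y) < 2) stop("tuning needs examples from both classes", call. = FALSE)
  if (min(table(y)) < spec$cv_folds) {
    stop("need at least cv_folds (", spec$cv_folds,
         ") training examples per class", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(fold_seed %% 2^31))
  folds <- integer(length(y))
  for (lv in levels(y)) {          # stratified assignment
    idx <- which(y == lv)
    folds[idx] <- sample(rep_len(seq_len(spec$cv_folds), length(idx)))
  }
  scales <- if (spec$kernel == "gaussian") {
    med <- stats::median(stats::dist(x))
    if (!is.finite(med) || med <= 0) med <- 1
    sort(spec$scale_grid * med)
  } else 1
  grid <- expand.grid(box = sort(spec$box_grid), scale = scales)
  cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
    sp <- spec
    sp$box_constraint <- grid$box[g]
    sp$kernel_scale <- grid$scale[g]
    accs <- vapply(seq_len(spec$cv_folds), function(f) {
      tr <- folds != f
      if (nlevels(droplevels(y[tr])) < 2) return(NA_real_)
      fit <- .fit_classifier(x[tr, , drop = FALSE], y[tr], sp)
      mean(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }, 0)
    mean(accs, na.rm = TRUE)
  }, 0)
  # max accuracy; ties to smaller box then smaller scale (grid is sorted
  # with box varying fastest, so the first argmax is the tie-break winner)
  ord <- order(grid$box, grid$scale)
  grid <- grid[ord, ]; cv_acc <- cv_acc[ord]
  best <- which.max(cv_acc)
  spec$box_constraint <- grid$box[best]
  spec$kernel_scale <- grid$scale[best]
  spec$cv_accuracy <- cv_acc[best]
  spec
}

#' Online windowed leave-one-out classification run
#'
#' The online protocol: signals are cut into half-overlapping windows; at
#' each window index a fresh binary classifier is trained on the training
#' trials' windows at that index (raw samples as features) and predicts the
#' held-out trial's window at the same index, emulating train/predict on a
#' live stream. Every trial is held out once (leave-one-out repeats).
#' Hyperparameters are tuned once per run, by cross-validation on the first
#' window of the first repeat's training set, then reused across window
#' indices.
#'
#' @param dataset A `rig_dataset` with exactly two condition labels.
#' @param sensor_id Sensor to classify from.
#' @param window A [window_spec()] (or window length in samples).
#' @param spec A [classifier_spec()].
#' @param seed Integer seed for CV fold assignment.
#' @param tune If `FALSE`, use the spec's hyperparameters as given.
#' @return Object of class `online_run`: list with `sensor_id`, `window`,
#'   `spec` (post-tuning), `true` (per-repeat labels), `predicted`
#'   (repeats x windows matrix), `correct` (logical matrix),
#'   `repeat_accuracy`, `window_accuracy`, `mean_accuracy`, `sd_accuracy`.
#' @export
online_run <- function(dataset, sensor_id, window, spec = classifier_spec(),
                       seed = 1L, tune = TRUE) {
  if (!inherits(window, "window_spec")) window <- window_spec(window)
  labels <- factor(dataset_labels(dataset))
  if (nlevels(labels) != 2) stop("online_run is binary: need exactly 2 labels", call. = FALSE)
  if (min(table(labels)) < 2) stop("need at least 2 trials per class", call. = FALSE)
  signals <- dataset_signals(dataset, sensor_id)
  wins <- lapply(signals, segment_windows, spec = window)
  n_win <- nrow(wins[[1]])
  n_rep <- length(signals)

  if (tune) {
    tr <- setdiff(seq_len(n_rep), 1L)
    if (min(table(labels[tr])) >= spec$cv_folds) {
      x0 <- do.call(rbind, lapply(wins[tr], function(w) w[1, , drop = FALSE]))
      spec <- tune_hyperparameters(x0, labels[tr], spec,
                                   fold_seed = child_seed(seed, 7L))
    } else {
      message("too few trials per class for ", spec$cv_folds,
              "-fold tuning; using the spec's hyperparameters as given")
    }
  }

  predicted <- matrix(NA_character_, n_rep, n_win)
  for (r in seq_len(n_rep)) {
    tr <- setdiff(seq_len(n_rep), r)
    y_tr <- labels[tr]
    for (k in seq_len(n_win)) {
      x_tr <- do.call(rbind, lapply(wins[tr], function(w) w[k, , drop = FALSE]))
      fit <- .fit_classifier(x_tr, y_tr, spec)
      predicted[r, k] <- as.character(predict(fit, wins[[r]][k, , drop = FALSE]))
    }
  }
  true <- as.character(labels)
  correct <- predicted == matrix(true, n_rep, n_win)
  rep_acc <- rowMeans(correct)
  structure(list(sensor_id = sensor_id, window = window, spec = spec,
                 true = true, predicted = predicted, correct = correct,
                 repeat_accuracy = rep_acc,
                 window_accuracy = colMeans(correct),
                 mean_accuracy = mean(rep_acc),
                 sd_accuracy = stats::sd(rep_acc)),
            class = "online_run")
}

#' @export
print.online_run <- function(x, ...) {
  cat(sprintf("<online_run> %s | n = %d (%.0f ms) | accuracy %.1f%% +/- %.1f%% over %d repeats x %d windows\n",
              x$sensor_id, x$window$n,
              ifelse(is.na(x$window$window_ms), NA, x$window$window_ms),
              100 * x$mean_accuracy, 100 * x$sd_accuracy,
              length(x$repeat_accuracy), length(x$window_accuracy)))
  invisible(x)
}

#' Summarise an online run
#'
#' @param result An [online_run()] result.
#' @return List with `mean` and `sd` of accuracy over repeats (each repeat's
#'   accuracy is its mean over window indices) and `curve`, a tibble of
#'   accuracy per window index across repeats.
#' @export
accuracy_summary <- function(result) {
  stopifnot(inherits(result, "online_run"))
  list(mean = result$mean_accuracy, sd = result$sd_accuracy,
       curve = tibble::tibble(window_index = seq_along(result$window_accuracy),
                              accuracy = result$window_accuracy))
}

#' Accuracy versus window size
#'
#' Runs the online protocol for each sensor at each window size and tabulates
#' mean accuracy with its standard error over repeats.
#'
#' @param dataset A `rig_dataset`.
#' @param sensor_ids Sensors to sweep.
#' @param window_ms Window sizes in milliseconds (converted to even sample
#'   counts at the dataset's rate).
#' @param spec A [classifier_spec()].
#' @param seed Integer seed.
#' @return Tibble: sensor, window_ms, n, mean_accuracy, se_accuracy,
#'   sd_accuracy.
#' @export
window_sweep <- function(dataset, sensor_ids, window_ms,
                         spec = classifier_spec(), seed = 1L) {
  rate <- dataset[[1]]$config$sample_rate
  rows <- list()
  for (sid in sensor_ids) {
    for (ms in window_ms) {
      n_raw <- floor(rate * ms / 1000)
      ws <- suppressWarnings(window_spec(n_raw, sample_rate = rate))
      run <- online_run(dataset, sid, ws, spec,
                        seed = child_seed(seed, match(sid, sensor_ids),
                                          round(ms)))
      n_rep <- length(run$repeat_accuracy)
      rows[[length(rows) + 1]] <- tibble::tibble(
        sensor = sid, window_ms = ms, n = ws$n,
        mean_accuracy = run$mean_accuracy,
        se_accuracy = run$sd_accuracy / sqrt(n_rep),
        sd_accuracy = run$sd_accuracy)
    }
  }
  do.call(rbind, rows)
}
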