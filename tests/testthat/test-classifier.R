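test_that("separable constant classes classify perfectly at every window index", {
  ds <- toy_dataset(n_per_class = 6, P = 40, noise = 0.05)
  run <- online_run(ds, "S", window_spec(10), classifier_spec("linear"),
                    seed = 5, tune = FALSE)
  expect_true(all(run$correct))
  expect_equal(run$mean_accuracy, 1)
  expect_equal(run$sd_accuracy, 0)
  expect_equal(length(run$repeat_accuracy), 12)   # leave-one-out over all trials
  expect_equal(length(run$window_accuracy), window_count(40, 10))
})

test_that("identical-generator classes stay near chance", {
  # both "classes" drawn from the same process: accuracy should sit within
  # 3 binomial standard errors of 50% over repeats x windows
  set.seed(123)
  P <- 60
  trials <- lapply(1:16, function(i) {
    list(label = if (i <= 8) "A" else "B",
         signals = list(S = rnorm(P)), config = list(sample_rate = 100))
  })
  ds <- structure(trials, class = "rig_dataset",
                  labels = rep(c("A", "B"), each = 8))
  run <- online_run(ds, "S", window_spec(20),
                    classifier_spec("linear", box_constraint = 1),
                    seed = 7, tune = FALSE)
  n_pred <- length(run$correct)
  se <- sqrt(0.25 / n_pred)
  expect_lt(abs(mean(run$correct) - 0.5), 3 * se + 0.1)
})

test_that("hyperparameter tuning is deterministic and finds separable settings", {
  set.seed(33)
  x <- rbind(matrix(rnorm(200, 2), 10), matrix(rnorm(200, -2), 10))
  y <- rep(c("A", "B"), each = 10)
  sp1 <- tune_hyperparameters(x, y, classifier_spec("gaussian"), fold_seed = 42)
  sp2 <- tune_hyperparameters(x, y, classifier_spec("gaussian"), fold_seed = 42)
  expect_identical(sp1[c("box_constraint", "kernel_scale", "cv_accuracy")],
                   sp2[c("box_constraint", "kernel_scale", "cv_accuracy")])
  expect_equal(sp1$cv_accuracy, 1)

  expect_error(tune_hyperparameters(x, rep("A", 20)), "both classes")
  expect_error(tune_hyperparameters(x[1:6, ], y[c(1:3, 11:13)]), "cv_folds")
})

test_that("label-shuffled tuning stays near chance accuracy", {
  set.seed(44)
  accs <- vapply(1:5, function(s) {
    x <- matrix(rnorm(600), 30)
    y <- sample(rep(c("A", "B"), 15))
    tune_hyperparameters(x, y, classifier_spec("linear"), fold_seed = s)$cv_accuracy
  }, 0)
  expect_lt(mean(accs), 0.75)
  expect_gt(mean(accs), 0.3)
})

test_that("permuting trial order within a class leaves accuracy unchanged", {
  ds <- toy_dataset(n_per_class = 5, P = 40, noise = 0.4)
  perm <- structure(ds[c(3, 1, 2, 5, 4, 6:10)], class = "rig_dataset",
                    labels = dataset_labels(ds)[c(3, 1, 2, 5, 4, 6:10)])
  r1 <- online_run(ds, "S", window_spec(10), classifier_spec("linear"),
                   seed = 2, tune = FALSE)
  r2 <- online_run(perm, "S", window_spec(10), classifier_spec("linear"),
                   seed = 2, tune = FALSE)
  expect_equal(r1$mean_accuracy, r2$mean_accuracy)
})

test_that("linear-kernel decisions are scale-equivariant with rescaled box constraint", {
  ds <- toy_dataset(n_per_class = 5, P = 30, noise = 0.6)
  scaled <- structure(lapply(ds, function(tr) {
    tr$signals$S <- tr$signals$S * 10
    tr
  }), class = "rig_dataset", labels = dataset_labels(ds))
  r1 <- online_run(ds, "S", window_spec(10),
                   classifier_spec("linear", box_constraint = 1),
                   seed = 3, tune = FALSE)
  r2 <- online_run(scaled, "S", window_spec(10),
                   classifier_spec("linear", box_constraint = 1 / 100),
                   seed = 3, tune = FALSE)
  expect_equal(r1$predicted, r2$predicted)
})

test_that("accuracy summary matches a hand-computed prediction table", {
  run <- structure(list(
    sensor_id = "S", window = window_spec(4), spec = classifier_spec(),
    true = c("A", "A", "B", "B"),
    predicted = rbind(c("A", "A", "B"), c("A", "B", "A"),
                      c("B", "B", "B"), c("B", "B", "A")),
    correct = NULL), class = "online_run")
  run$correct <- run$predicted == matrix(run$true, 4, 3)
  run$repeat_accuracy <- rowMeans(run$correct)
  run$window_accuracy <- colMeans(run$correct)
  run$mean_accuracy <- mean(run$repeat_accuracy)
  run$sd_accuracy <- sd(run$repeat_accuracy)
  sm <- accuracy_summary(run)
  # repeats: 2/3, 2/3, 3/3, 2/3 -> mean 9/12; windows: 4/4, 3/4, 2/4
  expect_equal(sm$mean, 0.75)
  expect_equal(sm$sd, sd(c(2 / 3, 2 / 3, 1, 2 / 3)))
  expect_equal(sm$curve$accuracy, c(1, 0.75, 0.5))

  # degenerate all-correct / half-correct cases
  run$correct[] <- TRUE
  run$repeat_accuracy <- rowMeans(run$correct)
  run$window_accuracy <- colMeans(run$correct)
  run$mean_accuracy <- mean(run$repeat_accuracy)
  run$sd_accuracy <- sd(run$repeat_accuracy)
  expect_equal(accuracy_summary(run)$mean, 1)
  expect_equal(accuracy_summary(run)$sd, 0)
})

test_that("window sweep tabulates one row per sensor and size", {
  ds <- toy_dataset(n_per_class = 4, P = 60, noise = 0.3)
  sw <- window_sweep(ds, "S", window_ms = c(100, 300),
                     spec = classifier_spec("linear"), seed = 9)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$n, c(10L, 30L))  # 100 Hz toy rate
  expect_true(all(sw$mean_accuracy >= 0 & sw$mean_accuracy <= 1))
})
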