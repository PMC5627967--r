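test_that("trial CSVs round-trip through write and read", {
  tr <- simulate_trial(quick_config(duration = 0.5), seed = 6)
  path <- file.path(tempdir(), "t.csv")
  write_trial_csv(tr, path)
  back <- read_trial_csv(path)
  expect_equal(names(back$signals), names(tr$signals))
  for (id in names(tr$signals)) {
    expect_lt(max(abs(back$signals[[id]] - tr$signals[[id]])), 1e-9)
  }
  expect_lt(max(abs(back$time - tr$time)), 5e-7)  # time printed at 6 decimals
  header <- readLines(path, n = 1)
  expect_match(header, "^time_s,R1,F2,F3$")
})

test_that("malformed trial CSVs raise parse errors", {
  p <- file.path(tempdir(), "bad.csv")
  writeLines(c("R1,F2", "0.1,0.2"), p)
  expect_error(read_trial_csv(p), "header")
  writeLines(c("time_s,R1", "0.000000,0.5", "0.001667,abc"), p)
  expect_error(read_trial_csv(p))
})

test_that("datasets round-trip through a directory with manifest", {
  ds <- generate_dataset(quick_config(duration = 0.5), 2, c(0, 3),
                         master_seed = 9)
  dir <- file.path(tempdir(), "ds_rt")
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(dir, pattern = "\\.csv$"), 4)
  back <- read_dataset(dir)
  expect_equal(dataset_labels(back), dataset_labels(ds))
  expect_lt(max(abs(back[[3]]$signals$F3 - ds[[3]]$signals$F3)), 1e-9)
  # the reloaded dataset feeds the analysis path unchanged
  rep_out <- class_separation_report(back, c("R1", "F3"))
  expect_equal(nrow(rep_out$summary), 2)
})

test_that("experiment configs read from YAML and JSON", {
  y <- file.path(tempdir(), "cfg.yaml")
  writeLines(c("scenario: rigid_vs_fabric", "trials_per_condition: 3",
               "master_seed: 5", "apparatus:", "  duration: 1.0"), y)
  cfg <- read_experiment_config(y)
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$trials_per_condition, 3)
  expect_equal(cfg$apparatus$duration, 1.0)

  j <- file.path(tempdir(), "cfg.json")
  writeLines('{"scenario": "online_250ms", "master_seed": 7}', j)
  expect_equal(read_experiment_config(j)$scenario, "online_250ms")

  expect_error(experiment_config("nonsense"))
})

test_that("a reduced scenario runs end-to-end, reproducibly, and writes artifacts", {
  out1 <- file.path(tempdir(), "runA")
  out2 <- file.path(tempdir(), "runB")
  cfg <- function(out) experiment_config(
    "rigid_vs_fabric", trials_per_condition = 2, master_seed = 31,
    out_dir = out, apparatus = list(duration = 1.0))
  r1 <- run_experiment(cfg(out1))
  r2 <- run_experiment(cfg(out2))
  expect_s3_class(r1, "run_report")
  expect_true(file.exists(file.path(out1, "report.json")))
  expect_true(file.exists(file.path(out1, "summary.csv")))
  expect_setequal(unique(r1$tables$summary$sensor), c("R1", "F2", "F3", "R2", "R3"))
  # identical seed, identical numbers
  expect_equal(r1$tables$summary$separation, r2$tables$summary$separation)
  expect_equal(readLines(file.path(out1, "summary.csv")),
               readLines(file.path(out2, "summary.csv")))
})

test_that("weight-sweep and online scenarios run at reduced size", {
  out <- file.path(tempdir(), "sweep_smoke")
  r <- run_experiment(experiment_config(
    "weight_sweep", trials_per_condition = 2, master_seed = 13,
    apparatus = list(duration = 1.0)))
  # every load compared against the unloaded baseline, three sensors
  expect_equal(nrow(r$tables$summary), 3 * 6)
  expect_true(all(r$tables$summary$condition_a == "load0"))

  r2 <- run_experiment(experiment_config(
    "online_250ms", trials_per_condition = 2, master_seed = 13,
    apparatus = list(duration = 1.0)))
  expect_equal(r2$tables$summary$sensor, c("R1", "F2", "F3"))
  expect_true(all(r2$tables$summary$mean_accuracy >= 0 &
                    r2$tables$summary$mean_accuracy <= 1))
  files <- write_report(r2, out)
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "summary.csv")))
})
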