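#' Experiment configuration
#'
#' Declarative description of one end-to-end scenario: which study to run,
#' apparatus overrides, trial count and the master seed every random draw
#' descends from.
#'
#' Scenarios:
#' \describe{
#'   \item{rigid_vs_fabric}{jersey vs rigid-extension datasets, 0 N vs 3 N,
#'     similarity separation per sensor.}
#'   \item{weight_sweep}{jersey, tip loads 0 and 0.5-3 N in 0.5 N steps,
#'     separation of each load against the unloaded baseline.}
#'   \item{material_sweep}{rigid, denim, jersey, roma; separation tables per
#'     material.}
#'   \item{window_sweep}{jersey dataset, accuracy vs window size per sensor.}
#'   \item{online_250ms}{jersey dataset, online classification at a fixed
#'     250 ms window per sensor.}
#' }
#'
#' @param scenario Scenario name (see Details).
#' @param trials_per_condition Trials per condition.
#' @param master_seed Integer master seed.
#' @param out_dir Output directory for artifacts (`NULL`: no files written).
#' @param apparatus Optional named list of overrides: `duration`,
#'   `sample_rate`, `noise_sd`, plus any [pendulum_spec()] or
#'   [fabric_spec()] argument.
#' @param window_ms Window sizes (ms) for the sweep scenario.
#' @param kernel Classifier kernel for classification scenarios.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(scenario = c("rigid_vs_fabric", "weight_sweep",
                                           "material_sweep", "window_sweep",
                                           "online_250ms"),
                              trials_per_condition = 10, master_seed = 1L,
                              out_dir = NULL, apparatus = list(),
                              window_ms = c(50, 150, 250, 500, 1000, 1500),
                              kernel = "gaussian") {
  scenario <- match.arg(scenario)
  stopifnot(trials_per_condition >= 2, length(master_seed) == 1)
  structure(list(scenario = scenario,
                 trials_per_condition = trials_per_condition,
                 master_seed = as.integer(master_seed %% 2^31),
                 out_dir = out_dir, apparatus = apparatus,
                 window_ms = window_ms, kernel = kernel),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' Field names mirror the [experiment_config()] arguments.
#'
#' @param path Config file (`.yaml`/`.yml`/`.json`).
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(experiment_config, raw)
}

# Build an apparatus_config for one material/load from config overrides.
.build_apparatus <- function(ov, material, tip_load) {
  pargs <- ov[intersect(names(ov), names(formals(pendulum_spec)))]
  pargs$tip_load <- tip_load
  fargs <- ov[intersect(names(ov), setdiff(names(formals(fabric_spec)), "material"))]
  fargs$material <- material
  pend <- do.call(pendulum_spec, pargs)
  fab <- do.call(fabric_spec, fargs)
  sensors <- default_sensors(pend, fab,
                             noise_sd = if (is.null(ov$noise_sd)) 0.01 else ov$noise_sd)
  apparatus_config(pend, fab, sensors,
                   sample_rate = if (is.null(ov$sample_rate)) 600 else ov$sample_rate,
                   duration = if (is.null(ov$duration)) 10 else ov$duration)
}

# Simulate one labelled dataset for a material over a set of tip loads.
.scenario_dataset <- function(config, material, loads, seed_ix) {
  app <- .build_apparatus(config$apparatus, material, 0)
  generate_dataset(app, trials_per_condition = config$trials_per_condition,
                   conditions = loads,
                   master_seed = child_seed(config$master_seed, seed_ix))
}

#' Run one experiment scenario end-to-end
#'
#' Simulates the datasets the scenario calls for, runs the similarity and/or
#' classification analyses, and (when `out_dir` is set) writes every
#' intermediate: trial CSVs with manifests, tidy score/summary CSVs and a
#' JSON report. Idempotent for a fixed master seed.
#'
#' @param config An [experiment_config()].
#' @return Object of class `run_report`: list with `config`, `tables` (named
#'   list of tibbles), `files` (paths written), `elapsed_s`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- proc.time()[["elapsed"]]
  tables <- list()
  files <- character()
  out <- config$out_dir
  emit_dataset <- function(ds, name) {
    if (!is.null(out)) {
      files <<- c(files, write_dataset(ds, file.path(out, name)))
    }
    ds
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("experiment stage '", name, "' failed (scenario=",
           config$scenario, "): ", conditionMessage(e), call. = FALSE)
    })
  }
  cspec <- classifier_spec(kernel = config$kernel)

  if (config$scenario == "rigid_vs_fabric") {
    fab <- stage("simulate", .scenario_dataset(config, "jersey", c(0, 3), 1L))
    rig <- stage("simulate", .scenario_dataset(config, "rigid", c(0, 3), 2L))
    emit_dataset(fab, "jersey"); emit_dataset(rig, "rigid")
    rep_f <- stage("analyze", class_separation_report(fab, c("R1", "F2", "F3")))
    rep_r <- stage("analyze", class_separation_report(rig, c("R1", "R2", "R3")))
    rep_f$summary$material <- "jersey"; rep_r$summary$material <- "rigid"
    rep_f$scores$material <- "jersey"; rep_r$scores$material <- "rigid"
    tables$summary <- rbind(rep_f$summary, rep_r$summary)
    tables$scores <- rbind(rep_f$scores, rep_r$scores)
  } else if (config$scenario == "weight_sweep") {
    loads <- c(0, seq(0.5, 3, by = 0.5))
    ds <- stage("simulate", .scenario_dataset(config, "jersey", loads, 1L))
    emit_dataset(ds, "jersey_weights")
    base <- dataset_labels(ds)[1]
    rep <- stage("analyze", class_separation_report(ds, c("R1", "F2", "F3")))
    tables$summary <- rep$summary[rep$summary$condition_a == base |
                                    rep$summary$condition_b == base, ]
    tables$scores <- rep$scores
  } else if (config$scenario == "material_sweep") {
    mats <- c("rigid", "denim", "jersey", "roma")
    rows <- list()
    for (mi in seq_along(mats)) {
      ds <- stage("simulate", .scenario_dataset(config, mats[mi], c(0, 3), mi))
      emit_dataset(ds, mats[mi])
      ids <- vapply(ds[[1]]$config$sensors, function(s) s$id, "")
      rep <- stage("analyze", class_separation_report(ds, ids))
      rep$summary$material <- mats[mi]
      rows[[mi]] <- rep$summary
    }
    tables$summary <- do.call(rbind, rows)
  } else if (config$scenario == "window_sweep") {
    ds <- stage("simulate", .scenario_dataset(config, "jersey", c(0, 3), 1L))
    emit_dataset(ds, "jersey")
    tables$sweep <- stage("classify",
                          window_sweep(ds, c("R1", "F2", "F3"), config$window_ms,
                                       cspec, seed = child_seed(config$master_seed, 9L)))
  } else if (config$scenario == "online_250ms") {
    ds <- stage("simulate", .scenario_dataset(config, "jersey", c(0, 3), 1L))
    emit_dataset(ds, "jersey")
    rate <- ds[[1]]$config$sample_rate
    rows <- list(); curves <- list()
    for (sid in c("R1", "F2", "F3")) {
      run <- stage("classify",
                   online_run(ds, sid, window_spec(round(rate * 0.25), rate),
                              cspec, seed = child_seed(config$master_seed, 11L)))
      sm <- accuracy_summary(run)
      rows[[sid]] <- tibble::tibble(sensor = sid, window_ms = 250,
                                    mean_accuracy = sm$mean, sd_accuracy = sm$sd)
      sm$curve$sensor <- sid
      curves[[sid]] <- sm$curve
    }
    tables$summary <- do.call(rbind, rows)
    tables$curve <- do.call(rbind, curves)
  }

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      p <- file.path(out, paste0(nm, ".csv"))
      utils::write.csv(tables[[nm]], p, row.names = FALSE)
      files <- c(files, p)
    }
  }
  report <- structure(list(config = config, tables = tables, files = files,
                           elapsed_s = proc.time()[["elapsed"]] - t0),
                      class = "run_report")
  if (!is.null(out)) {
    rp <- file.path(out, "report.json")
    jsonlite::write_json(
      list(scenario = config$scenario, master_seed = config$master_seed,
           trials_per_condition = config$trials_per_condition,
           version = as.character(utils::packageVersion("fabsense")),
           files = files, elapsed_s = report$elapsed_s,
           tables = lapply(tables, function(tb) as.data.frame(tb))),
      rp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report$files <- c(files, rp)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$config$scenario, "| seed", x$config$master_seed,
      "|", length(x$files), "files |", round(x$elapsed_s, 1), "s\n")
  for (nm in names(x$tables)) {
    cat("--", nm, ":", nrow(x$tables[[nm]]), "rows\n")
  }
  invisible(x)
}

#' Write a run report's tables and metadata to a directory
#'
#' @param report A [run_experiment()] result.
#' @param dir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (nm in names(report$tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(report$tables[[nm]], p, row.names = FALSE)
    written <- c(written, p)
  }
  rp <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(scenario = report$config$scenario,
         master_seed = report$config$master_seed,
         elapsed_s = report$elapsed_s, files = written),
    rp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(written, rp))
}
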