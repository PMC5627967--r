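#' Write a trial to CSV
#'
#' One file per trial: header `time_s,<sensor ids>`, one row per sample,
#' time in seconds with 6 decimals, accelerations in standard gravities
#' written at full precision (round-trips to well below 1e-9). Dot-decimal
#' is enforced regardless of locale.
#'
#' @param trial A `rig_trial`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  ids <- names(trial$signals)
  cols <- c(list(sprintf("%.6f", trial$time)),
            lapply(trial$signals, function(s) sprintf("%.12g", s)))
  lines <- c(paste(c("time_s", ids), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trial CSV written by [write_trial_csv()]
#'
#' @param path File path.
#' @return List with `time` (numeric seconds) and `signals` (named list of
#'   numeric vectors, one per sensor column).
#' @export
read_trial_csv <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "time_s") {
    stop("malformed trial CSV header in ", path,
         " (expected 'time_s,<sensors>' at line 1)", call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "numeric")
  if (any(!stats::complete.cases(df))) {
    stop("non-numeric or missing values in ", path, " at line ",
         which(!stats::complete.cases(df))[1] + 1, call. = FALSE)
  }
  sig <- as.list(df[-1])
  list(time = df[[1]], signals = sig)
}

#' Write a dataset to a directory of trial CSVs plus a JSON manifest
#'
#' Filenames follow `<condition>_<trial##>.csv`; the manifest records files,
#' labels, seeds and a config snapshot so the dataset is self-describing.
#'
#' @param dataset A `rig_dataset`.
#' @param dir Output directory (created if needed).
#' @return Manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- dataset_labels(dataset)
  counter <- stats::ave(seq_along(labels), labels, FUN = seq_along)
  files <- sprintf("%s_trial%02d.csv", labels, counter)
  for (i in seq_along(dataset)) {
    write_trial_csv(dataset[[i]], file.path(dir, files[i]))
  }
  cfg <- dataset[[1]]$config
  manifest <- list(
    files = files, labels = labels,
    seeds = vapply(dataset, function(t) t$seed, 0L),
    master_seed = attr(dataset, "master_seed"),
    sample_rate = cfg$sample_rate, duration = cfg$duration,
    sensors = vapply(cfg$sensors, function(s) s$id, ""),
    config = list(pendulum = unclass(cfg$pendulum),
                  fabric = unclass(cfg$fabric)))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read a dataset directory back into signal form
#'
#' @param dir Directory written by [write_dataset()].
#' @return A list of trial records (each with `label`, `time`, `signals`)
#'   carrying the class `rig_dataset` attributes, usable by the analysis and
#'   classification functions.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  trials <- lapply(seq_along(manifest$files), function(i) {
    tr <- read_trial_csv(file.path(dir, manifest$files[i]))
    tr$label <- manifest$labels[i]
    tr$config <- list(sample_rate = manifest$sample_rate,
                      duration = manifest$duration)
    tr
  })
  structure(trials, class = "rig_dataset", labels = manifest$labels,
            master_seed = manifest$master_seed)
}
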