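#' Simulate one recorded trial
#'
#' Releases the pendulum from (jittered) rest at the release angle, integrates
#' the rig for the configured duration, and samples every sensor at the
#' configured rate through the virtual-accelerometer chain (gravity
#' projection, noise, quantization). Sensors on the rigid pendulum — and all
#' sensors when the appendage material is `"rigid"` — are rigid points at
#' their arc radius; fabric sensors attach to the nearest chain node and
#' read along that segment's tangential axis.
#'
#' @param config An [apparatus_config()].
#' @param seed Integer trial seed; drives release jitter and sensor noise.
#'   Results are bit-identical for identical seed and config.
#' @param noise Set `FALSE` to disable both jitter and sensor noise
#'   (deterministic physics, used by the physics checks).
#' @param chain_init Initial fabric shape, `"hanging"` or `"aligned"`; see
#'   [integrate_rig()].
#' @return An object of class `rig_trial`: list with `label` (condition
#'   string, e.g. `"load3"`), `signals` (named list of numeric sample vectors
#'   in standard gravities), `time` (seconds), `config`, `seed`,
#'   `release_angle`.
#' @examples
#' tr <- simulate_trial(apparatus_config(duration = 0.5), seed = 1)
#' lengths(tr$signals)
#' @export
simulate_trial <- function(config, seed = 1L, noise = TRUE,
                           chain_init = "hanging") {
  stopifnot(inherits(config, "apparatus_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed %% 2^31))

  pend <- config$pendulum
  jitter <- if (noise && pend$release_jitter_sd > 0) {
    stats::rnorm(1, 0, pend$release_jitter_sd)
  } else 0
  release <- min(max(pend$release_angle + jitter, 1e-6), pi)
  rig <- integrate_rig(config, release_angle = release,
                       chain_init = chain_init)

  n <- length(rig$time)
  L <- pend$length
  tvp <- cbind(cos(rig$theta), sin(rig$theta))
  uvp <- cbind(sin(rig$theta), -cos(rig$theta))

  # cumulative node kinematics along the chain (N x 2 per node)
  node_acc <- NULL
  if (rig$has_chain) {
    K <- config$fabric$segment_count
    seg_len <- config$fabric$taut_length / K
    node_acc <- vector("list", K)
    a_run <- L * (rig$thetaacc * tvp - rig$thetadot^2 * uvp)
    for (i in seq_len(K)) {
      tvi <- cbind(cos(rig$phi[, i]), sin(rig$phi[, i]))
      uvi <- cbind(sin(rig$phi[, i]), -cos(rig$phi[, i]))
      a_run <- a_run + seg_len * (rig$phiacc[, i] * tvi - rig$phidot[, i]^2 * uvi)
      node_acc[[i]] <- a_run
    }
  }

  signals <- list()
  for (s in config$sensors) {
    if (s$arc_position <= L + 1e-9 || !rig$has_chain) {
      d <- s$arc_position
      acc <- d * (rig$thetaacc * tvp - rig$thetadot^2 * uvp)
      ang <- rig$theta
    } else {
      K <- config$fabric$segment_count
      seg_len <- config$fabric$taut_length / K
      node <- min(max(round((s$arc_position - L) / seg_len), 1L), K)
      acc <- node_acc[[node]]
      ang <- rig$phi[, node]
    }
    signals[[s$id]] <- virtual_accelerometer(acc, ang, s,
                                             gravity = pend$gravity,
                                             noise = noise)
  }

  structure(list(label = paste0("load", format(pend$tip_load)),
                 signals = signals, time = rig$time, config = config,
                 seed = as.integer(seed %% 2^31), release_angle = release),
            class = "rig_trial")
}

#' @export
print.rig_trial <- function(x, ...) {
  cat("<rig_trial>", x$label, "|", length(x$signals), "sensors x",
      length(x$time), "samples @", x$config$sample_rate, "Hz | seed",
      x$seed, "\n")
  invisible(x)
}

#' Generate a labelled dataset of trials
#'
#' Runs [simulate_trial()] for every condition (tip load) the stated number
#' of times, with per-trial child seeds derived deterministically from the
#' master seed. Trials share the release instant t = 0 by construction, so
#' the dataset is time-synchronised; noise and release jitter are independent
#' across trials.
#'
#' @param config An [apparatus_config()]; its pendulum's `tip_load` is
#'   overridden per condition.
#' @param trials_per_condition Trials per tip-load condition (>= 2: a single
#'   trial leaves cluster statistics undefined).
#' @param conditions Numeric vector of tip loads in newtons.
#' @param master_seed Integer master seed.
#' @param noise Passed to [simulate_trial()].
#' @return An object of class `rig_dataset`: list of `rig_trial`s with
#'   attributes `labels` (per-trial condition strings) and `master_seed`.
#' @examples
#' ds <- generate_dataset(apparatus_config(duration = 0.5),
#'                        trials_per_condition = 2, conditions = c(0, 3),
#'                        master_seed = 42)
#' dataset_labels(ds)
#' @export
generate_dataset <- function(config, trials_per_condition = 10,
                             conditions = c(0, 3), master_seed = 1L,
                             noise = TRUE) {
  if (trials_per_condition < 2) {
    stop("trials_per_condition must be >= 2 (cluster statistics undefined ",
         "for a single trial)", call. = FALSE)
  }
  trials <- list()
  k <- 0L
  for (ci in seq_along(conditions)) {
    pend <- config$pendulum
    pend$tip_load <- conditions[ci]
    cfg_c <- config
    cfg_c$pendulum <- pend
    for (t in seq_len(trials_per_condition)) {
      k <- k + 1L
      child <- child_seed(master_seed, ci, t)
      trials[[k]] <- simulate_trial(cfg_c, seed = child, noise = noise)
    }
  }
  structure(trials, class = "rig_dataset",
            labels = vapply(trials, function(x) x$label, ""),
            master_seed = as.integer(master_seed %% 2^31))
}

#' Deterministic child seed derivation
#'
#' Mixes a master seed with stream indices into a 31-bit child seed, so every
#' random draw in a pipeline traces back to one master seed.
#'
#' @param master_seed Integer.
#' @param ... Integer stream indices.
#' @return Integer in `[0, 2^31)`.
#' @export
child_seed <- function(master_seed, ...) {
  x <- as.double(master_seed %% 2147483647)
  for (ix in c(...)) {
    x <- (x * 1103515245 + 12345 + as.double(ix) * 2654435761) %% 2147483647
  }
  as.integer(x)
}

#' Condition labels of a dataset
#' @param dataset A `rig_dataset`.
#' @return Character vector, one label per trial.
#' @export
dataset_labels <- function(dataset) attr(dataset, "labels")

#' Extract one sensor's signals from a dataset
#'
#' @param dataset A `rig_dataset`.
#' @param sensor_id Sensor label, e.g. `"F3"`.
#' @param label Optional condition label filter.
#' @return List of numeric sample vectors.
#' @export
dataset_signals <- function(dataset, sensor_id, label = NULL) {
  keep <- if (is.null(label)) seq_along(dataset) else which(dataset_labels(dataset) == label)
  if (length(keep) == 0) stop("no trials with label ", label, call. = FALSE)
  out <- lapply(dataset[keep], function(tr) {
    if (is.null(tr$signals[[sensor_id]])) {
      stop("sensor ", sensor_id, " absent from dataset", call. = FALSE)
    }
    tr$signals[[sensor_id]]
  })
  out
}
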