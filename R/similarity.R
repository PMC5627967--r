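#' Stack same-class signals into a cluster matrix
#'
#' Columns are the individual trial signals of one sensor under one
#' condition; with the default 600 Hz x 10 s x 10 trials this is the
#' 6000 x 10 cluster matrix whose column mean is the class prototype.
#'
#' @param signals List (or matrix) of equal-length numeric signals, one per
#'   trial, in trial order.
#' @param label Optional condition label.
#' @param sensor_id Optional sensor label.
#' @return Numeric matrix of class `cluster_matrix` (P x M) with attributes
#'   `label` and `sensor_id`.
#' @examples
#' build_cluster(list(c(0, 0, 0), c(2, 4, 6)))
#' @export
build_cluster <- function(signals, label = NULL, sensor_id = NULL) {
  if (is.matrix(signals)) signals <- lapply(seq_len(ncol(signals)), function(j) signals[, j])
  if (length(signals) < 2) {
    stop("a cluster needs at least 2 signals", call. = FALSE)
  }
  lens <- lengths(signals)
  if (length(unique(lens)) != 1) {
    stop("ragged signal lengths: ", paste(unique(lens), collapse = ", "),
         call. = FALSE)
  }
  m <- do.call(cbind, signals)
  structure(m, class = c("cluster_matrix", class(m)),
            label = label, sensor_id = sensor_id)
}

#' Cluster model: the column mean prototype
#'
#' @param cluster A [build_cluster()] matrix.
#' @return Numeric vector of length P (class `cluster_model`), the
#'   arithmetic mean across trials at each time step.
#' @export
cluster_mean <- function(cluster) {
  stopifnot(inherits(cluster, "cluster_matrix"))
  structure(rowMeans(cluster), class = "cluster_model",
            label = attr(cluster, "label"), sensor_id = attr(cluster, "sensor_id"))
}

#' Euclidean similarity score between a model and a probe signal
#'
#' The (dis)similarity `s` is the Euclidean distance between the class
#' prototype and a probe: small values mean the probe belongs to the cluster.
#'
#' @param model Numeric vector (a [cluster_mean()] or any signal).
#' @param probe Numeric vector of the same length.
#' @return Nonnegative scalar distance.
#' @examples
#' similarity(c(0, 0, 0), c(1, 2, 2)) # 3
#' @export
similarity <- function(model, probe) {
  model <- as.numeric(model); probe <- as.numeric(probe)
  if (length(model) != length(probe)) {
    stop("model and probe lengths differ (", length(model), " vs ",
         length(probe), ")", call. = FALSE)
  }
  sqrt(sum((model - probe)^2))
}

#' Min-max normalize a collection of similarity scores
#'
#' Maps raw distances onto `[0, 1]` over the range of the collection; the
#' smallest raw score maps to 0 and the largest to 1. Ranks are preserved.
#' A degenerate collection (all scores equal) normalizes to all zeros with a
#' warning.
#'
#' @param raw Numeric vector of nonnegative raw scores.
#' @return Numeric vector in `[0, 1]` of the same length.
#' @examples
#' normalize_scores(c(2, 4, 6)) # 0, 0.5, 1
#' @export
normalize_scores <- function(raw) {
  stopifnot(is.numeric(raw), all(raw >= 0))
  rng <- range(raw)
  if (diff(rng) == 0) {
    warning("all raw scores equal; normalized scores set to 0")
    return(rep(0, length(raw)))
  }
  (raw - rng[1]) / diff(rng)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA of scalar observations grouped by
#' condition: `F = MS_between / MS_within` with an upper-tail F p-value.
#' Zero within-group variance with unequal group means yields `F = Inf`,
#' `p = 0`.
#'
#' @param groups List of numeric vectors, one per group (each of length
#'   >= 2).
#' @return List of class `anova_result` with `F`, `df_between`, `df_within`,
#'   `p`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4))) # F = 1.5 on (1, 4) df
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  df_b <- nlevels(g) - 1L
  df_w <- length(values) - nlevels(g)
  ssw <- sum(tapply(values, g, function(v) sum((v - mean(v))^2)))
  means <- tapply(values, g, mean)
  if (ssw == 0) {
    equal <- max(means) - min(means) == 0
    res <- list(F = if (equal) 0 else Inf, df_between = df_b,
                df_within = df_w, p = if (equal) 1 else 0)
  } else {
    ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
    res <- list(F = unname(ow$statistic), df_between = df_b,
                df_within = df_w, p = unname(ow$p.value))
  }
  structure(res, class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Class-separation report for one dataset
#'
#' For each sensor and each pair of condition labels, quantifies how far
#' apart the two motion classes sit relative to their own spread:
#' \itemize{
#'   \item between-class scores: each trial of class B scored against the
#'     full class-A prototype, and vice versa;
#'   \item in-class scores: each trial scored against its own class
#'     prototype with the trial itself left out (avoiding self-inclusion
#'     bias);
#'   \item all scores of one condition-pair comparison — every sensor in the
#'     report together — min-max normalized jointly, the shared axis on which
#'     per-sensor box plots of class contrast are drawn; a sensor's
#'     `separation` is the mean normalized between-class score, its class
#'     contrast on that shared axis (in-class scores anchor the low end of
#'     the normalization);
#'   \item a one-way ANOVA grouping one scalar per trial — its raw distance
#'     to the pooled grand-mean prototype of both classes — by condition.
#' }
#'
#' @param dataset A `rig_dataset` (or any list of trials with `signals` and
#'   labels retrievable via [dataset_labels()]).
#' @param sensors Character vector of sensor ids to analyse.
#' @param conditions Optional subset of condition labels (default: all, in
#'   first-appearance order).
#' @return List with `scores` (tibble: sensor, condition_a, condition_b,
#'   trial, class, type in `between`/`within`, raw, normalized), `summary`
#'   (tibble: sensor, condition_a, condition_b, separation, F, df_between,
#'   df_within, p).
#' @export
class_separation_report <- function(dataset, sensors, conditions = NULL) {
  labels <- dataset_labels(dataset)
  if (is.null(conditions)) conditions <- unique(labels)
  if (length(conditions) < 2) stop("need at least 2 conditions", call. = FALSE)
  if (min(table(factor(labels, levels = conditions))) < 2) {
    stop("need at least 2 trials per condition", call. = FALSE)
  }
  loo_score <- function(sigs) {
    m <- do.call(cbind, sigs)
    tot <- rowSums(m)
    vapply(seq_len(ncol(m)), function(j) {
      similarity((tot - m[, j]) / (ncol(m) - 1), m[, j])
    }, 0)
  }
  pairs <- utils::combn(conditions, 2, simplify = FALSE)
  score_rows <- list()
  summary_rows <- list()
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    pair_tabs <- list()
    pair_aov <- list()
    for (sid in sensors) {
      sa <- dataset_signals(dataset, sid, a)
      sb <- dataset_signals(dataset, sid, b)
      model_a <- rowMeans(do.call(cbind, sa))
      model_b <- rowMeans(do.call(cbind, sb))
      between <- c(vapply(sb, function(s) similarity(model_a, s), 0),
                   vapply(sa, function(s) similarity(model_b, s), 0))
      within <- c(loo_score(sa), loo_score(sb))
      pair_tabs[[sid]] <- tibble::tibble(
        sensor = sid, condition_a = a, condition_b = b,
        trial = c(seq_along(sb), seq_along(sa), seq_along(sa), seq_along(sb)),
        class = c(rep(b, length(sb)), rep(a, length(sa)),
                  rep(a, length(sa)), rep(b, length(sb))),
        type = rep(c("between", "within"), c(length(between), length(within))),
        raw = c(between, within))
      grand <- rowMeans(do.call(cbind, c(sa, sb)))
      pair_aov[[sid]] <- one_way_anova(list(
        vapply(sa, function(s) similarity(grand, s), 0),
        vapply(sb, function(s) similarity(grand, s), 0)))
    }
    pair_tab <- do.call(rbind, pair_tabs)
    pair_tab$normalized <- normalize_scores(pair_tab$raw)
    score_rows[[length(score_rows) + 1]] <- pair_tab
    for (sid in sensors) {
      rows <- pair_tab$sensor == sid
      aov_res <- pair_aov[[sid]]
      summary_rows[[length(summary_rows) + 1]] <- tibble::tibble(
        sensor = sid, condition_a = a, condition_b = b,
        separation = mean(pair_tab$normalized[rows & pair_tab$type == "between"]),
        F = aov_res$F, df_between = aov_res$df_between,
        df_within = aov_res$df_within, p = aov_res$p)
    }
  }
  list(scores = do.call(rbind, score_rows),
       summary = do.call(rbind, summary_rows))
}

#' Compare class contrast across fabric materials on a common scale
#'
#' Scores each material's dataset at one sensor (between-class and
#' leave-one-out in-class Euclidean distances, as in
#' [class_separation_report()]), then min-max normalizes all materials'
#' scores jointly so their separations are directly comparable — the shared
#' axis of a multi-material box-plot figure.
#'
#' @param datasets Named list of `rig_dataset`s, one per material, each with
#'   exactly two condition labels.
#' @param sensor_id Sensor to compare at (default the fabric tip).
#' @return List with `scores` (tibble: material, type, raw, normalized) and
#'   `summary` (tibble: material, separation, F, p from the per-material
#'   grand-mean ANOVA).
#' @export
material_separation <- function(datasets, sensor_id = "F3") {
  stopifnot(is.list(datasets), length(datasets) >= 2, !is.null(names(datasets)))
  rows <- list()
  aovs <- list()
  for (mat in names(datasets)) {
    rep_m <- class_separation_report(datasets[[mat]], sensor_id)
    tab <- rep_m$scores
    rows[[mat]] <- tibble::tibble(material = mat, type = tab$type, raw = tab$raw)
    aovs[[mat]] <- rep_m$summary
  }
  scores <- do.call(rbind, rows)
  scores$normalized <- normalize_scores(scores$raw)
  summary <- do.call(rbind, lapply(names(datasets), function(mat) {
    sel <- scores$material == mat & scores$type == "between"
    tibble::tibble(material = mat,
                   separation = mean(scores$normalized[sel]),
                   F = aovs[[mat]]$F, p = aovs[[mat]]$p)
  }))
  list(scores = scores, summary = summary)
}
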