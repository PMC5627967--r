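# Shared fixtures. Short-duration configs keep unit tests fast; full-length
# 600 Hz x 10 s runs live in the acceptance suite.

quick_config <- function(material = "jersey", tip_load = 0, duration = 2,
                         noise_sd = 0.01, ...) {
  pend <- pendulum_spec(tip_load = tip_load, ...)
  fab <- fabric_spec(material)
  apparatus_config(pend, fab, default_sensors(pend, fab, noise_sd = noise_sd),
                   duration = duration)
}

# Brute-force one-way ANOVA from sums of squares, the oracle the fast path
# is checked against.
anova_oracle <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- length(groups) - 1
  df_w <- length(all_v) - length(groups)
  F <- (ssb / df_b) / (ssw / df_w)
  list(F = F, p = stats::pf(F, df_b, df_w, lower.tail = FALSE))
}

# Constant-signal toy dataset with two perfectly separable classes.
toy_dataset <- function(n_per_class = 4, P = 40, a = 1, b = -1, noise = 0) {
  trials <- list()
  labels <- character()
  set.seed(99)
  for (i in seq_len(n_per_class)) {
    trials[[length(trials) + 1]] <- list(
      label = "A", signals = list(S = rep(a, P) + rnorm(P, 0, noise)),
      config = list(sample_rate = 100))
    labels <- c(labels, "A")
  }
  for (i in seq_len(n_per_class)) {
    trials[[length(trials) + 1]] <- list(
      label = "B", signals = list(S = rep(b, P) + rnorm(P, 0, noise)),
      config = list(sample_rate = 100))
    labels <- c(labels, "B")
  }
  structure(trials, class = "rig_dataset", labels = labels, master_seed = 99L)
}
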