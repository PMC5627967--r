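test_that("cluster construction stacks signals in trial order and rejects bad input", {
  m <- build_cluster(list(c(0, 0, 0), c(2, 4, 6)), label = "load0", sensor_id = "F3")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m[, 2], c(2, 4, 6))
  expect_equal(attr(m, "label"), "load0")

  same <- build_cluster(list(1:5 / 2, 1:5 / 2))
  expect_equal(same[, 1], same[, 2])

  expect_error(build_cluster(list(rnorm(6000))), "at least 2")
  expect_error(build_cluster(list(rnorm(6000), rnorm(5999))), "ragged")
})

test_that("cluster mean equals the element-wise brute-force average", {
  expect_equal(as.numeric(cluster_mean(build_cluster(list(c(0, 0, 0), c(2, 4, 6))))),
               c(1, 2, 3))

  set.seed(11)
  sig <- replicate(10, rnorm(600), simplify = FALSE)
  psi <- cluster_mean(build_cluster(sig))
  slow <- vapply(seq_len(600), function(t) {
    mean(vapply(sig, `[`, 0, t))
  }, 0)
  expect_equal(as.numeric(psi), slow)

  # identical columns reproduce the column
  c0 <- rnorm(50)
  expect_equal(as.numeric(cluster_mean(build_cluster(list(c0, c0, c0)))), c0)
})

test_that("cluster mean minimizes total squared distance to the cluster columns", {
  set.seed(21)
  cl <- build_cluster(replicate(8, rnorm(200), simplify = FALSE))
  psi <- as.numeric(cluster_mean(cl))
  obj <- function(v) sum(apply(cl, 2, function(col) sum((col - v)^2)))
  base <- obj(psi)
  for (k in 1:20) {
    expect_gt(obj(psi + rnorm(200, 0, 0.05)), base)
  }
})

test_that("similarity is the Euclidean distance and a metric", {
  expect_equal(similarity(c(0, 0, 0), c(1, 2, 2)), 3)
  expect_equal(similarity(1:4, 1:4), 0)
  expect_error(similarity(1:4, 1:5), "lengths differ")

  set.seed(31)
  a <- rnorm(6000); b <- rnorm(6000)
  expect_equal(similarity(a, b), sqrt(sum((a - b)^2)))
  expect_equal(similarity(a, b), similarity(b, a))

  # triangle inequality and identity of indiscernibles on random triples
  for (k in 1:25) {
    x <- rnorm(40); y <- rnorm(40); z <- rnorm(40)
    expect_lte(similarity(x, z), similarity(x, y) + similarity(y, z) + 1e-12)
    expect_gte(similarity(x, y), 0)
  }
})

test_that("min-max normalization maps the range onto [0,1] and preserves ranks", {
  expect_equal(normalize_scores(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(out <- normalize_scores(c(5, 5)), "all raw scores equal")
  expect_equal(out, c(0, 0))

  set.seed(41)
  for (k in 1:10) {
    raw <- abs(rnorm(12, 5, 2))
    nn <- normalize_scores(raw)
    expect_equal(order(nn), order(raw))
    expect_equal(range(nn), c(0, 1))
    # invariance to common affine rescaling
    expect_equal(normalize_scores(3.7 * raw + 11), nn)
  }
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  r <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(r$F, 1.5, tolerance = 1e-12)
  expect_equal(r$df_between, 1L)
  expect_equal(r$df_within, 4L)

  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)

  degen <- one_way_anova(list(c(0, 0), c(1, 1)))
  expect_equal(degen$F, Inf)
  expect_equal(degen$p, 0)

  set.seed(51)
  for (k in 1:20) {
    groups <- lapply(sample(2:5, sample(2:4, 1), replace = TRUE) + 1,
                     function(n) rnorm(n, sample(0:2, 1)))
    got <- one_way_anova(groups)
    want <- anova_oracle(groups)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("with two groups F equals the square of the pooled-variance t statistic", {
  set.seed(61)
  for (k in 1:10) {
    g1 <- rnorm(sample(3:8, 1)); g2 <- rnorm(sample(3:8, 1), 0.5)
    F <- one_way_anova(list(g1, g2))$F
    t <- stats::t.test(g1, g2, var.equal = TRUE)$statistic
    expect_equal(F, unname(t)^2, tolerance = 1e-10)
  }
})

test_that("identical-condition clusters yield zero between-class scores", {
  set.seed(71)
  one <- rnorm(100)   # every trial of both "classes" is the same record
  base <- list(one, one, one)
  trials <- c(lapply(base, function(s) list(label = "A", signals = list(S = s))),
              lapply(base, function(s) list(label = "B", signals = list(S = s))))
  ds <- structure(trials, class = "rig_dataset",
                  labels = rep(c("A", "B"), each = 3))
  rep_out <- suppressWarnings(class_separation_report(ds, "S"))
  bet <- rep_out$scores$raw[rep_out$scores$type == "between"]
  expect_true(all(bet < 1e-12))
})

test_that("separation report has the expected tidy shape", {
  ds <- toy_dataset(n_per_class = 4, noise = 0.1)
  rep_out <- class_separation_report(ds, "S")
  expect_named(rep_out, c("scores", "summary"))
  expect_setequal(unique(rep_out$scores$type), c("between", "within"))
  expect_equal(nrow(rep_out$scores), 16)  # 8 between + 8 within
  expect_equal(nrow(rep_out$summary), 1)
  expect_true(all(rep_out$scores$normalized >= 0 & rep_out$scores$normalized <= 1))
  # separable toy: between-class contrast dominates in-class spread
  expect_gt(rep_out$summary$separation, 0.5)
})
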