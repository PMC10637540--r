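test_that("normalized cluster means stay in [0, 1] and match a single cluster", {
  set.seed(71)
  clin <- data.frame(age = runif(40, 20, 80), BMI = runif(40, 18, 35))
  one <- cluster_means_normalized(rep(1, 40), clin)
  norm_mean <- function(x) mean((x - min(x)) / (max(x) - min(x)))
  expect_equal(one[1, "age"], norm_mean(clin$age))
  two <- cluster_means_normalized(rep(1:2, 20), clin)
  expect_true(all(two >= 0 & two <= 1))
})

test_that("the youngest planted class has the lowest normalized age mean", {
  ds <- generate_dataset(synthetic_config(n_subjects = 200L,
                                          pulses_per_subject = 2L, seed = 72))
  m <- cluster_means_normalized(ds$labels, ds$clinical["age"])
  expect_identical(unname(which.min(m[, "age"])), 1L)
})

test_that("identical covariates across clusters yield no rejections", {
  clin <- data.frame(age = rep(c(30, 40, 50, 60), 10))
  labels <- rep(1:2, each = 20)  # same value pattern in both clusters
  rep_ <- kruskal_then_welch(labels, clin)
  expect_false(any(rep_$kruskal$significant))
  expect_identical(nrow(rep_$welch), 0L)
})

test_that("well-separated clusters are detected by both test stages", {
  for (seed in 1:10) {
    set.seed(seed)
    clin <- data.frame(age = c(rnorm(100, 40, 5), rnorm(100, 60, 5)))
    rep_ <- kruskal_then_welch(rep(1:2, each = 100), clin)
    expect_true(rep_$kruskal$significant[1], label = paste("kw seed", seed))
    expect_true(all(rep_$welch$significant), label = paste("welch seed", seed))
  }
})

test_that("Welch entries exist only for Kruskal-Wallis-significant variables", {
  set.seed(73)
  clin <- data.frame(different = c(rnorm(60, 0, 1), rnorm(60, 5, 1)),
                     same = rnorm(120))
  rep_ <- kruskal_then_welch(rep(1:2, each = 60), clin)
  sig_vars <- rep_$kruskal$variable[rep_$kruskal$significant]
  expect_identical(sort(unique(rep_$welch$variable)), sort(sig_vars))
  expect_false("same" %in% rep_$welch$variable)
})

test_that("quantile distance has the closed-form shift behaviour", {
  set.seed(74)
  x <- rnorm(80)
  expect_identical(quantile_distance(x, x), 0)
  expect_equal(quantile_distance(rep(0, 10), rep(1, 15)), 1)
  expect_equal(quantile_distance(rep(0, 10), rep(1, 15), type = "rms"), 1)
  expect_equal(quantile_distance(x + 2.5, x), 2.5)
  expect_equal(quantile_distance(x + 2.5, x, type = "rms"), 2.5)
  expect_error(quantile_distance(numeric(0), x), "nonempty")
})

test_that("the weighted distance reproduces the worked point-mass example", {
  labels <- rep(1:2, each = 10)
  values <- rep(c(0, 1), each = 10)
  rep_ <- csm_weighted_distance(labels, values, normalize = FALSE)
  expect_equal(rep_$d, 0.25)
  expect_equal(sum(rep_$weights), 1)
  expect_identical(rep_$dist, t(rep_$dist))
  expect_true(all(diag(rep_$dist) == 0))
})

test_that("identical cluster distributions give d = 0", {
  set.seed(75)
  values <- rep(rnorm(20), 3)
  labels <- rep(1:3, each = 20)
  expect_equal(csm_weighted_distance(labels, values)$d, 0)
  expect_error(csm_weighted_distance(rep(1, 10), rnorm(10)), "at least 2")
})

test_that("d is positively homogeneous without normalization", {
  set.seed(76)
  values <- c(rnorm(30, 0), rnorm(30, 3))
  labels <- rep(1:2, each = 30)
  d1 <- csm_weighted_distance(labels, values, normalize = FALSE)$d
  d7 <- csm_weighted_distance(labels, 7 * values, normalize = FALSE)$d
  expect_equal(d7, 7 * d1)
})

test_that("d is invariant to relabeling and to duplicating every cluster", {
  set.seed(77)
  values <- c(rnorm(25, 0), rnorm(25, 2), rnorm(25, 4))
  labels <- rep(1:3, each = 25)
  d0 <- csm_weighted_distance(labels, values)$d
  relab <- c(3L, 1L, 2L)[labels]
  expect_equal(csm_weighted_distance(relab, values)$d, d0)
  # duplication shifts the interpolated empirical quantiles only slightly
  expect_equal(csm_weighted_distance(rep(labels, 2), rep(values, 2))$d, d0,
               tolerance = 0.01)
})

test_that("planted labels separate age better than random labels", {
  wins <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    ds <- generate_dataset(synthetic_config(n_subjects = 60L,
                                            pulses_per_subject = 3L,
                                            seed = 700 + r))
    d_planted <- csm_weighted_distance(ds$labels, ds$clinical$age)$d
    set.seed(800 + r)
    d_random <- csm_weighted_distance(sample(ds$labels), ds$clinical$age)$d
    wins <- wins + (d_planted > d_random)
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("shape-linked covariates outrank noise covariates under planted labels", {
  ds <- generate_dataset(synthetic_config(n_subjects = 150L,
                                          pulses_per_subject = 3L, seed = 42))
  d_of <- function(v) csm_weighted_distance(ds$labels, ds$clinical[[v]])$d
  expect_gt(d_of("age"), d_of("BMI"))
  expect_gt(d_of("age"), d_of("BPM"))
  expect_gt(d_of("TT"), d_of("BMI"))
  expect_gt(d_of("TT"), d_of("BPM"))
})
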