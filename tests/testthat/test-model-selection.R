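test_that("coincident far-apart clusters score silhouette 1", {
  x <- rbind(matrix(0, 10, 2), matrix(10, 10, 2))
  labels <- rep(1:2, each = 10)
  expect_identical(silhouette_score(labels, x), 1)
})

test_that("per-sample silhouette follows (b - a) / max(a, b)", {
  # three points: d(1,2) = 1 within cluster 1, d(1,3) = 2 to cluster 2
  D <- matrix(c(0, 1, 2,
                1, 0, 2.5,
                2, 2.5, 0), 3, 3, byrow = TRUE)
  s <- silhouette_score(c(1, 1, 2), D, per_sample = TRUE)
  expect_equal(s[1], (2 - 1) / 2)      # a = 1, b = 2 -> 0.5
  expect_identical(s[3], 0)            # singleton convention
})

test_that("silhouette matches the brute-force formula and cluster::silhouette", {
  set.seed(61)
  x <- matrix(rnorm(400), 200, 2)
  labels <- sample(1:3, 200, replace = TRUE)
  D <- as.matrix(dist(x))
  expect_equal(silhouette_score(labels, D), mean(bf_silhouette(labels, D)),
               tolerance = 1e-9)
  ref <- mean(cluster::silhouette(labels, dmatrix = D)[, "sil_width"])
  expect_equal(silhouette_score(labels, D), ref, tolerance = 1e-9)
})

test_that("silhouette is undefined for a single cluster", {
  expect_error(silhouette_score(rep(1, 10), matrix(0, 10, 10)), "single")
})

test_that("prediction strength is 1 for k = 1 and for recoverable blobs", {
  set.seed(62)
  any_data <- matrix(rnorm(40), 20, 2)
  expect_identical(prediction_strength(any_data[1:10, ], any_data[11:20, ], 1),
                   1)
  b <- make_blobs(n_per = 30, seed = 63)
  odd <- seq(1, 60, 2)
  expect_identical(prediction_strength(b$x[odd, ], b$x[-odd, ], 2), 1)
})

test_that("all-singleton test clusters give prediction strength 1", {
  set.seed(64)
  x <- matrix(rnorm(24), 12, 2)
  expect_identical(prediction_strength(x[1:6, ], x[7:12, ], 6), 1)
  expect_error(prediction_strength(x[1:6, ], x[7:12, ], 7), "partition")
})

test_that("prediction strength works on a precomputed dissimilarity", {
  b <- make_blobs(n_per = 20, seed = 65)
  D <- as.matrix(dist(b$x))
  expect_identical(prediction_strength(seq(1, 40, 2), seq(2, 40, 2), 2,
                                       d = D), 1)
})

test_that("scan_k produces coherent curves on planted feature blobs", {
  set.seed(66)
  x <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
             matrix(rnorm(40, 5, 0.3), 20, 2),
             matrix(rnorm(40, c(10, 0), 0.3), 20, 2))
  curves <- scan_k(x, k_range = 1:8, compute_ps = TRUE, seed = 1)
  expect_identical(curves$k, 1:8)
  expect_true(is.na(curves$silhouette[1]))
  expect_identical(curves$k[which.max(curves$silhouette)], 3L)
  expect_true(all(diff(curves$inertia) <= 1e-9))
  expect_identical(curves$ps[1], 1)
  expect_true(all(curves$ps >= 0 & curves$ps <= 1, na.rm = TRUE))
  expect_identical(choose_k(curves), 3L)
})

test_that("inertia vanishes when every point is its own medoid", {
  x <- matrix(rnorm(16), 8, 2)
  curves <- scan_k(x, k_range = c(1, 4, 8))
  expect_equal(curves$inertia[3], 0)
})

test_that("choose_k applies the threshold, argmax and fallback rules", {
  curves <- data.frame(k = 1:5,
                       silhouette = c(NA, 0.9, 0.6, 0.5, 0.4),
                       inertia = c(10, 4, 3, 2.5, 2.2),
                       ps = c(1, 1, 1, 1, 1))
  expect_identical(choose_k(curves), 2L)
  curves$ps <- c(1, 0.2, 0.9, 0.9, 0.9)  # best silhouette k gated out
  expect_identical(choose_k(curves), 3L)
  curves$ps <- c(1, 0.1, 0.1, 0.1, 0.1)
  expect_warning(k <- choose_k(curves), "falling back")
  expect_identical(k, 2L)
  curves$ps <- NA_real_  # ps unavailable: pure silhouette argmax
  expect_identical(choose_k(curves), 2L)
})

test_that("silhouette ties break toward the inertia elbow", {
  curves <- data.frame(k = 1:6,
                       silhouette = c(NA, 0.7, 0.7, 0.4, 0.3, 0.2),
                       inertia = c(10, 6, 2, 1.8, 1.7, 1.6),
                       ps = 1)
  expect_identical(choose_k(curves), 3L)  # elbow at k = 3
})
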