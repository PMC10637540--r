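test_that("two well-separated blobs are recovered exactly", {
  b <- make_blobs(seed = 51)
  fit <- kmedoids_fit(b$x, k = 2)
  expect_identical(mclust::adjustedRandIndex(fit$labels, b$labels), 1)
  expect_identical(sort(unique(fit$labels)), 1:2)
})

test_that("k = n gives singleton clusters with zero objective", {
  x <- matrix(rnorm(12), 12, 1)
  fit <- kmedoids_fit(x, k = 12)
  expect_identical(sort(fit$medoid_idx), 1:12)
  expect_identical(fit$objective, 0)
})

test_that("the k = 1 medoid is the brute-force argmin of total dissimilarity", {
  set.seed(52)
  D <- as.matrix(dist(matrix(rnorm(40), 20, 2)))
  fit <- kmedoids_fit(D, k = 1, diss = TRUE)
  expect_identical(fit$medoid_idx, unname(which.min(colSums(D))))
  expect_equal(fit$objective, min(colSums(D)))
})

test_that("the PAM objective never increases across swaps", {
  set.seed(53)
  for (rep_ in 1:5) {
    x <- matrix(runif(60), 30, 2)
    fit <- kmedoids_fit(x, k = 4)
    expect_true(all(diff(fit$objective_trace) <= 1e-12))
  }
})

test_that("each medoid belongs to its own cluster and the objective is exact", {
  set.seed(54)
  D <- as.matrix(dist(matrix(rnorm(50), 25, 2)))
  fit <- kmedoids_fit(D, k = 3, diss = TRUE)
  expect_identical(fit$labels[fit$medoid_idx], 1:3)
  recomputed <- sum(D[cbind(seq_len(25), fit$medoid_idx[fit$labels])])
  expect_equal(fit$objective, recomputed)
})

test_that("the partition is invariant under input permutation", {
  b <- make_blobs(n_per = 15, seed = 55)
  set.seed(56)
  perm <- sample(nrow(b$x))
  f1 <- kmedoids_fit(b$x, k = 2)
  f2 <- kmedoids_fit(b$x[perm, , drop = FALSE], k = 2)
  expect_identical(mclust::adjustedRandIndex(f1$labels[perm], f2$labels), 1)
})

test_that("PAM agrees with an independent implementation on separated data", {
  b <- make_blobs(seed = 57)
  ours <- kmedoids_fit(b$x, k = 2)
  ref <- cluster::pam(b$x, k = 2)
  expect_identical(mclust::adjustedRandIndex(ours$labels, ref$clustering), 1)
})

test_that("invalid clustering inputs are rejected", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(kmedoids_fit(x, k = 6), "exceeds")
  bad <- matrix(1:9, 3, 3)
  expect_error(kmedoids_fit(bad, k = 2, diss = TRUE), "symmetric|diagonal")
})

test_that("template assignment maps the templates to themselves", {
  tp <- template_pulses()
  cross <- cross_ddtw(tp, tp)
  fit <- assign_fixed_medoids(cross)
  expect_identical(fit$labels, 1:4)
  expect_identical(fit$objective, 0)
  expect_identical(fit$mode, "template")
  expect_identical(fit$medoid_idx, 1:4)
})

test_that("noise-free class pulses all land on their own template", {
  set.seed(58)
  tpl <- make_class_templates()
  pulses <- do.call(rbind, lapply(1:4, function(cls) {
    t(vapply(seq_len(6), function(i) {
      normalize_pulse(generate_pulse(tpl[[cls]], runif(1, 20, 80),
                                     noise_sd = 0))
    }, numeric(100)))
  }))
  fit <- assign_fixed_medoids(cross_ddtw(pulses, template_pulses()))
  expect_identical(fit$labels, rep(1:4, each = 6))
})

test_that("inertia follows the mean and sum conventions", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  fit <- kmedoids_fit(D, k = 1, diss = TRUE)
  expect_equal(cluster_inertia(fit, D, type = "mean"), 0.5)
  expect_equal(cluster_inertia(fit, D, type = "sum"), 1)
  full <- kmedoids_fit(D, k = 2, diss = TRUE)
  expect_identical(cluster_inertia(full, D), 0)
})

test_that("inertia equals a brute-force recomputation from labels", {
  set.seed(59)
  D <- as.matrix(dist(matrix(rnorm(60), 30, 2)))
  fit <- kmedoids_fit(D, k = 3, diss = TRUE)
  manual <- mean(vapply(seq_len(30), function(i) {
    D[i, fit$medoid_idx[fit$labels[i]]]^2
  }, numeric(1)))
  expect_equal(cluster_inertia(fit, D), manual)
})
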