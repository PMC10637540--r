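test_that("architecture widths match the design", {
  m <- build_autoencoder(ae_config())
  expect_identical(m$dims$flatten, 416L)
  expect_identical(m$dims$latent, 8L)
  expect_identical(m$dims$pool3, 13L)
  expect_identical(m$dims$dilated, 26L)
  expect_identical(m$dims$crop, 25L)
  expect_identical(m$dims$flatten_dec, 3200L)
})

test_that("invalid configurations fail at construction, naming the layer", {
  expect_error(build_autoencoder(ae_config(input_length = 90)), "cropping")
  expect_error(build_autoencoder(ae_config(kernel_size = 5)), "convolution")
})

test_that("encoder emits 8-vectors and the decoder 100-sample (0,1) output", {
  m <- build_autoencoder(ae_config(seed = 2))
  pulses <- random_pulses(5, seed = 41)
  z <- encode_pulses(m, pulses)
  expect_identical(dim(z), c(5L, 8L))
  y <- reconstruct_pulses(m, pulses)
  expect_identical(dim(y), c(5L, 100L))
  expect_true(all(y > 0 & y < 1))
  expect_error(encode_pulses(m, matrix(0.5, 2, 50)), "length 100")
})

test_that("inference is deterministic", {
  m <- build_autoencoder(ae_config(seed = 2))
  p <- random_pulses(1, seed = 42)
  expect_identical(encode_pulses(m, p), encode_pulses(m, p))
  expect_identical(predict(m, p, type = "latent"), encode_pulses(m, p))
})

test_that("analytic gradients match finite differences", {
  m <- build_autoencoder(ae_config(seed = 3))
  set.seed(43)
  X <- matrix(runif(2 * 100), 2, 100)
  fwd <- dvpclust:::ae_forward(m, X, keep_cache = TRUE)
  g <- dvpclust:::ae_backward(m, X, fwd)
  eps <- 1e-6
  set.seed(44)
  for (nm in names(m$weights)) {
    idx <- sample(length(m$weights[[nm]]), 1)
    m2 <- m
    m2$weights[[nm]][idx] <- m2$weights[[nm]][idx] + eps
    up <- dvpclust:::ae_loss(m2, X, dvpclust:::ae_forward(m2, X)$Yhat)
    m2$weights[[nm]][idx] <- m2$weights[[nm]][idx] - 2 * eps
    dn <- dvpclust:::ae_loss(m2, X, dvpclust:::ae_forward(m2, X)$Yhat)
    num <- (up - dn) / (2 * eps)
    expect_lt(abs(num - g[[nm]][idx]) /
                max(abs(num), abs(g[[nm]][idx]), 1e-10), 1e-4,
              label = paste("gradient of", nm))
  }
})

test_that("short training lowers reconstruction error and keeps the early-stopping contract", {
  pulses <- template_pulses()[rep(1:4, each = 15), ]
  pulses <- pulses + matrix(rnorm(length(pulses), 0, 0.003), nrow(pulses))
  pulses <- pmin(pmax(pulses, 0), 1)
  tr <- pulses[1:40, ]
  va <- pulses[41:60, ]
  m0 <- build_autoencoder(ae_config(max_epochs = 8, seed = 6))
  before <- mean((reconstruct_pulses(m0, va) - va)^2)
  m <- train_autoencoder(m0, tr, va)
  expect_true(m$trained)
  expect_lt(m$val_mse, before)
  expect_lte(m$val_mse, m$history$val_mse[1])
  expect_lte(nrow(m$history), 8)
})

test_that("training is reproducible for a fixed seed", {
  pulses <- template_pulses()[rep(1:2, each = 10), ]
  tr <- pulses[1:14, ]
  va <- pulses[15:20, ]
  cfg <- ae_config(max_epochs = 3, seed = 12)
  h1 <- train_autoencoder(build_autoencoder(cfg), tr, va)$history
  h2 <- train_autoencoder(build_autoencoder(cfg), tr, va)$history
  expect_identical(h1, h2)
})

test_that("latent codes separate marked-notch from notch-free classes", {
  # train briefly on the two extreme classes; their codes should be linearly
  # separable (weak property at small scale)
  set.seed(45)
  mk <- function(cls, n) {
    tpl <- make_class_templates()[[cls]]
    t(vapply(seq_len(n), function(i) {
      normalize_pulse(generate_pulse(tpl, runif(1, 20, 80), n_samples = 100))
    }, numeric(100)))
  }
  tr <- rbind(mk(1, 30), mk(4, 30))
  va <- rbind(mk(1, 8), mk(4, 8))
  m <- train_autoencoder(build_autoencoder(ae_config(max_epochs = 30,
                                                     seed = 7)), tr, va)
  z <- encode_pulses(m, va)
  y <- rep(c(0, 1), each = 8)
  fit <- suppressWarnings(glm(y ~ z, family = binomial()))
  expect_true(all((predict(fit, type = "response") > 0.5) == (y == 1)))
})
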