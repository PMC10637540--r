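# 1-D convolutional autoencoder for 100-sample pulses, implemented directly
# on base-R matrix algebra: im2col convolutions (kernel 3, same padding),
# factor-2 max pooling (ceiling mode), nearest-neighbour upsampling, a
# stride-2 transposed convolution realized as zero-dilation + convolution,
# and dense layers. Trained with Adam on squared reconstruction error plus an
# L2 weight penalty; correctness of every backward pass is pinned by
# finite-difference gradient checks in the test suite.
#
# Encoder: 100 -> [conv(32) + pool/2] x3 -> flatten(416) -> dense(latent).
# Decoder: dense(416) -> reshape(13,32) -> transposed conv to 26 -> crop 25
#          -> upsample 50 -> conv(32) -> upsample 100 -> conv(32)
#          -> flatten(3200) -> dense(100, sigmoid).
# Conv layers are ReLU; the bottleneck and the 416-wide dense are linear.

#' Autoencoder configuration
#'
#' @param latent_dim Width of the bottleneck (default 8).
#' @param conv_channels Channels of every convolution (default 32).
#' @param kernel_size Convolution kernel length (default 3, same padding).
#' @param input_length Pulse length (default 100; must be divisible by 4).
#' @param learning_rate Adam step size (default 1e-3).
#' @param l2_lambda L2 weight-penalty coefficient (default 1e-4).
#' @param batch_size Minibatch size (default 32).
#' @param max_epochs Training epoch cap (default 200).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement (default 10).
#' @param seed Seed controlling initialization and epoch shuffling.
#' @return List of class `dvp_ae_config`.
#' @export
ae_config <- function(latent_dim = 8L, conv_channels = 32L, kernel_size = 3L,
                      input_length = 100L, learning_rate = 1e-3,
                      l2_lambda = 1e-4, batch_size = 32L, max_epochs = 200L,
                      patience = 10L, seed = 1L) {
  stopifnot_scalar_count(latent_dim, "latent_dim")
  stopifnot_scalar_count(conv_channels, "conv_channels")
  structure(list(latent_dim = as.integer(latent_dim),
                 conv_channels = as.integer(conv_channels),
                 kernel_size = as.integer(kernel_size),
                 input_length = as.integer(input_length),
                 learning_rate = learning_rate, l2_lambda = l2_lambda,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "dvp_ae_config")
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

slice_mat <- function(A, from, to) {
  d <- dim(A)
  matrix(A[, from:to, , drop = FALSE], d[1L] * (to - from + 1L), d[3L])
}

conv_fwd <- function(A, W, b, activation = "relu") {
  d <- dim(A)  # B, L, Cin
  Apad <- array(0, c(d[1L], d[2L] + 2L, d[3L]))
  Apad[, 2:(d[2L] + 1L), ] <- A
  Xcol <- cbind(slice_mat(Apad, 1L, d[2L]),
                slice_mat(Apad, 2L, d[2L] + 1L),
                slice_mat(Apad, 3L, d[2L] + 2L))
  Z <- Xcol %*% W
  Z <- Z + rep(b, each = nrow(Z))
  out <- if (activation == "relu") relu(Z) else Z
  list(A = array(out, c(d[1L], d[2L], ncol(W))), Z = Z, Xcol = Xcol,
       in_dim = d)
}

conv_bwd <- function(dA_out, cache, W, activation = "relu") {
  d <- cache$in_dim
  L <- d[2L]
  Cout <- ncol(W)
  dZ <- matrix(dA_out, d[1L] * L, Cout)
  if (activation == "relu") dZ <- dZ * (cache$Z > 0)
  dW <- crossprod(cache$Xcol, dZ)
  db <- colSums(dZ)
  dXcol <- dZ %*% t(W)
  Cin <- d[3L]
  dApad <- array(0, c(d[1L], L + 2L, Cin))
  for (k in 0:2) {
    dApad[, (1L + k):(L + k), ] <- dApad[, (1L + k):(L + k), , drop = FALSE] +
      array(dXcol[, (k * Cin + 1L):((k + 1L) * Cin)], c(d[1L], L, Cin))
  }
  list(dA = dApad[, 2:(L + 1L), , drop = FALSE], dW = dW, db = db)
}

pool_fwd <- function(A) {
  d <- dim(A)
  L <- d[2L]
  Lout <- as.integer(ceiling(L / 2))
  odd <- seq(1L, L, 2L)
  A1 <- A[, odd, , drop = FALSE]
  A2 <- array(-Inf, c(d[1L], Lout, d[3L]))
  if (L >= 2L) {
    even <- seq(2L, L, 2L)
    A2[, seq_along(even), ] <- A[, even, , drop = FALSE]
  }
  mask <- A1 >= A2  # ties go to the first element of the window
  list(A = ifelse(mask, A1, A2), mask = mask, in_dim = d)
}

pool_bwd <- function(dA_out, cache) {
  d <- cache$in_dim
  L <- d[2L]
  dA <- array(0, d)
  odd <- seq(1L, L, 2L)
  even <- if (L >= 2L) seq(2L, L, 2L) else integer(0)
  dA[, odd, ] <- dA_out * cache$mask
  if (length(even)) {
    rest <- (dA_out * !cache$mask)[, seq_along(even), , drop = FALSE]
    dA[, even, ] <- rest
  }
  dA
}

upsample_fwd <- function(A) {
  d <- dim(A)
  out <- array(0, c(d[1L], 2L * d[2L], d[3L]))
  out[, seq(1L, 2L * d[2L], 2L), ] <- A
  out[, seq(2L, 2L * d[2L], 2L), ] <- A
  out
}

upsample_bwd <- function(dA_out) {
  L2 <- dim(dA_out)[2L]
  dA_out[, seq(1L, L2, 2L), , drop = FALSE] +
    dA_out[, seq(2L, L2, 2L), , drop = FALSE]
}

dilate_fwd <- function(A) {
  # stride-2 zero insertion: input j lands at output 2j - 1; length doubles.
  d <- dim(A)
  out <- array(0, c(d[1L], 2L * d[2L], d[3L]))
  out[, seq(1L, 2L * d[2L] - 1L, 2L), ] <- A
  out
}

dilate_bwd <- function(dA_out, Lin) {
  dA_out[, seq(1L, 2L * Lin - 1L, 2L), , drop = FALSE]
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

he <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

#' Build the convolutional autoencoder
#'
#' Constructs the model with seeded random weights. The encoder maps a pulse
#' of `input_length` samples through three conv(+ReLU)/halving-pool stages to
#' a flattened width of `ceiling(input_length / 8) * conv_channels` (416 for
#' the defaults) and a linear bottleneck of `latent_dim` units; the decoder
#' mirrors it back through a stride-2 transposed convolution, a cropping
#' layer, two upsample/conv stages and a sigmoid dense reconstruction of
#' `input_length` samples.
#'
#' @param config An `ae_config()`.
#' @return Object of class `dvp_autoencoder` (untrained).
#' @export
#' @examples
#' m <- build_autoencoder(ae_config())
#' m$dims$flatten  # 416
build_autoencoder <- function(config = ae_config()) {
  stopifnot(inherits(config, "dvp_ae_config"))
  L <- config$input_length
  if (L %% 4L != 0L) {
    stop("cropping layer: input_length must be divisible by 4 (got ", L, ")",
         call. = FALSE)
  }
  if (config$kernel_size != 3L) {
    stop("convolution layer: only kernel_size = 3 is implemented",
         call. = FALSE)
  }
  C <- config$conv_channels
  l1 <- L %/% 2L                       # after pool 1
  l2 <- l1 %/% 2L                      # after pool 2
  l3 <- as.integer(ceiling(l2 / 2))    # after pool 3 (ceiling mode)
  flat <- l3 * C
  dims <- list(input = L, pool1 = l1, pool2 = l2, pool3 = l3, flatten = flat,
               latent = config$latent_dim, dilated = 2L * l3,
               crop = l2, up1 = l1, up2 = L, flatten_dec = L * C)
  if (dims$dilated - 1L != dims$crop) {
    stop("cropping layer: transposed-conv output ", dims$dilated,
         " cannot be cropped to ", dims$crop, call. = FALSE)
  }
  weights <- with_seed(config$seed, list(
    W1 = he(3L, C), b1 = numeric(C),
    W2 = he(3L * C, C), b2 = numeric(C),
    W3 = he(3L * C, C), b3 = numeric(C),
    W4 = glorot(flat, config$latent_dim), b4 = numeric(config$latent_dim),
    W5 = glorot(config$latent_dim, flat), b5 = numeric(flat),
    W6 = he(3L * C, C), b6 = numeric(C),
    W7 = he(3L * C, C), b7 = numeric(C),
    W8 = he(3L * C, C), b8 = numeric(C),
    W9 = glorot(L * C, L), b9 = numeric(L)
  ))
  structure(list(config = config, dims = dims, weights = weights,
                 trained = FALSE, history = NULL),
            class = "dvp_autoencoder")
}

# Full forward pass; X is a B x input_length matrix. Returns the
# reconstruction, the latent codes, and (when keep_cache) everything the
# backward pass needs.
ae_forward <- function(model, X, keep_cache = FALSE) {
  w <- model$weights
  d <- model$dims
  B <- nrow(X)
  A0 <- array(X, c(B, d$input, 1L))
  c1 <- conv_fwd(A0, w$W1, w$b1)
  p1 <- pool_fwd(c1$A)
  c2 <- conv_fwd(p1$A, w$W2, w$b2)
  p2 <- pool_fwd(c2$A)
  c3 <- conv_fwd(p2$A, w$W3, w$b3)
  p3 <- pool_fwd(c3$A)
  flat <- matrix(p3$A, B, d$flatten)
  latent <- flat %*% w$W4 + rep(w$b4, each = B)
  up <- latent %*% w$W5 + rep(w$b5, each = B)
  dec0 <- array(up, c(B, d$pool3, dim(c3$A)[3L]))
  dil <- dilate_fwd(dec0)
  c6 <- conv_fwd(dil, w$W6, w$b6)
  crop <- c6$A[, seq_len(d$crop), , drop = FALSE]
  u1 <- upsample_fwd(crop)
  c7 <- conv_fwd(u1, w$W7, w$b7)
  u2 <- upsample_fwd(c7$A)
  c8 <- conv_fwd(u2, w$W8, w$b8)
  flat_dec <- matrix(c8$A, B, d$flatten_dec)
  Zout <- flat_dec %*% w$W9 + rep(w$b9, each = B)
  Yhat <- sigmoid(Zout)
  out <- list(Yhat = Yhat, latent = latent)
  if (keep_cache) {
    out$cache <- list(A0 = A0, c1 = c1, p1 = p1, c2 = c2, p2 = p2, c3 = c3,
                      p3 = p3, flat = flat, latent = latent, up = up,
                      dil = dil, c6 = c6, crop_in_len = dim(c6$A)[2L],
                      u1 = u1, c7 = c7, u2 = u2, c8 = c8,
                      flat_dec = flat_dec, Zout = Zout, B = B)
  }
  out
}

# Gradients of mean squared reconstruction error + l2 * sum(W^2) w.r.t. all
# weights, for one batch.
ae_backward <- function(model, X, fwd) {
  w <- model$weights
  d <- model$dims
  cc <- fwd$cache
  B <- cc$B
  Yhat <- fwd$Yhat
  dZout <- (2 / (B * d$input)) * (Yhat - X) * Yhat * (1 - Yhat)
  g <- list()
  g$W9 <- crossprod(cc$flat_dec, dZout)
  g$b9 <- colSums(dZout)
  dflat_dec <- dZout %*% t(w$W9)
  C <- dim(cc$c8$A)[3L]
  dc8 <- array(dflat_dec, c(B, d$up2, C))
  bk8 <- conv_bwd(dc8, cc$c8, w$W8)
  g$W8 <- bk8$dW; g$b8 <- bk8$db
  du2 <- upsample_bwd(bk8$dA)
  bk7 <- conv_bwd(du2, cc$c7, w$W7)
  g$W7 <- bk7$dW; g$b7 <- bk7$db
  du1 <- upsample_bwd(bk7$dA)
  dcrop_full <- array(0, c(B, cc$crop_in_len, C))
  dcrop_full[, seq_len(d$crop), ] <- du1
  bk6 <- conv_bwd(dcrop_full, cc$c6, w$W6)
  g$W6 <- bk6$dW; g$b6 <- bk6$db
  ddec0 <- dilate_bwd(bk6$dA, d$pool3)
  dup <- matrix(ddec0, B, d$flatten)
  g$W5 <- crossprod(cc$latent, dup)
  g$b5 <- colSums(dup)
  dlatent <- dup %*% t(w$W5)
  g$W4 <- crossprod(cc$flat, dlatent)
  g$b4 <- colSums(dlatent)
  dflat <- dlatent %*% t(w$W4)
  dp3 <- array(dflat, c(B, d$pool3, C))
  dc3 <- pool_bwd(dp3, cc$p3)
  bk3 <- conv_bwd(dc3, cc$c3, w$W3)
  g$W3 <- bk3$dW; g$b3 <- bk3$db
  dc2 <- pool_bwd(bk3$dA, cc$p2)
  bk2 <- conv_bwd(dc2, cc$c2, w$W2)
  g$W2 <- bk2$dW; g$b2 <- bk2$db
  dc1 <- pool_bwd(bk2$dA, cc$p1)
  bk1 <- conv_bwd(dc1, cc$c1, w$W1)
  g$W1 <- bk1$dW; g$b1 <- bk1$db
  lambda <- model$config$l2_lambda
  if (lambda > 0) {
    for (nm in names(g)) {
      if (startsWith(nm, "W")) g[[nm]] <- g[[nm]] + 2 * lambda * w[[nm]]
    }
  }
  g
}

ae_loss <- function(model, X, Yhat) {
  mse <- mean((Yhat - X)^2)
  l2 <- sum(vapply(model$weights[grep("^W", names(model$weights))],
                   function(W) sum(W^2), numeric(1)))
  mse + model$config$l2_lambda * l2
}

ae_val_mse <- function(model, X, chunk = 512L) {
  tot <- 0
  for (start in seq(1L, nrow(X), chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(X))
    Yhat <- ae_forward(model, X[idx, , drop = FALSE])$Yhat
    tot <- tot + sum((Yhat - X[idx, , drop = FALSE])^2)
  }
  tot / (nrow(X) * ncol(X))
}

#' Train the autoencoder
#'
#' Minimizes mean squared reconstruction error plus the L2 weight penalty
#' with Adam, shuffled minibatches, and early stopping on the validation
#' reconstruction error: training halts after `patience` epochs without
#' improvement and the best-validation weights are restored. Training is a
#' pure function of the model's config seed and the data. A non-finite loss
#' aborts with diagnostics.
#'
#' @param model A `dvp_autoencoder` from [build_autoencoder()].
#' @param train Matrix of normalized pulses (one per row), the training set.
#' @param val Matrix of normalized pulses, the validation set (disjoint from
#'   `train`).
#' @param verbose Print one line per epoch (default FALSE).
#' @return The trained model: `history` (per-epoch train objective and
#'   validation MSE), `best_epoch`, `val_mse`, and `trained = TRUE`.
#' @export
train_autoencoder <- function(model, train, val, verbose = FALSE) {
  stopifnot(inherits(model, "dvp_autoencoder"))
  train <- as.matrix(train)
  val <- as.matrix(val)
  cfg <- model$config
  if (ncol(train) != cfg$input_length || ncol(val) != cfg$input_length) {
    stop("pulses must have length ", cfg$input_length, call. = FALSE)
  }
  n <- nrow(train)
  w <- model$weights
  mom <- lapply(w, function(x) x * 0)
  vel <- lapply(w, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  best_val <- Inf
  best_w <- w
  best_epoch <- 0L
  wait <- 0L
  hist_train <- hist_val <- numeric(0)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- train[idx, , drop = FALSE]
        fwd <- ae_forward(model, Xb, keep_cache = TRUE)
        loss <- ae_loss(model, Xb, fwd$Yhat)
        if (!is.finite(loss)) {
          stop(sprintf(
            "non-finite training loss at epoch %d, batch starting %d",
            epoch, start), call. = FALSE)
        }
        g <- ae_backward(model, Xb, fwd)
        step <- step + 1L
        corr1 <- 1 - beta1^step
        corr2 <- 1 - beta2^step
        for (nm in names(w)) {
          mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * g[[nm]]
          vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * g[[nm]]^2
          w[[nm]] <- w[[nm]] - cfg$learning_rate * (mom[[nm]] / corr1) /
            (sqrt(vel[[nm]] / corr2) + eps)
        }
        model$weights <- w
        epoch_loss <- epoch_loss + loss
        nb <- nb + 1L
      }
      val_mse <- ae_val_mse(model, val)
      hist_train <- c(hist_train, epoch_loss / nb)
      hist_val <- c(hist_val, val_mse)
      if (verbose) {
        message(sprintf("epoch %3d  train %.6f  val %.6f", epoch,
                        epoch_loss / nb, val_mse))
      }
      if (val_mse < best_val - 1e-12) {
        best_val <- val_mse
        best_w <- w
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  model$weights <- best_w
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_along(hist_train),
                              train_objective = hist_train,
                              val_mse = hist_val)
  model$best_epoch <- best_epoch
  model$val_mse <- best_val
  model
}

#' Encode pulses to latent features
#'
#' Deterministic inference through the trained encoder only.
#'
#' @param model A `dvp_autoencoder`.
#' @param pulses Matrix of normalized pulses (one per row) or a single pulse.
#' @return `n x latent_dim` matrix of latent features.
#' @export
encode_pulses <- function(model, pulses) {
  stopifnot(inherits(model, "dvp_autoencoder"))
  X <- if (is.matrix(pulses)) pulses else matrix(pulses, nrow = 1L)
  if (ncol(X) != model$config$input_length) {
    stop("pulses must have length ", model$config$input_length, call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(X), model$config$latent_dim)
  for (start in seq(1L, nrow(X), 512L)) {
    idx <- start:min(start + 511L, nrow(X))
    out[idx, ] <- ae_forward(model, X[idx, , drop = FALSE])$latent
  }
  out
}

#' Reconstruct pulses through the full autoencoder
#'
#' @param model A `dvp_autoencoder`.
#' @param pulses Matrix of normalized pulses or a single pulse.
#' @return `n x input_length` matrix of reconstructions in (0, 1).
#' @export
reconstruct_pulses <- function(model, pulses) {
  stopifnot(inherits(model, "dvp_autoencoder"))
  X <- if (is.matrix(pulses)) pulses else matrix(pulses, nrow = 1L)
  out <- matrix(NA_real_, nrow(X), model$config$input_length)
  for (start in seq(1L, nrow(X), 512L)) {
    idx <- start:min(start + 511L, nrow(X))
    out[idx, ] <- ae_forward(model, X[idx, , drop = FALSE])$Yhat
  }
  out
}

#' @export
predict.dvp_autoencoder <- function(object, newdata,
                                    type = c("latent", "reconstruction"),
                                    ...) {
  type <- match.arg(type)
  if (type == "latent") encode_pulses(object, newdata)
  else reconstruct_pulses(object, newdata)
}

#' @export
print.dvp_autoencoder <- function(x, ...) {
  d <- x$dims
  cat("1-D convolutional autoencoder",
      if (x$trained) "(trained)" else "(untrained)", "\n")
  cat(sprintf("  encoder: %d -> conv/pool -> %d -> %d -> %d -> flatten %d -> latent %d\n",
              d$input, d$pool1, d$pool2, d$pool3, d$flatten, d$latent))
  cat(sprintf("  decoder: %d -> %d -> tconv %d -> crop %d -> %d -> %d -> dense %d (sigmoid)\n",
              d$latent, d$flatten, d$dilated, d$crop, d$up1, d$up2, d$input))
  if (x$trained) {
    cat(sprintf("  best epoch %d, validation MSE %.6f\n", x$best_epoch,
                x$val_mse))
  }
  invisible(x)
}
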