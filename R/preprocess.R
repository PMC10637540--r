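# Pulse normalization onto the canonical 100-sample [0, 1] grid, z-scoring,
# and the train/validation/test split.

#' Normalize a raw pulse
#'
#' Resamples a raw single-beat pulse by linear interpolation onto `n_out`
#' equally spaced points spanning the pulse duration, then min-max scales the
#' amplitude to \[0, 1\]. Already-normalized pulses pass through unchanged
#' (the operation is idempotent).
#'
#' @param x Numeric vector, length >= 4, finite and non-constant.
#' @param n_out Output grid length (default 100).
#' @return Numeric vector of length `n_out` with min 0 and max 1.
#' @export
#' @examples
#' p <- normalize_pulse(sin(seq(0, pi, length.out = 73)))
#' length(p); range(p)
normalize_pulse <- function(x, n_out = 100L) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("pulse must have at least 4 samples", call. = FALSE)
  if (any(!is.finite(x))) stop("pulse contains non-finite values", call. = FALSE)
  if (max(x) == min(x)) {
    stop("degenerate pulse: constant amplitude cannot be normalized",
         call. = FALSE)
  }
  y <- approx(seq_along(x), x, xout = seq(1, length(x), length.out = n_out),
              method = "linear")$y
  (y - min(y)) / (max(y) - min(y))
}

#' Normalize a set of pulses into a matrix
#'
#' @param pulses List of raw pulses or a matrix with one pulse per row.
#' @param n_out Output grid length (default 100).
#' @return Matrix with one normalized pulse per row.
#' @export
normalize_pulses <- function(pulses, n_out = 100L) {
  pl <- as_pulse_list(pulses)
  t(vapply(pl, normalize_pulse, numeric(n_out), n_out = n_out))
}

#' Z-normalize a pulse
#'
#' Centers to mean zero and scales to unit *population* standard deviation
#' (divisor n). Affine amplitude maps a*x + b with a > 0 are removed exactly.
#'
#' @param x Numeric vector with nonzero variance.
#' @return Numeric vector, mean 0, population sd 1.
#' @export
znormalize_pulse <- function(x) {
  x <- as.numeric(x)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) {
    stop("degenerate pulse: zero variance cannot be z-normalized",
         call. = FALSE)
  }
  (x - m) / s
}

#' Split pulses into train / validation / test partitions
#'
#' Pulse-level uniform random assignment: `test_frac` of all pulses go to the
#' test set, and `val_frac` of the remaining training pool to the validation
#' set. Splitting is per pulse, not per subject, so one subject may contribute
#' to several partitions.
#'
#' @param n_pulses Total number of pulses (>= 10).
#' @param test_frac Fraction of all pulses held out as test (default 0.30).
#' @param val_frac Fraction of the non-test pool used for validation
#'   (default 0.30).
#' @param seed Integer seed; the split is a pure function of
#'   `(n_pulses, fractions, seed)`.
#' @return Factor of length `n_pulses` with levels `train`, `val`, `test`.
#' @export
#' @examples
#' table(split_dataset(1000, seed = 7))
split_dataset <- function(n_pulses, test_frac = 0.30, val_frac = 0.30,
                          seed = 1L) {
  stopifnot_scalar_count(n_pulses, "n_pulses")
  if (n_pulses < 10L) stop("need at least 10 pulses to split", call. = FALSE)
  for (f in c(test_frac, val_frac)) {
    if (!is.numeric(f) || length(f) != 1L || f <= 0 || f >= 1) {
      stop("split fractions must lie strictly in (0, 1)", call. = FALSE)
    }
  }
  n_test <- round(test_frac * n_pulses)
  n_val <- round(val_frac * (n_pulses - n_test))
  with_seed(seed, {
    idx <- sample.int(n_pulses)
    out <- rep("train", n_pulses)
    out[idx[seq_len(n_test)]] <- "test"
    out[idx[n_test + seq_len(n_val)]] <- "val"
    factor(out, levels = c("train", "val", "test"))
  })
}
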