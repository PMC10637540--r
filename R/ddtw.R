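# Derivative dynamic time warping: derivative transform, banded DTW dynamic
# program (C++ kernel), and pairwise dissimilarity matrices.

#' Derivative transform of a series
#'
#' Estimates the local slope at interior points as the average of the
#' left-difference and half the centred two-sample span:
#' `d[i] = ((x[i] - x[i-1]) + (x[i+1] - x[i-1]) / 2) / 2`; the endpoints copy
#' their nearest interior value, so the output has the input's length.
#'
#' @param x Numeric series of length >= 3.
#' @return Numeric vector of slopes, same length as `x`.
#' @export
#' @examples
#' derivative_series(c(0, 1, 2, 3))  # constant slope 1
derivative_series <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to differentiate", call. = FALSE)
  i <- 2:(n - 1L)
  d <- numeric(n)
  d[i] <- ((x[i] - x[i - 1L]) + (x[i + 1L] - x[i - 1L]) / 2) / 2
  d[1L] <- d[2L]
  d[n] <- d[n - 1L]
  d
}

#' Dynamic time warping distance
#'
#' Exact minimal alignment cost between two series under the three-move
#' recurrence with cell cost `|s[i] - t[j]|` (no step weights, no path-length
#' normalization: the raw cumulative cost at the final cell is returned).
#' With a Sakoe-Chiba half-width `w`, only cells with `|i - j| <= w` are
#' reachable; `w = NULL` runs the unconstrained program. DTW is symmetric in
#' its arguments but is not a metric (no triangle inequality).
#'
#' @param s,t Numeric series (nonempty).
#' @param w Band half-width in samples, or `NULL` for unbanded. Must satisfy
#'   `w >= |length(s) - length(t)|` for the end cell to be reachable.
#' @return Nonnegative alignment cost.
#' @export
#' @examples
#' dtw_distance(c(0, 0), c(1, 1))        # 2
#' dtw_distance(1:10, 1:10, w = 0)       # 0
dtw_distance <- function(s, t, w = NULL) {
  s <- as.numeric(s)
  t <- as.numeric(t)
  if (!length(s) || !length(t)) stop("series must be nonempty", call. = FALSE)
  if (is.null(w)) {
    wi <- -1L
  } else {
    wi <- as.integer(w)
    if (wi < abs(length(s) - length(t))) {
      stop("band half-width w = ", wi, " is infeasible for lengths ",
           length(s), " and ", length(t),
           " (need w >= |n - m|)", call. = FALSE)
    }
  }
  dtw_cost_cpp(s, t, wi)
}

#' Derivative DTW distance between two pulses
#'
#' Each pulse is z-normalized (removing affine amplitude maps exactly), then
#' derivative-transformed, and the banded DTW cost of the two slope series is
#' returned. The default band half-width is 20 samples on the 100-sample
#' grid.
#'
#' @param p,q Pulses (non-constant numeric vectors, typically normalized to
#'   100 samples).
#' @param w Sakoe-Chiba half-width (default 20); `NULL` for unbanded.
#' @return Nonnegative dissimilarity; 0 for affinely related pulses.
#' @export
ddtw_distance <- function(p, q, w = 20L) {
  dtw_distance(derivative_series(znormalize_pulse(p)),
               derivative_series(znormalize_pulse(q)), w = w)
}

ddtw_transform <- function(pulses) {
  pl <- as_pulse_list(pulses)
  rows <- lapply(seq_along(pl), function(i) {
    tryCatch(derivative_series(znormalize_pulse(pl[[i]])),
             error = function(e) {
               stop("pulse ", i, ": ", conditionMessage(e), call. = FALSE)
             })
  })
  len <- unique(lengths(rows))
  if (length(len) != 1L) {
    stop("all pulses must share one length for pairwise DDTW; normalize first",
         call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Pairwise DDTW dissimilarity matrix
#'
#' Computes [ddtw_distance()] for every unordered pair of pulses (row-major
#' upper triangle, each pair once) and mirrors the result into a symmetric
#' matrix with a zero diagonal.
#'
#' @param pulses Matrix (one pulse per row) or list of equal-length pulses.
#' @param w Sakoe-Chiba half-width (default 20); `NULL` for unbanded.
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
pairwise_ddtw <- function(pulses, w = 20L) {
  dmat <- ddtw_transform(pulses)
  if (nrow(dmat) < 2L) stop("need at least 2 pulses", call. = FALSE)
  wi <- if (is.null(w)) -1L else as.integer(w)
  pairwise_dtw_cpp(dmat, wi)
}

#' DDTW distances from pulses to reference templates
#'
#' @param pulses Matrix or list of pulses (rows of the output).
#' @param templates Matrix or list of reference pulses (columns).
#' @param w Sakoe-Chiba half-width (default 20); `NULL` for unbanded.
#' @return `length(pulses)` x `length(templates)` matrix of DDTW costs.
#' @export
cross_ddtw <- function(pulses, templates, w = 20L) {
  a <- ddtw_transform(pulses)
  b <- ddtw_transform(templates)
  if (ncol(a) != ncol(b)) {
    stop("pulses and templates must share one grid length", call. = FALSE)
  }
  wi <- if (is.null(w)) -1L else as.integer(w)
  cross_dtw_cpp(a, b, wi)
}
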