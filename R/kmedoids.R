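# K-medoids (PAM) over precomputed dissimilarities or Euclidean feature
# space; free-medoid (baseline) and fixed-template modes; inertia.

# Nearest/second-nearest medoid bookkeeping for a medoid set.
pam_nearest <- function(D, medoids) {
  dm <- D[, medoids, drop = FALSE]
  ord1 <- max.col(-dm, ties.method = "first")
  n <- nrow(dm)
  dn <- dm[cbind(seq_len(n), ord1)]
  if (length(medoids) > 1L) {
    dm2 <- dm
    dm2[cbind(seq_len(n), ord1)] <- Inf
    ds <- dm2[cbind(seq_len(n), max.col(-dm2, ties.method = "first"))]
  } else {
    ds <- rep(Inf, n)
  }
  list(nearest = ord1, dn = dn, ds = ds)
}

# PAM core: greedy BUILD (optionally warm-started) then best-improvement SWAP
# until no swap lowers the total dissimilarity. Deterministic: ties break to
# the lowest index. Returns medoids plus the objective trace (BUILD value and
# the value after each accepted swap).
pam_fit <- function(D, k, init_medoids = NULL) {
  dimnames(D) <- NULL
  n <- nrow(D)
  medoids <- unique(as.integer(init_medoids))
  medoids <- medoids[medoids >= 1L & medoids <= n]
  if (length(medoids) > k) medoids <- medoids[seq_len(k)]
  if (!length(medoids)) medoids <- which.min(colSums(D))
  dn <- do.call(pmin, lapply(medoids, function(m) D[, m]))
  while (length(medoids) < k) {
    cand <- setdiff(seq_len(n), medoids)
    gains <- colSums(pmax(dn - D[, cand, drop = FALSE], 0))
    best <- cand[which.max(gains)]
    medoids <- c(medoids, best)
    dn <- pmin(dn, D[, best])
  }
  trace <- sum(dn)
  repeat {
    st <- pam_nearest(D, medoids)
    cand <- setdiff(seq_len(n), medoids)
    if (!length(cand)) break
    best_delta <- 0
    best_swap <- NULL
    td <- sum(st$dn)
    for (mi in seq_along(medoids)) {
      base <- ifelse(st$nearest == mi, st$ds, st$dn)
      deltas <- colSums(pmin(D[, cand, drop = FALSE], base)) - td
      j <- which.min(deltas)
      if (deltas[j] < best_delta - 1e-12) {
        best_delta <- deltas[j]
        best_swap <- c(mi, cand[j])
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1L]] <- best_swap[2L]
    dn <- do.call(pmin, lapply(medoids, function(m) D[, m]))
    trace <- c(trace, sum(dn))
  }
  medoids <- sort(medoids)
  st <- pam_nearest(D, medoids)
  list(medoids = medoids, labels = st$nearest, objective = sum(st$dn),
       trace = trace)
}

looks_like_diss <- function(x) {
  inherits(x, "dist") ||
    (is.matrix(x) && nrow(x) == ncol(x) && all(diag(x) == 0) &&
       isTRUE(all.equal(x, t(x), tolerance = 1e-8, check.attributes = FALSE)))
}

#' K-medoids (PAM) clustering
#'
#' Partitions samples around medoids — cluster centers that are themselves
#' samples — by greedy BUILD initialization followed by SWAP steps until no
#' single medoid exchange lowers the total dissimilarity. Accepts either a
#' precomputed dissimilarity (a `dist` object or symmetric zero-diagonal
#' matrix) or a feature matrix, in which case Euclidean distances are used.
#' The procedure is deterministic given the input order (ties break to the
#' lowest index); `seed` is accepted for interface symmetry with the
#' stochastic stages.
#'
#' @param x Dissimilarity (`dist`/symmetric matrix) or feature matrix (one
#'   sample per row).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param diss Force interpretation of `x` as dissimilarity (`TRUE`) or
#'   features (`FALSE`); default `NULL` auto-detects.
#' @param seed Unused by the deterministic optimizer; kept in the signature.
#' @param init_medoids Optional warm-start medoid indices.
#' @return Object of class `dvp_kmedoids`: `labels` (1..k per sample),
#'   `medoid_idx` (sample indices), `k`, `mode` (`"baseline"`), `objective`
#'   (total dissimilarity to assigned medoids) and `objective_trace` (value
#'   after BUILD and after each accepted swap; non-increasing).
#' @export
#' @examples
#' x <- matrix(c(rnorm(20, 0), rnorm(20, 10)), ncol = 1)
#' fit <- kmedoids_fit(x, k = 2)
#' table(fit$labels)
kmedoids_fit <- function(x, k, diss = NULL, seed = NULL, init_medoids = NULL) {
  if (is.null(diss)) diss <- looks_like_diss(x)
  if (diss) {
    D <- as_diss_matrix(x, "x")
  } else {
    x <- as.matrix(x)
    D <- as.matrix(dist(x))
  }
  n <- nrow(D)
  stopifnot_scalar_count(k, "k")
  if (k > n) stop("k = ", k, " exceeds the number of samples ", n,
                  call. = FALSE)
  fit <- pam_fit(D, as.integer(k), init_medoids = init_medoids)
  structure(list(labels = fit$labels, medoid_idx = fit$medoids,
                 k = as.integer(k), mode = "baseline",
                 objective = fit$objective, objective_trace = fit$trace,
                 n = n),
            class = "dvp_kmedoids")
}

#' Assign pulses to fixed template medoids
#'
#' Template-mode clustering: the medoids are held fixed (e.g. the four
#' canonical notch-based class shapes) and every pulse is assigned to its
#' nearest template; ties break to the lowest template index. The medoid set
#' is identical before and after.
#'
#' @param cross `n x m` matrix of dissimilarities from each of `n` pulses to
#'   each of `m` template medoids (e.g. from [cross_ddtw()]).
#' @return Object of class `dvp_kmedoids` with `mode = "template"`,
#'   `labels` in 1..m, `medoid_idx = 1:m` (template indices) and `objective`
#'   (total dissimilarity to the assigned template).
#' @export
assign_fixed_medoids <- function(cross) {
  cross <- as.matrix(cross)
  if (!nrow(cross) || !ncol(cross)) {
    stop("need a nonempty pulse-by-template dissimilarity matrix",
         call. = FALSE)
  }
  if (any(!is.finite(cross))) {
    stop("non-finite pulse-to-template dissimilarities", call. = FALSE)
  }
  labels <- max.col(-cross, ties.method = "first")
  dmin <- cross[cbind(seq_len(nrow(cross)), labels)]
  structure(list(labels = labels, medoid_idx = seq_len(ncol(cross)),
                 k = ncol(cross), mode = "template",
                 objective = sum(dmin), objective_trace = sum(dmin),
                 n = nrow(cross)),
            class = "dvp_kmedoids")
}

#' Cluster inertia
#'
#' Squared dissimilarity of each sample to its cluster medoid, reported by
#' default as the mean over samples (comparable across differently scaled
#' dissimilarity spaces); `type = "sum"` gives the raw sum.
#'
#' @param result A `dvp_kmedoids` object.
#' @param d For baseline fits, the `n x n` dissimilarity used for fitting
#'   (or the feature matrix it came from); for template fits, the `n x m`
#'   pulse-to-template matrix.
#' @param type `"mean"` (default) or `"sum"`.
#' @return Nonnegative scalar.
#' @export
cluster_inertia <- function(result, d, type = c("mean", "sum")) {
  type <- match.arg(type)
  stopifnot(inherits(result, "dvp_kmedoids"))
  if (result$mode == "template") {
    d <- as.matrix(d)
    dm <- d[cbind(seq_len(nrow(d)), result$labels)]
  } else {
    if (!looks_like_diss(d)) d <- dist(as.matrix(d))
    D <- as_diss_matrix(d, "d")
    dm <- D[cbind(seq_len(result$n), result$medoid_idx[result$labels])]
  }
  if (type == "mean") mean(dm^2) else sum(dm^2)
}

#' @export
print.dvp_kmedoids <- function(x, ...) {
  cat(sprintf("K-medoids fit (%s mode): k = %d, n = %d\n",
              x$mode, x$k, x$n))
  cat("Cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  cat(sprintf("Objective (total dissimilarity): %.6g\n", x$objective))
  invisible(x)
}

#' @export
summary.dvp_kmedoids <- function(object, ...) {
  sizes <- tabulate(object$labels, object$k)
  out <- list(k = object$k, mode = object$mode, n = object$n, sizes = sizes,
              percent = 100 * sizes / object$n,
              medoid_idx = object$medoid_idx, objective = object$objective,
              n_swaps = length(object$objective_trace) - 1L)
  class(out) <- "summary.dvp_kmedoids"
  out
}

#' @export
print.summary.dvp_kmedoids <- function(x, ...) {
  cat(sprintf("K-medoids (%s), k = %d on n = %d samples; %d swap(s)\n",
              x$mode, x$k, x$n, x$n_swaps))
  tab <- data.frame(cluster = seq_len(x$k), size = x$sizes,
                    percent = round(x$percent, 1), medoid = x$medoid_idx)
  print(tab, row.names = FALSE)
  cat(sprintf("Objective: %.6g\n", x$objective))
  invisible(x)
}
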