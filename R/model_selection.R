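# Cluster-number selection: silhouette, prediction strength, inertia curves
# over a k grid, and the joint selection rule.

#' Mean silhouette score
#'
#' For each sample, `a` is its mean dissimilarity to the other members of its
#' own cluster and `b` the smallest mean dissimilarity to any cluster it does
#' not belong to; its silhouette is `(b - a) / max(a, b)`. Members of
#' singleton clusters score 0 by convention, as do samples with
#' `a = b = 0`. The mean over samples is returned.
#'
#' @param labels Integer cluster labels (at least two distinct clusters).
#' @param d Dissimilarity (`dist` or symmetric matrix) or feature matrix
#'   (Euclidean distances are then used).
#' @param per_sample Return the per-sample scores instead of the mean.
#' @return Mean silhouette in \[-1, 1\] (or the per-sample vector).
#' @export
silhouette_score <- function(labels, d, per_sample = FALSE) {
  if (!looks_like_diss(d)) d <- dist(as.matrix(d))
  D <- as_diss_matrix(d, "d")
  labels <- as.integer(factor(labels))
  n <- length(labels)
  if (n != nrow(D)) stop("labels and dissimilarity sizes differ", call. = FALSE)
  k <- max(labels)
  if (k < 2L) {
    stop("silhouette is undefined for a single cluster", call. = FALSE)
  }
  sizes <- tabulate(labels, k)
  # S[i, c] = total dissimilarity from sample i to cluster c.
  S <- D %*% outer(labels, seq_len(k), `==`)
  a <- S[cbind(seq_len(n), labels)] / pmax(sizes[labels] - 1L, 1L)
  Smean <- sweep(S, 2L, sizes, `/`)
  Smean[cbind(seq_len(n), labels)] <- Inf
  b <- do.call(pmin, lapply(seq_len(k), function(c) Smean[, c]))
  s <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  s[sizes[labels] == 1L] <- 0
  if (per_sample) s else mean(s)
}

# Minimum over own-clusters of the co-membership proportion: for each cluster
# of `own` with >= 2 members, the fraction of ordered pairs that `ref` also
# co-assigns; smaller clusters contribute 1.
co_membership_min <- function(own, ref) {
  own <- as.integer(factor(own))
  per_cluster <- vapply(seq_len(max(own)), function(j) {
    members <- which(own == j)
    nj <- length(members)
    if (nj < 2L) return(1)
    m <- tabulate(factor(ref[members]))
    sum(m * (m - 1)) / (nj * (nj - 1))
  }, numeric(1))
  min(per_cluster)
}

#' Prediction strength of a clustering
#'
#' Fits k-medoids independently on a train and a test partition, assigns the
#' test samples to their nearest *train* medoid, and for each test cluster
#' with at least two members computes the fraction of ordered sample pairs
#' that the train-fitted model also co-assigns. The prediction strength is
#' the minimum of this fraction over test clusters; singleton test clusters
#' contribute 1, and `ps(1) = 1` always.
#'
#' @param train,test Feature matrices (Euclidean metric), or — when `d` is
#'   supplied — integer index vectors into the rows of `d`.
#' @param k Number of clusters (`k <=` both partition sizes).
#' @param d Optional full dissimilarity matrix over all samples; `train` and
#'   `test` then index into it.
#' @return Prediction strength in \[0, 1\].
#' @export
prediction_strength <- function(train, test, k, d = NULL) {
  stopifnot_scalar_count(k, "k")
  if (is.null(d)) {
    train <- as.matrix(train)
    test <- as.matrix(test)
    n_tr <- nrow(train)
    n_te <- nrow(test)
    if (k > n_tr || k > n_te) {
      stop("k exceeds a partition size", call. = FALSE)
    }
    if (k == 1L) return(1)
    fit_tr <- kmedoids_fit(train, k, diss = FALSE)
    fit_te <- kmedoids_fit(test, k, diss = FALSE)
    cross <- as.matrix(pracma::distmat(test, train[fit_tr$medoid_idx, ,
                                                   drop = FALSE]))
    by_train <- max.col(-cross, ties.method = "first")
    co_membership_min(fit_te$labels, by_train)
  } else {
    D <- as_diss_matrix(d, "d")
    train <- as.integer(train)
    test <- as.integer(test)
    if (k > length(train) || k > length(test)) {
      stop("k exceeds a partition size", call. = FALSE)
    }
    if (k == 1L) return(1)
    fit_tr <- kmedoids_fit(D[train, train, drop = FALSE], k, diss = TRUE)
    fit_te <- kmedoids_fit(D[test, test, drop = FALSE], k, diss = TRUE)
    cross <- D[test, train[fit_tr$medoid_idx], drop = FALSE]
    by_train <- max.col(-cross, ties.method = "first")
    co_membership_min(fit_te$labels, by_train)
  }
}

#' Scan a range of cluster numbers
#'
#' Fits k-medoids for each k in `k_range` (warm-starting each fit from the
#' previous k's medoids, which also keeps the inertia curve monotone) and
#' records the silhouette score (NA where undefined, i.e. k = 1), the mean
#' squared inertia, and optionally the prediction strength computed from a
#' seeded 50/50 split of the samples. Prediction strength is optional because
#' its cost grows quickly for dissimilarity representations; leave it off
#' where not needed.
#'
#' @param x Dissimilarity (`dist`/symmetric matrix) or feature matrix.
#' @param k_range Integer vector of cluster numbers (default 1:15).
#' @param compute_ps Also compute prediction strength per k (default FALSE).
#' @param ps_frac Fraction of samples in the prediction-strength train half
#'   (default 0.5).
#' @param seed Seed for the prediction-strength split.
#' @param method Free-text tag stored with the curves.
#' @return Object of class `dvp_selection_curves`: a data.frame with columns
#'   `k`, `silhouette`, `inertia`, `ps`, plus the fitted `dvp_kmedoids`
#'   objects in `attr(, "fits")`.
#' @export
scan_k <- function(x, k_range = 1:15, compute_ps = FALSE, ps_frac = 0.5,
                   seed = 1L, method = "unnamed") {
  if (!looks_like_diss(x)) {
    D <- as.matrix(dist(as.matrix(x)))
  } else {
    D <- as_diss_matrix(x, "x")
  }
  n <- nrow(D)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L) || any(k_range > n)) {
    stop("k_range must lie in [1, n]", call. = FALSE)
  }
  split_idx <- with_seed(seed, sample.int(n))
  n_tr <- max(1L, round(ps_frac * n))
  tr <- split_idx[seq_len(n_tr)]
  te <- split_idx[(n_tr + 1L):n]

  fits <- vector("list", length(k_range))
  sil <- iner <- ps <- rep(NA_real_, length(k_range))
  prev_medoids <- NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- kmedoids_fit(D, k, diss = TRUE, init_medoids = prev_medoids)
    prev_medoids <- fit$medoid_idx
    fits[[i]] <- fit
    iner[i] <- cluster_inertia(fit, D, type = "mean")
    if (k >= 2L && k < n) sil[i] <- silhouette_score(fit$labels, D)
    if (compute_ps && k <= length(tr) && k <= length(te)) {
      ps[i] <- prediction_strength(tr, te, k, d = D)
    }
  }
  out <- data.frame(k = k_range, silhouette = sil, inertia = iner, ps = ps)
  attr(out, "fits") <- fits
  attr(out, "method") <- method
  class(out) <- c("dvp_selection_curves", "data.frame")
  out
}

# k at the inertia elbow: the point with maximum perpendicular distance to
# the straight line joining the first and last points of the curve.
inertia_elbow_k <- function(k, inertia) {
  ok <- is.finite(inertia)
  k <- k[ok]
  inertia <- inertia[ok]
  if (length(k) < 3L) return(k[1L])
  p1 <- c(k[1L], inertia[1L])
  p2 <- c(k[length(k)], inertia[length(k)])
  v <- p2 - p1
  nv <- sqrt(sum(v^2))
  dist_perp <- abs(v[2L] * (k - p1[1L]) - v[1L] * (inertia - p1[2L])) / nv
  k[which.max(dist_perp)]
}

#' Choose the number of clusters from selection curves
#'
#' Among k with prediction strength at or above `ps_threshold` (k where ps is
#' unavailable always qualify), picks the k maximizing the silhouette score;
#' ties break toward the inertia elbow (the curve point farthest from the
#' line joining its endpoints). When no k clears the threshold the silhouette
#' argmax is returned with a warning. The result is a recommendation — the
#' curves themselves remain the primary output.
#'
#' @param curves A `dvp_selection_curves` object (or data.frame with columns
#'   `k`, `silhouette`, `inertia`, `ps`).
#' @param ps_threshold Prediction-strength admissibility threshold
#'   (default 0.7).
#' @return The chosen k (integer).
#' @export
choose_k <- function(curves, ps_threshold = 0.7) {
  cand <- curves[is.finite(curves$silhouette), , drop = FALSE]
  if (!nrow(cand)) stop("no k with a defined silhouette score", call. = FALSE)
  feasible <- cand[is.na(cand$ps) | cand$ps >= ps_threshold, , drop = FALSE]
  if (!nrow(feasible)) {
    warning("no k reaches prediction strength ", ps_threshold,
            "; falling back to the silhouette argmax", call. = FALSE)
    feasible <- cand
  }
  best <- max(feasible$silhouette)
  tied <- feasible$k[feasible$silhouette >= best - 1e-9]
  if (length(tied) == 1L) return(as.integer(tied))
  elbow <- inertia_elbow_k(curves$k, curves$inertia)
  as.integer(tied[order(abs(tied - elbow), tied)][1L])
}

#' @export
print.dvp_selection_curves <- function(x, ...) {
  cat("Cluster-number selection curves (method:",
      attr(x, "method"), ")\n")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.dvp_selection_curves <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(1, if (all(is.na(x$ps))) 2L else 3L))
  on.exit(graphics::par(oldpar))
  plot(x$k, x$silhouette, type = "b", xlab = "k", ylab = "silhouette", ...)
  plot(x$k, x$inertia, type = "b", xlab = "k", ylab = "inertia", ...)
  if (!all(is.na(x$ps))) {
    plot(x$k, x$ps, type = "b", xlab = "k", ylab = "prediction strength", ...)
  }
  invisible(x)
}
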