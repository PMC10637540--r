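# Cluster / clinical-covariate association: normalized per-cluster means
# (radar values), Kruskal-Wallis + pairwise Welch testing, and the weighted
# quantile-function distance scoring how clinically separated clusters are.

minmax_normalize <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[1L] == r[2L]) return(rep(0, length(x)))
  (x - r[1L]) / (r[2L] - r[1L])
}

#' Per-cluster normalized covariate means
#'
#' Min-max normalizes every covariate over the full dataset and averages it
#' within each cluster — the values drawn on radar plots of cluster clinical
#' profiles. Clusters with no members get `NA`.
#'
#' @param labels Cluster labels, one per row of `clinical`.
#' @param clinical Data frame of numeric covariates aligned with `labels`.
#' @return Matrix: one row per cluster, one column per covariate, all values
#'   in \[0, 1\] (or `NA` for empty clusters).
#' @export
cluster_means_normalized <- function(labels, clinical) {
  clinical <- as.data.frame(clinical)
  if (length(labels) != nrow(clinical)) {
    stop("labels and clinical table are not aligned", call. = FALSE)
  }
  num <- vapply(clinical, is.numeric, logical(1))
  norm <- vapply(clinical[num], minmax_normalize, numeric(nrow(clinical)))
  norm <- matrix(norm, nrow = nrow(clinical),
                 dimnames = list(NULL, names(clinical)[num]))
  lv <- sort(unique(labels))
  out <- do.call(rbind, lapply(lv, function(l) {
    colMeans(norm[labels == l, , drop = FALSE])
  }))
  rownames(out) <- as.character(lv)
  out
}

#' Kruskal-Wallis screening with Welch post-hoc tests
#'
#' For each covariate, a Kruskal-Wallis test across clusters asks whether any
#' cluster's distribution differs; only where its null (equal mean ranks) is
#' rejected at `alpha` are all pairwise Welch two-sample t tests run, with
#' Holm adjustment over the pairs of that covariate. Covariates with fewer
#' than two clusters of size two or more are skipped with a warning.
#'
#' @param labels Cluster labels, one per row of `clinical`.
#' @param clinical Data frame of numeric covariates.
#' @param alpha Significance level (default 0.05).
#' @return List of class `dvp_test_report` with data frames `kruskal`
#'   (variable, statistic, p, significant) and `welch` (variable, cluster_i,
#'   cluster_j, statistic, p, p_adj, significant; rows exist only for
#'   Kruskal-Wallis-significant variables).
#' @export
kruskal_then_welch <- function(labels, clinical, alpha = 0.05) {
  clinical <- as.data.frame(clinical)
  if (length(labels) != nrow(clinical)) {
    stop("labels and clinical table are not aligned", call. = FALSE)
  }
  g <- factor(labels)
  vars <- names(clinical)[vapply(clinical, is.numeric, logical(1))]
  kw <- data.frame(variable = character(), statistic = numeric(),
                   p = numeric(), significant = logical(),
                   stringsAsFactors = FALSE)
  welch <- data.frame(variable = character(), cluster_i = character(),
                      cluster_j = character(), statistic = numeric(),
                      p = numeric(), p_adj = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  sizes <- table(g)
  if (sum(sizes >= 2L) < 2L) {
    stop("need at least two clusters with two or more members", call. = FALSE)
  }
  for (v in vars) {
    x <- clinical[[v]]
    keep <- g %in% names(sizes)[sizes >= 2L]
    gi <- droplevels(g[keep])
    xi <- x[keep]
    if (length(unique(xi)) < 2L) {
      warning("covariate ", v, " is constant; skipped", call. = FALSE)
      next
    }
    kt <- kruskal.test(xi, gi)
    sig <- kt$p.value < alpha
    kw <- rbind(kw, data.frame(variable = v,
                               statistic = unname(kt$statistic),
                               p = kt$p.value, significant = sig))
    if (isTRUE(sig)) {
      lv <- levels(gi)
      pairs <- utils::combn(lv, 2L)
      rows <- lapply(seq_len(ncol(pairs)), function(pi) {
        a <- xi[gi == pairs[1L, pi]]
        b <- xi[gi == pairs[2L, pi]]
        if (var(a) == 0 && var(b) == 0) {
          return(data.frame(variable = v, cluster_i = pairs[1L, pi],
                            cluster_j = pairs[2L, pi],
                            statistic = 0, p = 1))
        }
        wt <- t.test(a, b, var.equal = FALSE)
        data.frame(variable = v, cluster_i = pairs[1L, pi],
                   cluster_j = pairs[2L, pi],
                   statistic = unname(wt$statistic), p = wt$p.value)
      })
      rows <- do.call(rbind, rows)
      rows$p_adj <- p.adjust(rows$p, method = "holm")
      rows$significant <- rows$p_adj < alpha
      welch <- rbind(welch, rows)
    }
  }
  structure(list(kruskal = kw, welch = welch, alpha = alpha),
            class = "dvp_test_report")
}

#' @export
print.dvp_test_report <- function(x, ...) {
  cat("Kruskal-Wallis screening (alpha =", x$alpha, "):\n")
  print(x$kruskal, row.names = FALSE, digits = 4)
  if (nrow(x$welch)) {
    cat("\nPairwise Welch tests (Holm-adjusted) for significant variables:\n")
    print(x$welch, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Distance between two empirical quantile functions
#'
#' Evaluates both samples' empirical quantile functions (linear interpolation
#' of the order statistics) on the midpoint probability grid
#' `(q - 0.5) / Q`, `q = 1..Q`, and aggregates the pointwise absolute gaps.
#' The default mean-absolute aggregation equals the 1-Wasserstein distance
#' between the empirical distributions; `type = "rms"` gives the
#' root-mean-square variant. Either way a pure location shift by `c` yields a
#' distance of exactly `|c|` — distribution shifts along the x-axis are
#' deliberately not discounted.
#'
#' @param x,y Nonempty numeric samples.
#' @param grid_size Number of probability grid points Q (default 100).
#' @param type `"mean_abs"` (default) or `"rms"`.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' quantile_distance(rnorm(50), rnorm(50) + 2)  # close to 2
quantile_distance <- function(x, y, grid_size = 100L,
                              type = c("mean_abs", "rms")) {
  type <- match.arg(type)
  if (!length(x) || !length(y)) stop("samples must be nonempty", call. = FALSE)
  p <- (seq_len(grid_size) - 0.5) / grid_size
  qx <- quantile(x, probs = p, names = FALSE, type = 7)
  qy <- quantile(y, probs = p, names = FALSE, type = 7)
  gap <- abs(qx - qy)
  if (type == "mean_abs") mean(gap) else sqrt(mean(gap^2))
}

#' Weighted quantile-distance separation of clusters
#'
#' Scores how differently a clinical covariate is distributed across
#' clusters: all pairwise quantile-function distances between cluster
#' subsamples are averaged with size weights `w_n = n_n / N` (penalizing tiny
#' clusters) and the normalizer `1 / (k (k - 1))` over ordered pairs:
#' `d = 1/(k(k-1)) * sum_i w_i sum_{j != i} w_j dist(i, j)`.
#' Larger `d` means the clustering separates the covariate better; `d = 0`
#' iff all cluster distributions coincide on the quantile grid. By default
#' the covariate is min-max normalized over the full dataset first, so `d`
#' is comparable across covariates with different units.
#'
#' @param labels Cluster labels aligned with `values`.
#' @param values Numeric covariate values, one per sample.
#' @param normalize Min-max normalize `values` first (default TRUE).
#' @param grid_size,type Passed to [quantile_distance()].
#' @param variable Optional covariate name stored in the report.
#' @return List of class `dvp_csm_report`: `d`, `k`, `weights` (sum to 1),
#'   `dist` (symmetric k x k matrix, zero diagonal), `variable`,
#'   `normalized`.
#' @export
csm_weighted_distance <- function(labels, values, normalize = TRUE,
                                  grid_size = 100L,
                                  type = c("mean_abs", "rms"),
                                  variable = NULL) {
  type <- match.arg(type)
  if (length(labels) != length(values)) {
    stop("labels and values are not aligned", call. = FALSE)
  }
  if (normalize) values <- minmax_normalize(values)
  lv <- sort(unique(labels))
  k <- length(lv)
  if (k < 2L) stop("need at least 2 clusters", call. = FALSE)
  groups <- lapply(lv, function(l) values[labels == l])
  w <- lengths(groups) / length(values)
  dm <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      dm[i, j] <- dm[j, i] <- quantile_distance(groups[[i]], groups[[j]],
                                                grid_size = grid_size,
                                                type = type)
    }
  }
  d <- sum((w %o% w) * dm) / (k * (k - 1L))
  structure(list(d = d, k = k, weights = w, dist = dm,
                 variable = variable, normalized = normalize,
                 clusters = lv),
            class = "dvp_csm_report")
}

#' @export
print.dvp_csm_report <- function(x, ...) {
  cat(sprintf("Weighted quantile-distance separation%s: d = %.4g (k = %d%s)\n",
              if (is.null(x$variable)) "" else paste0(" for ", x$variable),
              x$d, x$k,
              if (x$normalized) ", min-max normalized" else ""))
  invisible(x)
}
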