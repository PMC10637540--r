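# Independent oracles and small fixture builders used across the suite.

# Brute-force DTW: explore every monotone alignment path from (1,1) to
# (n,m) by forward recursion over the three moves, with no cost table.
# Exponential, usable only for short series; written directly from the
# definition of an alignment path so it is independent of the DP kernel.
bf_dtw <- function(s, t) {
  n <- length(s)
  m <- length(t)
  rec <- function(i, j) {
    cost <- abs(s[i] - t[j])
    if (i == n && j == m) return(cost)
    nxt <- Inf
    if (i < n) nxt <- min(nxt, rec(i + 1L, j))
    if (j < m) nxt <- min(nxt, rec(i, j + 1L))
    if (i < n && j < m) nxt <- min(nxt, rec(i + 1L, j + 1L))
    cost + nxt
  }
  rec(1L, 1L)
}

# Textbook silhouette, one sample at a time, straight from the definition.
bf_silhouette <- function(labels, D) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(D[i, labels == cl]))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

# Two tight, far-apart 1-D blobs with ground-truth labels.
make_blobs <- function(n_per = 20L, gap = 10, sd = 0.3, seed = 1L) {
  set.seed(seed)
  x <- matrix(c(rnorm(n_per, 0, sd), rnorm(n_per, gap, sd)), ncol = 1L)
  list(x = x, labels = rep(1:2, each = n_per))
}

# Normalized noise-free renderings of the four class templates.
template_pulses <- function() {
  normalize_pulses(lapply(make_class_templates(), render_template))
}

# Random smooth pulse-like curves on the 100-sample grid.
random_pulses <- function(n, seed = 1L) {
  set.seed(seed)
  t(replicate(n, {
    tt <- seq(0, 1, length.out = 100)
    y <- exp(-((tt - runif(1, 0.15, 0.35))^2) / (2 * runif(1, 0.05, 0.15)^2)) +
      runif(1, 0, 0.5) *
        exp(-((tt - runif(1, 0.5, 0.8))^2) / (2 * runif(1, 0.05, 0.15)^2))
    normalize_pulse(y + rnorm(100, 0, 0.01))
  }))
}
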