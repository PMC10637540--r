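# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. Keeps every seeded operation a pure function of
# its seed without clobbering the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  expr
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Accept a stats::dist object or a square symmetric matrix with a zero
# diagonal; return the dense matrix. Used by every consumer of dissimilarities.
as_diss_matrix <- function(d, arg = "d") {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop(sprintf("`%s` must be a square dissimilarity matrix or a dist object",
                 arg), call. = FALSE)
  }
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8, check.attributes = FALSE))) {
    stop(sprintf("`%s` must be symmetric", arg), call. = FALSE)
  }
  if (any(diag(d) != 0)) {
    stop(sprintf("`%s` must have a zero diagonal", arg), call. = FALSE)
  }
  if (any(d < 0)) stop(sprintf("`%s` must be nonnegative", arg), call. = FALSE)
  d
}

# Pulses can arrive as a list of numeric vectors or a matrix (one pulse per
# row). Return a list of numeric vectors.
as_pulse_list <- function(pulses) {
  if (is.matrix(pulses)) {
    lapply(seq_len(nrow(pulses)), function(i) as.numeric(pulses[i, ]))
  } else if (is.list(pulses)) {
    lapply(pulses, as.numeric)
  } else if (is.numeric(pulses)) {
    list(as.numeric(pulses))
  } else {
    stop("pulses must be a numeric matrix (one pulse per row) or a list of
         numeric vectors", call. = FALSE)
  }
}

# Strict interior local maxima/minima of a numeric vector.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] > x[i + 1L]]
}

local_minima <- function(x) local_maxima(-x)
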