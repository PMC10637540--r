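# Handcrafted pulse morphology features: fiducial-point detection on the
# 100-sample normalized grid, the 14-feature vector used for clustering, and
# the train-fitted standardizer.

# Feature column order is part of the interface.
feature_names <- c("DDR", "RDS", "DDM", "Skew", "P_b_2Dev_A", "P_b_2Dev_i",
                   "P_a_2Dev_A", "P_a_2Dev_i", "S_P_Onde", "nbr_peaks",
                   "log_RT", "log_Kurt", "AI_bin", "log_DDV")

# Topographic prominence of the interior local maxima of x: each peak's bases
# are the minima between it and the nearest higher terrain (or the signal
# edge) on either side; prominence = peak - max(left base, right base).
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(i) {
    left <- x[seq_len(i - 1L)]
    higher_l <- which(left > x[i])
    lo_l <- if (length(higher_l)) max(higher_l) + 1L else 1L
    base_l <- min(x[lo_l:i])
    right <- x[(i + 1L):length(x)]
    higher_r <- which(right > x[i])
    hi_r <- if (length(higher_r)) i + min(higher_r) - 1L else length(x)
    base_r <- min(x[i:hi_r])
    x[i] - max(base_l, base_r)
  }, numeric(1))
}

#' Detect fiducial points on a normalized pulse
#'
#' Locates the landmarks used by the handcrafted features: pulse onset (the
#' amplitude minimum at or before the systolic peak), systolic peak (global
#' maximum), point of maximum downslope (most negative first derivative after
#' the systolic peak), dicrotic notch (first local minimum of the pulse after
#' the maximum downslope, falling back to the most negative local minimum of
#' the first derivative), the diastolic peak (first local maximum after the
#' notch), and the first local minimum and the global maximum of the second
#' derivative. Notch and diastolic peak are `NA` when no qualifying extremum
#' exists (e.g. a notch-free class-4 shape); detection never fails.
#'
#' @param pulse Normalized pulse (see [normalize_pulse()]).
#' @return List of class `dvp_fiducials` with elements `onset_idx`,
#'   `systolic_peak_idx`, `max_downslope_idx`, `dicrotic_notch_idx`,
#'   `diastolic_peak_idx`, `sdppg_min1_idx`, `sdppg_min1_amp`,
#'   `sdppg_max_idx`, `sdppg_max_amp`. Indices are on the input grid.
#' @export
detect_fiducials <- function(pulse) {
  x <- as.numeric(pulse)
  n <- length(x)
  sp <- which.max(x)
  onset <- which.min(x[seq_len(sp)])
  d <- diff(x)                      # d[i] = x[i+1] - x[i], i = 1..n-1
  post <- sp:(n - 1L)
  mds <- if (sp < n) post[which.min(d[post])] else sp

  # Dicrotic notch: first strict local minimum of the pulse after the maximum
  # downslope; fallback: a second deceleration episode, i.e. the most
  # negative local minimum of the first derivative strictly after the
  # maximum-downslope point (which is itself a derivative minimum and must
  # not qualify).
  mins <- local_minima(x)
  mins <- mins[mins > mds]
  notch <- if (length(mins)) mins[1L] else NA_integer_
  if (is.na(notch)) {
    dmins <- local_minima(d)
    dmins <- dmins[dmins > mds]
    if (length(dmins)) notch <- dmins[which.min(d[dmins])]
  }

  dia <- NA_integer_
  if (!is.na(notch)) {
    maxs <- local_maxima(x)
    maxs <- maxs[maxs > notch]
    if (length(maxs)) dia <- maxs[1L]
  }
  if (!is.na(dia) && is.na(notch)) dia <- NA_integer_

  d2 <- c(NA, diff(x, differences = 2L), NA)  # centred on sample i
  d2v <- d2[2:(n - 1L)]
  d2_mins <- local_minima(d2v) + 1L
  sd_min_idx <- if (length(d2_mins)) d2_mins[1L] else which.min(d2v) + 1L
  sd_max_idx <- which.max(d2v) + 1L

  structure(list(onset_idx = onset, systolic_peak_idx = sp,
                 max_downslope_idx = mds, dicrotic_notch_idx = notch,
                 diastolic_peak_idx = dia,
                 sdppg_min1_idx = sd_min_idx, sdppg_min1_amp = d2[sd_min_idx],
                 sdppg_max_idx = sd_max_idx, sdppg_max_amp = d2[sd_max_idx]),
            class = "dvp_fiducials")
}

#' Extract the 14 handcrafted morphology features
#'
#' Computes, in fixed order: `DDR` (dicrotic notch / diastolic peak amplitude
#' ratio, sentinel 1.1 when no diastolic point is detected), `RDS` (area under
#' the curve from the maximum downslope to the pulse end), `DDM` (mean first
#' derivative after the systolic peak), `Skew` (skewness of the amplitude
#' distribution), `P_b_2Dev_A`/`P_b_2Dev_i` (amplitude and index of the first
#' local minimum of the second derivative), `P_a_2Dev_A`/`P_a_2Dev_i`
#' (amplitude and index of the maximum of the second derivative), `S_P_Onde`
#' (total area under the curve), `nbr_peaks` (count of local maxima with
#' topographic prominence at least `peak_prominence`), `log_RT` (log rise
#' time in samples, floored at one sample), `log_Kurt` (log of kurtosis,
#' excess + 3), `AI_bin` (1 when an augmentation-index inflection — a
#' secondary systolic shoulder between the systolic peak and the notch — is
#' detectable), and `log_DDV` (log variance of the first derivative over the
#' downslope, floored at 1e-8). Areas use the trapezoid rule on the unit time
#' grid. Extraction is total: notch-free shapes produce sentinels, never
#' errors.
#'
#' @param pulse Normalized pulse.
#' @param peak_prominence Minimum prominence (normalized amplitude units) for
#'   a local maximum to count as a peak (default 0.02).
#' @return Named numeric vector of length 14.
#' @export
#' @examples
#' tpl <- make_class_templates()
#' extract_features(render_template(tpl[[4]]))[["DDR"]]  # sentinel 1.1
extract_features <- function(pulse, peak_prominence = 0.02) {
  x <- as.numeric(pulse)
  n <- length(x)
  fid <- detect_fiducials(x)
  tgrid <- seq(0, 1, length.out = n)
  d <- diff(x)

  ddr <- if (is.na(fid$diastolic_peak_idx) || is.na(fid$dicrotic_notch_idx)) {
    1.1
  } else {
    x[fid$dicrotic_notch_idx] / x[fid$diastolic_peak_idx]
  }
  seg <- fid$max_downslope_idx:n
  rds <- pracma::trapz(tgrid[seg], x[seg])
  ddm <- if (fid$systolic_peak_idx < n) {
    mean(d[fid$systolic_peak_idx:(n - 1L)])
  } else 0
  skew <- e1071::skewness(x)
  s_p_onde <- pracma::trapz(tgrid, x)

  peaks <- local_maxima(x)
  npk <- if (length(peaks)) {
    sum(peak_prominences(x, peaks) >= peak_prominence)
  } else 0L
  npk <- max(npk, 1L)  # the systolic peak always counts

  log_rt <- log(max(fid$systolic_peak_idx - fid$onset_idx, 1L))
  log_kurt <- log(e1071::kurtosis(x) + 3)

  # Augmentation-index detectability: a secondary systolic shoulder shows as a
  # strict local maximum of the first derivative between the systolic peak and
  # the dicrotic notch (or the end of the downslope when no notch exists).
  seg_end <- if (!is.na(fid$dicrotic_notch_idx)) fid$dicrotic_notch_idx else n - 1L
  ai_bin <- 0
  if (seg_end - fid$systolic_peak_idx >= 3L) {
    dseg <- d[fid$systolic_peak_idx:(seg_end - 1L)]
    ai_bin <- as.numeric(length(local_maxima(dseg)) > 0L)
  }

  down <- d[fid$systolic_peak_idx:(n - 1L)]
  log_ddv <- log(max(var(down), 1e-8))

  out <- c(ddr, rds, ddm, skew, fid$sdppg_min1_amp, fid$sdppg_min1_idx,
           fid$sdppg_max_amp, fid$sdppg_max_idx, s_p_onde, npk, log_rt,
           log_kurt, ai_bin, log_ddv)
  names(out) <- feature_names
  out
}

#' Feature matrix for a set of pulses
#'
#' @param pulses Matrix (one normalized pulse per row) or list of pulses.
#' @param ... Passed to [extract_features()].
#' @return Numeric matrix, one row per pulse, 14 named columns.
#' @export
extract_feature_matrix <- function(pulses, ...) {
  pl <- as_pulse_list(pulses)
  t(vapply(pl, extract_features, numeric(length(feature_names)), ...))
}

#' Fit a column standardizer on training features
#'
#' @param train Numeric feature matrix (training partition only).
#' @param drop_constant Drop zero-variance columns with a warning instead of
#'   erroring (default FALSE).
#' @return An object of class `dvp_feature_scaler` holding per-column mean and
#'   standard deviation; apply it with `predict()`.
#' @export
fit_feature_scaler <- function(train, drop_constant = FALSE) {
  train <- as.matrix(train)
  mu <- colMeans(train)
  sdv <- apply(train, 2L, sd)
  bad <- which(sdv == 0 | !is.finite(sdv))
  if (length(bad)) {
    cols <- paste(colnames(train)[bad], collapse = ", ")
    if (!drop_constant) {
      stop("zero-variance feature column(s): ", cols, call. = FALSE)
    }
    warning("dropping zero-variance feature column(s): ", cols, call. = FALSE)
    mu <- mu[-bad]
    sdv <- sdv[-bad]
  }
  structure(list(mean = mu, sd = sdv, columns = names(mu)),
            class = "dvp_feature_scaler")
}

#' @export
predict.dvp_feature_scaler <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$columns) && !is.null(colnames(newdata))) {
    newdata <- newdata[, object$columns, drop = FALSE]
  }
  scale(newdata, center = object$mean, scale = object$sd)[, , drop = FALSE]
}

#' Standardize feature matrices with train-fitted statistics
#'
#' Per-column z-scoring whose mean and standard deviation are estimated on the
#' training partition only and applied unchanged to every other partition.
#'
#' @param train Training feature matrix.
#' @param ... Further feature matrices (validation, test, ...) transformed
#'   with the train statistics.
#' @param drop_constant See [fit_feature_scaler()].
#' @return List with the transformed `train`, the transformed `...` matrices
#'   (by position/name), and the fitted `scaler`.
#' @export
fit_transform_features <- function(train, ..., drop_constant = FALSE) {
  scaler <- fit_feature_scaler(train, drop_constant = drop_constant)
  others <- lapply(list(...), function(m) predict(scaler, m))
  c(list(train = predict(scaler, train)), others, list(scaler = scaler))
}
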