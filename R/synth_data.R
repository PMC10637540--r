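# Synthetic DVP generator: four planted morphology classes (the classic
# notch-based classes 1..4) rendered as a sum of three Gaussians (systolic,
# reflected, diastolic wave) minus a notch dip, with age-modulated amplitudes
# and clinical covariates coupled to vascular age.

# Target moments and bounds of the emulated clinical population.
.clinical_targets <- list(
  age    = list(mean = 44.31, sd = 14.34, min = 19.48, max = 83.00),
  weight = list(mean = 74.60, sd = 16.99, min = 45.00, max = 180.00),
  height = list(mean = 170.04, sd = 8.45, min = 140.00, max = 196.00),
  PWV    = list(mean = 7.99,  sd = 2.91,  min = 3.70,  max = 26.10),
  PAS    = list(mean = 124.77, sd = 16.01, min = 90.00, max = 190.00),
  PAD    = list(mean = 76.10, sd = 9.73,  min = 48.00, max = 120.00),
  BMI    = list(mean = 25.78, sd = 5.12,  min = 6.00,  max = 56.00),
  BPM    = list(mean = 71.82, sd = 14.89, min = 40.00, max = 185.00)
)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Morphology class templates
#'
#' Parameter sets for the four canonical single-beat pulse shapes, graded by
#' dicrotic-notch prominence: class 1 has a clearly marked notch and diastolic
#' peak, classes 2 and 3 are intermediate, and class 4 is a single broad wave
#' with no notch and no diastolic peak. Each template is a sum of three
#' Gaussians on normalized time t in \[0, 1\] (systolic, reflected and
#' diastolic wave) minus a Gaussian notch dip centred between the reflected
#' and diastolic waves.
#'
#' @return A list of four objects of class `dvp_class_template`, each with
#'   fields `class_id`, `systolic_amp/center/width`,
#'   `reflected_amp/center/width`, `diastolic_amp/center/width` and
#'   `notch_depth`.
#' @seealso [render_template()], [generate_pulse()], [generate_dataset()]
#' @export
#' @examples
#' tpl <- make_class_templates()
#' w1 <- render_template(tpl[[1]])
#' range(w1)  # 0 and 1
make_class_templates <- function() {
  p <- list(
    list(class_id = 1L,
         systolic_amp = 1.00, systolic_center = 0.19, systolic_width = 0.085,
         reflected_amp = 0.33, reflected_center = 0.36, reflected_width = 0.085,
         diastolic_amp = 0.50, diastolic_center = 0.62, diastolic_width = 0.09,
         notch_depth = 0.24),
    list(class_id = 2L,
         systolic_amp = 1.00, systolic_center = 0.23, systolic_width = 0.10,
         reflected_amp = 0.27, reflected_center = 0.42, reflected_width = 0.10,
         diastolic_amp = 0.35, diastolic_center = 0.65, diastolic_width = 0.10,
         notch_depth = 0.16),
    list(class_id = 3L,
         systolic_amp = 1.00, systolic_center = 0.27, systolic_width = 0.135,
         reflected_amp = 0.17, reflected_center = 0.48, reflected_width = 0.11,
         diastolic_amp = 0.24, diastolic_center = 0.69, diastolic_width = 0.11,
         notch_depth = 0.10),
    list(class_id = 4L,
         systolic_amp = 1.00, systolic_center = 0.33, systolic_width = 0.19,
         reflected_amp = 0.04, reflected_center = 0.54, reflected_width = 0.16,
         diastolic_amp = 0.00, diastolic_center = 0.72, diastolic_width = 0.12,
         notch_depth = 0.00)
  )
  lapply(p, function(x) structure(x, class = "dvp_class_template"))
}

gaussian_bump <- function(t, amp, center, width) {
  if (amp == 0) return(numeric(length(t)))
  amp * exp(-((t - center)^2) / (2 * width^2))
}

# Age-modulation schedule: older vascular age attenuates the reflected and
# diastolic waves and the notch, and broadens the systolic peak. The
# coefficients are kept well below the between-class parameter gaps so that a
# subject's class, not their age, dominates the pulse shape: each noise-free
# pulse stays nearest its own class template under DDTW at every age.
age_modulated_params <- function(params, vascular_age) {
  s <- clip((vascular_age - 19) / (83 - 19), 0, 1)
  params$diastolic_amp <- params$diastolic_amp * (1 - 0.08 * s)
  params$reflected_amp <- params$reflected_amp * (1 - 0.05 * s)
  params$notch_depth <- params$notch_depth * (1 - 0.08 * s)
  params$systolic_width <- params$systolic_width * (1 + 0.025 * s)
  params
}

eval_template <- function(params, t) {
  notch_center <- (params$reflected_center + params$diastolic_center) / 2
  gaussian_bump(t, params$systolic_amp, params$systolic_center,
                params$systolic_width) +
    gaussian_bump(t, params$reflected_amp, params$reflected_center,
                  params$reflected_width) +
    gaussian_bump(t, params$diastolic_amp, params$diastolic_center,
                  params$diastolic_width) -
    gaussian_bump(t, params$notch_depth, notch_center, 0.035)
}

#' Render a class template as a waveform
#'
#' Evaluates a morphology template on an equally spaced time grid, optionally
#' after applying the vascular-age modulation and min-max normalization.
#'
#' @param params A `dvp_class_template` (see [make_class_templates()]).
#' @param n Number of samples (default 100).
#' @param age Optional vascular age in years; when given, amplitudes and the
#'   systolic width are modulated before rendering.
#' @param normalize Min-max scale the rendered wave to \[0, 1\] (default TRUE).
#' @return Numeric vector of length `n`.
#' @export
render_template <- function(params, n = 100L, age = NULL, normalize = TRUE) {
  stopifnot(inherits(params, "dvp_class_template"))
  if (!is.null(age)) params <- age_modulated_params(params, age)
  y <- eval_template(params, seq(0, 1, length.out = n))
  if (normalize) y <- (y - min(y)) / (max(y) - min(y))
  y
}

#' Generate one raw synthetic pulse
#'
#' Renders an age-modulated class template on a randomly drawn grid length
#' (60 to 140 samples, so the downstream resampling path is exercised) and
#' adds band-limited Gaussian amplitude noise. The result is a *raw* pulse;
#' [normalize_pulse()] maps it onto the canonical 100-sample \[0, 1\] grid.
#'
#' Uses the current RNG stream: seed the session (or wrap with
#' [set.seed()]) for reproducibility.
#'
#' @param params A `dvp_class_template`.
#' @param vascular_age Age in years, in \[19, 83\].
#' @param noise_sd Additive noise standard deviation in raw amplitude units.
#' @param n_samples Optional fixed grid length (default: drawn from 60..140).
#' @return Numeric vector (raw pulse).
#' @export
generate_pulse <- function(params, vascular_age, noise_sd = 0.004,
                           n_samples = NULL) {
  stopifnot(inherits(params, "dvp_class_template"))
  if (!is.numeric(vascular_age) || length(vascular_age) != 1L ||
      vascular_age < 19 || vascular_age > 83) {
    stop("`vascular_age` must be a single value in [19, 83]", call. = FALSE)
  }
  if (is.null(n_samples)) n_samples <- sample(60:140, 1L)
  y <- render_template(params, n = n_samples, age = vascular_age,
                       normalize = FALSE)
  if (noise_sd > 0) y <- y + smooth_noise(n_samples, noise_sd)
  y
}

# Band-limited additive noise: white Gaussian noise convolved with a Gaussian
# kernel (correlation length ~2 samples), rescaled to the requested sd.
# Quality-screened PPG beats carry smooth residual artifacts (baseline,
# vasomotion), not per-sample sensor noise; smooth noise also keeps
# derivative-domain distances meaningful.
smooth_noise <- function(n, noise_sd) {
  kern <- exp(-((-4:4)^2) / (2 * 2^2))
  kern <- kern / sum(kern)
  e <- as.numeric(stats::filter(rnorm(n + 8L), kern, sides = 2L))
  e <- e[5:(n + 4L)]
  noise_sd * e / sqrt(sum(kern^2))
}

#' Synthetic dataset configuration
#'
#' @param n_subjects Number of subjects.
#' @param pulses_per_subject Pulses recorded per subject.
#' @param class_mixture Prior class probabilities (length 4, sums to 1).
#' @param waveform_noise_sd Additive waveform noise (raw amplitude units).
#' @param age_class_slope Strength of the logistic age-class coupling (0
#'   decouples class from age).
#' @param covariate_noise_sd Std. dev. of the noise added to vascular age when
#'   reporting chronological age, in years.
#' @param tt_path_constant Transit time model constant: TT\[ms\] =
#'   constant / PWV\[m/s\], i.e. a 1 m finger-to-toe path per default 1000.
#' @param seed Integer seed making the dataset a pure function of the config.
#' @return A list of class `dvp_synth_config`.
#' @export
synthetic_config <- function(n_subjects = 300L, pulses_per_subject = 37L,
                             class_mixture = c(0.25, 0.25, 0.25, 0.25),
                             waveform_noise_sd = 0.004,
                             age_class_slope = 0.6,
                             covariate_noise_sd = 1.0,
                             tt_path_constant = 1000,
                             seed = 1L) {
  stopifnot_scalar_count(n_subjects, "n_subjects")
  stopifnot_scalar_count(pulses_per_subject, "pulses_per_subject")
  if (length(class_mixture) != 4L || any(class_mixture < 0) ||
      abs(sum(class_mixture) - 1) > 1e-8) {
    stop("`class_mixture` must be 4 nonnegative probabilities summing to 1",
         call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 pulses_per_subject = as.integer(pulses_per_subject),
                 class_mixture = class_mixture,
                 waveform_noise_sd = waveform_noise_sd,
                 age_class_slope = age_class_slope,
                 covariate_noise_sd = covariate_noise_sd,
                 tt_path_constant = tt_path_constant,
                 seed = as.integer(seed)),
            class = "dvp_synth_config")
}

#' Transit time from pulse wave velocity
#'
#' Deterministic inverse relation TT = constant / PWV: stiffer arteries
#' (higher PWV) give shorter finger-to-toe transit times.
#'
#' @param pwv Pulse wave velocity in m/s.
#' @param path_constant Path constant in ms·m/s (default 1000, a 1 m path).
#' @return Transit time in ms.
#' @export
tt_from_pwv <- function(pwv, path_constant = 1000) path_constant / pwv

#' Generate a synthetic DVP dataset
#'
#' Draws subjects with a vascular age, assigns each a morphology class with
#' age-dependent odds (older subjects favour the notch-free classes), renders
#' `pulses_per_subject` noisy raw pulses per subject, and generates a clinical
#' covariate table aligned row-for-row with the pulses. Covariates track the
#' emulated population: age drives PWV, PAS and PAD through affine couplings
#' with noise, TT = path constant / PWV with 5% multiplicative noise, and
#' BMI, BPM, height and weight are drawn around the population mean/sd; all
#' values are clipped to the population min/max bounds.
#'
#' @param config A `dvp_synth_config` from [synthetic_config()].
#' @return A list of class `dvp_synth_dataset` with elements `pulses` (list of
#'   raw numeric vectors), `clinical` (data.frame with columns subject_id,
#'   true_class, age, weight, height, PWV, PAS, PAD, BMI, BPM, TT; one row per
#'   pulse) and `labels` (integer planted class per pulse).
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_config(n_subjects = 5,
#'                                         pulses_per_subject = 3, seed = 1))
#' length(ds$pulses)
#' head(ds$clinical)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "dvp_synth_config"))
  templates <- make_class_templates()
  tg <- .clinical_targets
  with_seed(config$seed, {
    ns <- config$n_subjects
    npps <- config$pulses_per_subject

    vascular_age <- clip(rnorm(ns, tg$age$mean, tg$age$sd),
                         tg$age$min, tg$age$max)

    # Class odds: prior mixture times a softmax tilt in standardized age, so
    # older subjects favour classes 3-4. Zero-prior classes stay impossible.
    z <- (vascular_age - tg$age$mean) / tg$age$sd
    tilt <- exp(outer(z, config$age_class_slope * (1:4 - 2.5)))
    probs <- sweep(tilt, 2, config$class_mixture, `*`)
    probs <- probs / rowSums(probs)
    true_class <- vapply(seq_len(ns),
                         function(i) sample.int(4L, 1L, prob = probs[i, ]),
                         integer(1))

    age <- clip(vascular_age + rnorm(ns, 0, config$covariate_noise_sd),
                tg$age$min, tg$age$max)
    # PWV affine-increasing in age (correlation ~0.7 with the target sd).
    # The 0.13 m/s offset compensates the upward bias that clipping at the
    # population minimum introduces, calibrated once so the large-sample mean
    # sits on the target.
    b_pwv <- 0.7 * tg$PWV$sd / tg$age$sd
    pwv <- clip(tg$PWV$mean - 0.13 + b_pwv * (age - tg$age$mean) +
                  rnorm(ns, 0, tg$PWV$sd * sqrt(1 - 0.7^2)),
                tg$PWV$min, tg$PWV$max)
    tt <- tt_from_pwv(pwv, config$tt_path_constant) * (1 + rnorm(ns, 0, 0.05))
    b_pas <- 0.5 * tg$PAS$sd / tg$age$sd
    pas <- clip(tg$PAS$mean + b_pas * (age - tg$age$mean) +
                  rnorm(ns, 0, tg$PAS$sd * sqrt(1 - 0.5^2)),
                tg$PAS$min, tg$PAS$max)
    b_pad <- 0.5 * tg$PAD$sd / tg$age$sd
    pad <- clip(tg$PAD$mean + b_pad * (age - tg$age$mean) +
                  rnorm(ns, 0, tg$PAD$sd * sqrt(1 - 0.5^2)),
                tg$PAD$min, tg$PAD$max)
    bmi <- clip(rnorm(ns, tg$BMI$mean, tg$BMI$sd), tg$BMI$min, tg$BMI$max)
    bpm <- clip(rnorm(ns, tg$BPM$mean, tg$BPM$sd), tg$BPM$min, tg$BPM$max)
    height <- clip(rnorm(ns, tg$height$mean, tg$height$sd),
                   tg$height$min, tg$height$max)
    weight <- clip(rnorm(ns, tg$weight$mean, tg$weight$sd),
                   tg$weight$min, tg$weight$max)

    subj_row <- rep(seq_len(ns), each = npps)
    pulses <- lapply(subj_row, function(i) {
      generate_pulse(templates[[true_class[i]]], vascular_age[i],
                     noise_sd = config$waveform_noise_sd)
    })
    clinical <- data.frame(subject_id = subj_row,
                           true_class = true_class[subj_row],
                           age = age[subj_row], weight = weight[subj_row],
                           height = height[subj_row], PWV = pwv[subj_row],
                           PAS = pas[subj_row], PAD = pad[subj_row],
                           BMI = bmi[subj_row], BPM = bpm[subj_row],
                           TT = tt[subj_row])
    structure(list(pulses = pulses, clinical = clinical,
                   labels = true_class[subj_row], config = config),
              class = "dvp_synth_dataset")
  })
}

#' @export
print.dvp_synth_dataset <- function(x, ...) {
  cat("Synthetic DVP dataset:", length(x$pulses), "pulses from",
      x$config$n_subjects, "subjects\n")
  cat("Planted class counts:\n")
  print(table(factor(x$labels, levels = 1:4)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Pulses go to `pulses.csv` (one pulse per row; rows may have different
#' lengths before normalization) and the covariates to `clinical.csv` with
#' header `subject_id,true_class,age,weight,height,PWV,PAS,PAD,BMI,BPM,TT`.
#'
#' @param dataset A `dvp_synth_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "dvp_synth_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lines <- vapply(dataset$pulses,
                  function(p) paste(format(p, digits = 10, trim = TRUE),
                                    collapse = ","),
                  character(1))
  writeLines(lines, file.path(dir, "pulses.csv"))
  write.csv(dataset$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read ragged pulse rows from CSV
#'
#' @param path CSV file with one comma-separated pulse per line (lengths may
#'   differ between lines).
#' @return List of numeric vectors.
#' @export
read_pulses_csv <- function(path) {
  lapply(strsplit(readLines(path), ","), as.numeric)
}
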