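test_that("class templates grade notch and diastolic wave from class 1 to 4", {
  tpl <- make_class_templates()
  dia <- vapply(tpl, `[[`, numeric(1), "diastolic_amp")
  notch <- vapply(tpl, `[[`, numeric(1), "notch_depth")
  expect_true(all(diff(dia) < 0))
  expect_true(all(diff(notch) < 0))
  expect_identical(dia[4], 0)
  expect_identical(notch[4], 0)
  for (p in tpl) {
    expect_gt(p$systolic_amp, p$reflected_amp)
    expect_gte(p$reflected_amp, 0)
    expect_lt(p$systolic_center, p$reflected_center)
    expect_lt(p$reflected_center, p$diastolic_center)
  }
})

test_that("rendered templates show the expected peak structure", {
  tpl <- make_class_templates()
  n_max <- function(x) {
    i <- 2:(length(x) - 1L)
    sum(x[i] > x[i - 1L] & x[i] > x[i + 1L])
  }
  waves <- lapply(tpl, render_template)
  expect_gte(n_max(waves[[1]]), 2)        # marked notch + diastolic peak
  expect_identical(n_max(waves[[4]]), 1L) # single broad wave
  for (w in waves) {
    expect_equal(min(w), 0)
    expect_equal(max(w), 1)
  }
})

test_that("generate_pulse attenuates the diastolic wave with age", {
  tpl <- make_class_templates()
  young <- render_template(tpl[[1]], age = 20, normalize = FALSE)
  old <- render_template(tpl[[1]], age = 80, normalize = FALSE)
  dia_win <- 55:75  # around the diastolic center
  expect_gt(max(young[dia_win]), max(old[dia_win]))
})

test_that("generate_pulse is seeded-deterministic and validates age", {
  tpl <- make_class_templates()
  set.seed(4); p1 <- generate_pulse(tpl[[2]], 40)
  set.seed(4); p2 <- generate_pulse(tpl[[2]], 40)
  expect_identical(p1, p2)
  expect_true(length(p1) >= 60 && length(p1) <= 140)
  expect_error(generate_pulse(tpl[[1]], 15), "vascular_age")
  expect_error(generate_pulse(tpl[[1]], 90), "vascular_age")
})

test_that("noise-free class-4 pulses are single-peaked at any age", {
  tpl <- make_class_templates()
  for (age in c(19, 50, 83)) {
    p <- generate_pulse(tpl[[4]], age, noise_sd = 0, n_samples = 100)
    i <- 2:99
    expect_identical(sum(p[i] > p[i - 1] & p[i] > p[i + 1]), 1L)
  }
})

test_that("dataset covariate means recover the population targets", {
  ds <- generate_dataset(synthetic_config(n_subjects = 10000L,
                                          pulses_per_subject = 1L, seed = 7))
  targets <- list(age = c(44.31, 14.34), weight = c(74.60, 16.99),
                  height = c(170.04, 8.45), PWV = c(7.99, 2.91),
                  PAS = c(124.77, 16.01), PAD = c(76.10, 9.73),
                  BMI = c(25.78, 5.12), BPM = c(71.82, 14.89))
  for (v in names(targets)) {
    se <- targets[[v]][2] / sqrt(10000)
    expect_lt(abs(mean(ds$clinical[[v]]) - targets[[v]][1]), 3 * se,
              label = paste("mean of", v))
  }
  expect_lt(abs(mean(ds$clinical$age) - 44.31), 1.0)
  expect_lt(abs(mean(ds$clinical$PWV) - 7.99), 0.3)
})

test_that("dataset generation is a pure function of its config", {
  cfg <- synthetic_config(n_subjects = 12L, pulses_per_subject = 3L, seed = 3)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$clinical, d2$clinical)
  expect_identical(d1$pulses, d2$pulses)
  expect_identical(d1$labels, d2$labels)
})

test_that("degenerate class mixture plants a single class", {
  ds <- generate_dataset(synthetic_config(n_subjects = 20L,
                                          pulses_per_subject = 2L,
                                          class_mixture = c(1, 0, 0, 0),
                                          seed = 2))
  expect_true(all(ds$labels == 1L))
  expect_error(synthetic_config(class_mixture = c(0.5, 0.5, 0.5, 0.5)),
               "class_mixture")
})

test_that("clinical table aligns with pulses and respects bounds", {
  ds <- generate_dataset(synthetic_config(n_subjects = 30L,
                                          pulses_per_subject = 4L, seed = 9))
  expect_identical(nrow(ds$clinical), length(ds$pulses))
  expect_identical(ds$clinical$true_class, ds$labels)
  expect_true(all(ds$clinical$age >= 19.48 & ds$clinical$age <= 83))
  expect_true(all(ds$clinical$PWV >= 3.70 & ds$clinical$PWV <= 26.10))
  expect_true(all(ds$clinical$BMI >= 6 & ds$clinical$BMI <= 56))
  # pulses of one subject share one class
  by_subj <- split(ds$labels, ds$clinical$subject_id)
  expect_true(all(vapply(by_subj, function(x) length(unique(x)) == 1L,
                         logical(1))))
})

test_that("transit time is strictly decreasing in PWV for a fixed path", {
  pwv <- seq(4, 26, by = 0.5)
  tt <- tt_from_pwv(pwv)
  expect_true(all(diff(tt) < 0))
  expect_equal(tt_from_pwv(10, path_constant = 1000), 100)
})

test_that("age tilts class membership toward higher classes", {
  ds <- generate_dataset(synthetic_config(n_subjects = 3000L,
                                          pulses_per_subject = 1L, seed = 13))
  young <- ds$clinical$age < 35
  old <- ds$clinical$age > 55
  expect_gt(mean(ds$labels[old]), mean(ds$labels[young]))
})

test_that("dataset round-trips through the CSV writer", {
  ds <- generate_dataset(synthetic_config(n_subjects = 5L,
                                          pulses_per_subject = 2L, seed = 1))
  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  pulses <- read_pulses_csv(file.path(dir, "pulses.csv"))
  expect_identical(length(pulses), length(ds$pulses))
  expect_equal(pulses[[3]], ds$pulses[[3]], tolerance = 1e-8)
  clin <- read.csv(file.path(dir, "clinical.csv"))
  expect_identical(names(clin),
                   c("subject_id", "true_class", "age", "weight", "height",
                     "PWV", "PAS", "PAD", "BMI", "BPM", "TT"))
})
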