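# Alpha feature, calibration, BBA prediction, BR index and trajectory
# labels.

make_spectrum <- function(power_by_freq, labels = "O1") {
  freqs <- seq(0, 128, by = 0.5)
  p <- matrix(0, nrow = length(labels), ncol = length(freqs))
  for (f in names(power_by_freq)) {
    p[, freqs == as.numeric(f)] <- power_by_freq[[f]]
  }
  structure(list(freqs_hz = freqs, power = p, n_segments_used = 1,
                 window = "hann", channel_labels = labels),
            class = "power_spectrum")
}

test_that("alpha center of gravity matches hand arithmetic", {
  # all band power in one bin
  s1 <- make_spectrum(list(`9.5` = 2))
  expect_equal(extract_alpha_feature(s1, electrodes = "O1")$value_hz, 9.5)
  # power 1 at 8 Hz, 3 at 12 Hz: (8*1 + 12*3)/4 = 11
  s2 <- make_spectrum(list(`8` = 1, `12` = 3))
  expect_equal(extract_alpha_feature(s2, electrodes = "O1")$value_hz, 11.0)
  # flat power across the band: symmetry midpoint 10
  s3 <- make_spectrum(as.list(setNames(rep(1, 13), seq(7, 13, 0.5))))
  expect_equal(extract_alpha_feature(s3, electrodes = "O1")$value_hz, 10.0)
})

test_that("zero-band-power channels are excluded with a warning", {
  freqs <- seq(0, 128, by = 0.5)
  p <- rbind(ifelse(freqs == 10, 1, 0), 0)
  s <- structure(list(freqs_hz = freqs, power = p, n_segments_used = 1,
                      window = "hann", channel_labels = c("O1", "O2")),
                 class = "power_spectrum")
  expect_warning(f <- extract_alpha_feature(s, electrodes = c("O1", "O2")),
                 "zero alpha-band power")
  expect_equal(f$value_hz, 10)
  p0 <- s; p0$power[] <- 0
  expect_error(suppressWarnings(
    extract_alpha_feature(p0, electrodes = c("O1", "O2"))), "all electrodes")
})

test_that("two-point calibration is exact and degenerate fits error", {
  feats <- c(10.5, 10.5, 8.4, 8.4)
  cas <- c(20, 20, 90, 90)
  m <- fit_calibration(feats, cas)
  expect_equal(m$slope, 70 / -2.1, tolerance = 1e-9)   # -33.333 y/Hz
  expect_equal(m$intercept, 370, tolerance = 1e-6)
  expect_equal(m$fit_residual_sd, 0, tolerance = 1e-9)

  expect_error(fit_calibration(rep(10, 5), 1:5), "zero variance")
  expect_error(fit_calibration(c(10, 11), c(20, 30)), "n >= 3")
})

test_that("noiseless calibration inverts the generator mapping exactly", {
  eeg <- eeg_config()
  bba <- seq(20, 90, length.out = 50)
  m <- fit_calibration(alpha_from_bba(bba, eeg), bba)
  expect_equal(m$slope, 1 / eeg$alpha_age_slope, tolerance = 1e-9)
  expect_equal(m$fit_residual_sd, 0, tolerance = 1e-8)
  # fitted line is the exact inverse mapping
  expect_equal(m$intercept + m$slope * alpha_from_bba(55, eeg), 55,
               tolerance = 1e-9)
})

test_that("noisy calibration recovers the attenuation-corrected slope", {
  # Regressing CA on a noisy feature attenuates the slope by the
  # reliability lambda = var(f_true) / (var(f_true) + noise^2); the fitted
  # slope must match that prediction, and at the package default noise
  # (0.075 Hz) the attenuation is under 2%, i.e. slope within 5% of the
  # inverse mapping.
  eeg <- eeg_config()
  beta <- 1 / eeg$alpha_age_slope
  set.seed(31)
  ca <- runif(4000, 16, 100)
  f_true <- alpha_from_bba(ca, eeg)
  for (noise in c(0.2, eeg$feature_noise_sd_hz)) {
    m <- fit_calibration(f_true + rnorm(length(ca), 0, noise), ca)
    lambda <- var(f_true) / (var(f_true) + noise^2)
    expect_lt(abs(m$slope - beta * lambda) / abs(beta * lambda), 0.03)
    expect_lt(m$slope, 0)   # slower alpha => older prediction
  }
  m_def <- fit_calibration(
    f_true + rnorm(length(ca), 0, eeg$feature_noise_sd_hz), ca)
  expect_lt(abs(m_def$slope - beta) / abs(beta), 0.05)
})

test_that("BBA prediction, clamping and flags follow the model arithmetic", {
  m <- structure(list(intercept = 370, slope = -100 / 3, n_train = 4,
                      feature_range = c(8.4, 10.5), fit_residual_sd = 0),
                 class = "calibration_model")
  r <- predict_bba(m, 9.45, ca = 52)
  expect_equal(r$bba_years, 55, tolerance = 1e-9)
  expect_equal(r$gap_years, 3, tolerance = 1e-9)
  expect_false(r$clamped)

  # feature implying an age below 16 clamps with a flag
  r2 <- predict_bba(m, 10.74, ca = 30)    # raw = 12.0 years
  expect_equal(r2$bba_years, 16)
  expect_true(r2$clamped)
  expect_true("clamped" %in% r2$confidence_flags)
  expect_true("extrapolation" %in% r2$confidence_flags)

  # model-implied feature for the CA gives gap 0 and BR 0
  f_ca <- (52 - 370) / (-100 / 3)
  r3 <- predict_bba(m, f_ca, ca = 52)
  expect_equal(r3$gap_years, 0, tolerance = 1e-9)
  expect_equal(r3$br_percent, 0, tolerance = 1e-9)
})

test_that("BR is the gap on the 84-year scale with the documented sign", {
  expect_equal(compute_br(54.1, 46.3), 100 * 7.8 / 84, tolerance = 1e-9)
  expect_equal(round(compute_br(54.1, 46.3), 3), 9.286)
  expect_equal(round(compute_br(42.2, 51.4), 3), -10.952)
  expect_equal(compute_br(70, 70), 0)
  # affine in (ca - bba) with coefficient 100/84, BR(ca, ca) = 0
  for (ca in c(30, 50, 90)) {
    expect_equal(compute_br(ca, ca), 0)
    expect_equal(compute_br(ca, ca - 8.4), 10, tolerance = 1e-9)
  }
  expect_error(compute_br(12, 50), "argument error")
  expect_error(compute_br(50, 101), "argument error")
})

test_that("trajectory labels implement the rejuvenation/deceleration rules", {
  mk <- function(bba, ca) {
    structure(list(bba_years = bba, ca_years = ca), class = "bba_result")
  }
  expect_identical(classify_trajectory(mk(50, 50), mk(48, 51)), "rejuvenation")
  expect_identical(classify_trajectory(mk(50, 50), mk(51, 51)), "normal")
  expect_identical(classify_trajectory(mk(50, 50), mk(50.5, 51.08)),
                   "deceleration")
  expect_identical(classify_trajectory(mk(50, 50), mk(52, 51)), "acceleration")
  expect_error(classify_trajectory(mk(50, 50), mk(49, 50)), "data error")
})

test_that("calibration models serialize to JSON and back", {
  m <- fit_calibration(c(10.5, 9.3, 8.4), c(20, 60, 90))
  p <- tempfile(fileext = ".json")
  write_calibration(m, p)
  m2 <- read_calibration(p)
  expect_equal(m2$slope, m$slope, tolerance = 1e-12)
  expect_equal(m2$feature_range, m$feature_range, tolerance = 1e-12)
})
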