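# Filtering contract, segmentation arithmetic and artifact rejection.

db_ratio <- function(after, before) 20 * log10(after / before)
mid_rms <- function(x) sqrt(mean(x[round(length(x) * 0.2):
                                    round(length(x) * 0.8)]^2))

test_that("band-pass keeps the passband, rejects stopband and DC", {
  r10 <- tone_recording(10, amp = 1, dur_s = 10)
  out <- bandpass(r10)
  expect_lt(abs(db_ratio(mid_rms(out$data[1, ]), mid_rms(r10$data[1, ]))), 1)

  r60 <- tone_recording(60, amp = 1, dur_s = 10)
  out60 <- bandpass(r60)
  expect_lt(db_ratio(mid_rms(out60$data[1, ]), mid_rms(r60$data[1, ])), -20)

  rdc <- new_recording(matrix(100, 1, 2560), "O1", 256)
  outdc <- bandpass(rdc)
  expect_lt(max(abs(outdc$data[1, 500:2000])), 1)

  expect_error(bandpass(r10, low = 30, high = 0.5), "inverted")
  expect_error(bandpass(r10, low = 1, high = 200), "Nyquist")
})

test_that("notch removes the mains line and spares its neighbours", {
  for (f in c(45, 55, 10)) {
    r <- tone_recording(f, dur_s = 10)
    out <- notch(r)
    expect_lt(abs(db_ratio(mid_rms(out$data[1, ]), mid_rms(r$data[1, ]))), 1)
  }
  r50 <- tone_recording(50, dur_s = 10)
  out50 <- notch(r50)
  expect_lt(db_ratio(mid_rms(out50$data[1, ]), mid_rms(r50$data[1, ])), -20)

  # mixed 10 + 50 Hz: only the 50 Hz line disappears from the spectrum
  t <- seq_len(256 * 20) / 256
  mix <- new_recording(matrix(sin(2 * pi * 10 * t) + sin(2 * pi * 50 * t),
                              nrow = 1), "O1", 256)
  s <- compute_spectrum(segment_recording(notch(mix)))
  p10 <- sum(s$power[1, s$freqs_hz >= 9 & s$freqs_hz <= 11])
  p50 <- sum(s$power[1, s$freqs_hz >= 49 & s$freqs_hz <= 51])
  expect_equal(p10, 0.5, tolerance = 0.02)   # the 10 Hz component survives
  expect_lt(p50 / p10, 1e-3)                 # the 50 Hz line is gone

  expect_error(notch(tone_recording(10), f0 = 200), "Nyquist")
})

test_that("filtering is idempotent within tolerance in the passband", {
  rec <- synthesize_recording(50, quiet_eeg(duration_s = 20), seed = 4)
  once <- bandpass(rec)
  twice <- bandpass(once)
  r1 <- mid_rms(once$data[1, ])
  r2 <- mid_rms(twice$data[1, ])
  expect_lt(abs(r2 - r1) / r1, 0.01)
})

test_that("segmentation arithmetic matches the overlap contract", {
  rec6 <- new_recording(matrix(0, 1, 92160), "O1", 256)
  segs <- segment_recording(rec6)     # 2 s, 50% overlap
  expect_identical(segs$L, 512L)
  expect_identical(segs$step, 256L)
  expect_length(segs$segments, 359)

  one <- segment_recording(new_recording(matrix(1, 1, 512), "O1", 256))
  expect_length(one$segments, 1)

  two <- segment_recording(new_recording(matrix(1, 1, 1024), "O1", 256),
                           overlap = 0)
  expect_length(two$segments, 2)

  expect_error(segment_recording(rec6, overlap = 1), "overlap")
  expect_error(segment_recording(new_recording(matrix(1, 1, 100), "O1", 256)),
               "shorter")
})

test_that("concatenating non-overlapping segments reproduces the recording", {
  rec <- synthesize_recording(60, quiet_eeg(duration_s = 10), seed = 6)
  segs <- segment_recording(rec, overlap = 0)
  rebuilt <- do.call(cbind, segs$segments)
  expect_identical(rebuilt, rec$data[, seq_len(ncol(rebuilt))])
})

test_that("rejection criteria flag the right segments for the right reasons", {
  clean <- synthesize_recording(50, quiet_eeg(duration_s = 20), seed = 7)
  segs <- reject_artifacts(segment_recording(clean))
  expect_true(all(segs$retained_mask))

  # all-zero channel: every segment is a flatline
  flat <- new_recording(rbind(clean$data[1, ], 0), c("O1", "O2"), 256)
  expect_error(reject_artifacts(segment_recording(flat)), "all segments")
  segs_f <- segment_recording(flat)
  reasons <- tryCatch(reject_artifacts(segs_f), error = function(e) NULL)
  expect_null(reasons)

  # one big excursion: peak-to-peak rejection localized to its segments
  spiky <- clean
  spiky$data[1, 2560:2660] <- spiky$data[1, 2560:2660] + 500
  segs_s <- reject_artifacts(segment_recording(spiky))
  expect_false(all(segs_s$retained_mask))
  bad <- which(!segs_s$retained_mask)
  expect_true(all(grepl("peak_to_peak|jump", segs_s$rejection_reasons[bad])))
  # excursion sits near 10 s; rejected segments must overlap it
  bad_starts <- segs_s$starts[bad] / 256
  expect_true(all(bad_starts > 7 & bad_starts < 11))
})

test_that("lowering the peak-to-peak threshold never increases retention", {
  rec <- synthesize_recording(50, eeg_config(duration_s = 30,
                                             artifact_rate_per_min = 4),
                              seed = 8)
  rec <- bandpass(notch(rec))
  thresholds <- c(200, 150, 100, 80, 60)
  retained <- vapply(thresholds, function(th) {
    segs <- tryCatch(
      reject_artifacts(segment_recording(rec),
                       rejection_criteria(max_peak_to_peak_uV = th)),
      error = function(e) NULL)
    if (is.null(segs)) 0L else sum(segs$retained_mask)
  }, integer(1))
  expect_true(all(diff(retained) <= 0))
})

test_that("injected artifact events are caught by the rejection stage", {
  eeg <- eeg_config(duration_s = 60, artifact_rate_per_min = 6)
  caught <- total <- 0
  for (seed in 1:5) {
    rec <- synthesize_recording(50, eeg, seed = seed)
    if (nrow(rec$annotations) == 0) next
    filt <- bandpass(notch(rec))
    segs <- reject_artifacts(segment_recording(filt))
    # segments containing an event's central (peak) sample
    centers <- rec$annotations$onset_s + rec$annotations$duration_s / 2
    for (cs in centers) {
      hit <- which(segs$starts / 256 <= cs &
                     (segs$starts + segs$L - 1) / 256 >= cs)
      total <- total + 1
      if (any(!segs$retained_mask[hit])) caught <- caught + 1
    }
  }
  expect_gt(total, 5)
  expect_gte(caught / total, 0.8)
})

test_that("artifact event counts follow the configured Poisson rate", {
  counts <- vapply(1:40, function(s) {
    art <- inject_artifacts(matrix(0, 19, 256 * 120), channels_1020, 256,
                            rate_per_min = 10, seed = s)
    nrow(art$events)
  }, numeric(1))
  # rate 10/min for 120 s => Poisson(20): mean within 4 SE
  expect_lt(abs(mean(counts) - 20), 4 * sqrt(20 / 40))
  art0 <- inject_artifacts(matrix(1, 2, 1000), c("O1", "O2"), 256, 0)
  expect_identical(art0$data, matrix(1, 2, 1000))
  expect_identical(nrow(art0$events), 0L)
})
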