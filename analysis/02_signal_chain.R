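#!/usr/bin/env Rscript
# Step 2: demonstrate the raw-EEG signal chain on a handful of synthetic
# subjects: synthesize 19-channel recordings (EDF), filter, segment,
# reject artifacts, average spectra, and extract the alpha feature.
#
# Finds: the extracted alpha center of gravity tracks the frequency
# implied by each subject's true brain age to within a few hundredths of
# a Hz, and injected artifacts are rejected.

suppressMessages(library(qeegage))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

dir.create("results/signal_demo", recursive = TRUE, showWarnings = FALSE)
eeg <- eeg_config(duration_s = 120, artifact_rate_per_min = 2)
true_bbas <- c(25, 45, 65, 85)

rows <- list()
for (i in seq_along(true_bbas)) {
  rec <- synthesize_recording(true_bbas[i], eeg, seed = seed * 100 + i,
                              subject_id = sprintf("demo_%02d", i))
  edf <- sprintf("results/signal_demo/demo_%02d.edf", i)
  write_edf(rec, edf)
  rec2 <- read_recording(edf)            # exercise the EDF round trip
  stopifnot(validate_montage(rec2, min_duration_s = 60)$ok)
  pr <- process_recording(rec2)
  rows[[i]] <- data.frame(
    subject = rec$subject_id, true_bba = true_bbas[i],
    f_true = alpha_from_bba(true_bbas[i], eeg),
    f_measured = pr$feature$value_hz,
    segments_retained = pr$n_retained,
    segments_rejected = pr$report$n_rejected)
  if (i == 1) {
    write_spectrum_tsv(compute_spectrum(reject_artifacts(
      segment_recording(bandpass(notch(rec2))))),
      "results/signal_demo/demo_01_spectrum.tsv")
  }
}
tab <- do.call(rbind, rows)
write_table_tsv(tab, "results/signal_demo/feature_recovery.tsv")
print(tab, digits = 4)
cat("max |f_measured - f_true|:",
    signif(max(abs(tab$f_measured - tab$f_true)), 3), "Hz\n")
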