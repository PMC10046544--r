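# End-to-end orchestration: generate -> (synthesize/preprocess/spectrum ->
# feature) -> calibrate -> score -> battery, plus Monte-Carlo effect
# recovery across seeded replicates.

#' Run the full signal chain on one recording
#'
#' Notch, band-pass, segmentation, artifact rejection, averaged spectrum,
#' alpha feature — the per-recording analysis path.
#'
#' @param rec a `recording`.
#' @param band,electrodes feature settings.
#' @param criteria rejection criteria ([rejection_criteria()]).
#' @param length_s,overlap segmentation settings.
#' @return list `feature` (`alpha_feature`), `n_retained`, `low_confidence`
#'   (fewer retained segments than `criteria$min_retained`), `report`
#'   (rejection report).
#' @export
process_recording <- function(rec, band = c(7, 13),
                              electrodes = posterior_electrodes,
                              criteria = rejection_criteria(),
                              length_s = 2.0, overlap = 0.5) {
  rec <- notch(rec)
  rec <- bandpass(rec)
  segs <- segment_recording(rec, length_s = length_s, overlap = overlap)
  segs <- reject_artifacts(segs, criteria)
  spec <- compute_spectrum(segs)
  feat <- extract_alpha_feature(spec, band = band, electrodes = electrodes)
  list(feature = feat,
       n_retained = sum(segs$retained_mask),
       low_confidence = sum(segs$retained_mask) < criteria$min_retained,
       report = rejection_report(segs))
}

# Feature measurement for every subject-visit of a generated cohort. At
# feature fidelity the generator's noisy feature is used directly; at
# signal fidelity a recording is synthesized around it (so both fidelities
# share physiological feature noise) and the full chain re-measures it.
measure_features <- function(gen, cfg, out_dir = NULL, keep_edf = FALSE) {
  cohort <- gen$cohort
  reports <- list()
  if (identical(cfg$fidelity, "signal")) {
    for (i in seq_len(nrow(cohort))) {
      rec <- synthesize_recording(
        gen$truth$true_bba[i], cfg$eeg,
        seed = child_seed(cfg$seed, 5000L + i),
        subject_id = cohort$subject_id[i], visit = cohort$visit[i],
        alpha_hz = gen$truth$true_feature[i])
      if (keep_edf && !is.null(out_dir)) {
        write_edf(rec, file.path(out_dir, sprintf(
          "%s_%s.edf", cohort$subject_id[i], cohort$visit[i])))
      }
      pr <- process_recording(rec, band = cfg$band,
                              electrodes = cfg$electrodes)
      cohort$feature[i] <- pr$feature$value_hz
      reports[[length(reports) + 1]] <- pr$report
    }
  }
  list(cohort = cohort, reports = reports)
}

#' Run the whole analysis pipeline from one configuration
#'
#' Generates the cohort (and, at signal fidelity, the synthetic EEG run
#' through the full signal chain), calibrates the age model on an
#' independent reference cohort, scores every subject-visit, runs the
#' comparison battery, and writes all artifacts plus a machine-readable
#' manifest (seed, config hash, file checksums) to `out_dir`. Re-running
#' with the same configuration reproduces all numeric outputs exactly.
#'
#' @param cfg generator configuration (see [paper_profile()]).
#' @param out_dir output directory (created if needed).
#' @param keep_edf also write per-recording EDF files (signal fidelity).
#' @return invisibly, a list with `scored`, `truth`, `model`, `battery`,
#'   `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir, keep_edf = FALSE) {
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_cohort(cfg)
  mf <- measure_features(gen, cfg, out_dir, keep_edf)
  model <- calibrate_reference(cfg)
  scored <- score_cohort(mf$cohort, model, cfg$age_range)
  battery <- run_battery(scored)

  files <- c(cohort = "cohort.tsv", truth = "truth.tsv",
             scored = "cohort_scored.tsv", calibration = "calibration.json",
             battery_tsv = "battery.tsv", battery_json = "battery.json",
             config = "config.yaml")
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  write_table_tsv(gen$cohort, paths["cohort"])
  write_table_tsv(gen$truth, paths["truth"])
  write_table_tsv(scored, paths["scored"])
  write_calibration(model, paths["calibration"])
  write_table_tsv(as.data.frame(battery), paths["battery_tsv"])
  write_json_file(as.data.frame(battery), paths["battery_json"])
  write_config(cfg, paths["config"])
  if (length(mf$reports)) {
    rp <- file.path(out_dir, "rejection_reports.json")
    write_json_file(mf$reports, rp)
    paths <- c(paths, rejection = rp)
  }
  manifest <- list(
    package = "qeegage",
    version = as.character(utils::packageVersion("qeegage")),
    seed = cfg$seed,
    fidelity = cfg$fidelity,
    config_hash = digest_config(cfg),
    files = lapply(stats::setNames(as.list(paths), names(paths)), function(p) {
      list(name = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(scored = scored, truth = gen$truth, model = model,
                 battery = battery, manifest = manifest))
}

# Stable hash of a configuration (via its canonical YAML serialization).
digest_config <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

# Arm-level summaries recovered from one scored replicate.
arm_summaries <- function(scored) {
  wide <- cohort_wide(scored)
  do.call(rbind, lapply(split(wide, wide$arm), function(w) {
    older <- w$gap_pre > 0
    data.frame(arm = w$arm[1],
               n = nrow(w),
               pre_gap = mean(w$gap_pre),
               post_gap = mean(w$gap_post),
               d_bba = mean(w$d_bba),
               d_ca = mean(w$d_ca),
               d_bba_older = if (any(older)) mean(w$d_bba[older]) else NA_real_,
               d_bba_younger = if (any(!older)) mean(w$d_bba[!older])
                               else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Monte-Carlo recovery of the configured intervention effects
#'
#' Runs the feature-level pipeline over `replicates` seeded replicates and
#' reports, per arm, the Monte-Carlo mean and standard error of the
#' recovered quantities (pre/post brain-age gap, mean BBA change, mean CA
#' drift, stratified BBA changes) next to the configured generator truths.
#'
#' @param cfg generator configuration.
#' @param replicates number of replicates (>= 2).
#' @param progress print a dot every 25 replicates.
#' @return list with `summary` (data.frame: arm, quantity, mc_mean, mc_se,
#'   truth) and `per_replicate` (data.frame of arm summaries).
#' @export
recover_effects <- function(cfg, replicates = 200, progress = FALSE) {
  if (replicates < 2) stop("argument error: need at least 2 replicates")
  reps <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- child_seed(cfg$seed, r)
    gen <- generate_cohort(cfg_r)
    model <- calibrate_reference(cfg_r)
    scored <- score_cohort(gen$cohort, model, cfg$age_range)
    s <- arm_summaries(scored)
    s$replicate <- r
    reps[[r]] <- s
    if (progress && r %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  per <- do.call(rbind, reps)
  quantities <- c("pre_gap", "post_gap", "d_bba", "d_ca",
                  "d_bba_older", "d_bba_younger")
  rows <- list()
  for (a in unique(per$arm)) {
    arm_cfg <- cfg$arms[[a]]
    pa <- per[per$arm == a, ]
    truth <- configured_truths(arm_cfg)
    for (q in quantities) {
      v <- pa[[q]]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1]] <- data.frame(
        arm = a, quantity = q,
        mc_mean = mean(v), mc_se = stats::sd(v) / sqrt(length(v)),
        truth = truth[[q]], stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, rows), per_replicate = per)
}

# Population-level truths implied by an arm configuration.
configured_truths <- function(arm) {
  p <- round(arm$n_subjects * arm$p_older) / arm$n_subjects
  d_bba <- p * arm$effect_mean_older + (1 - p) * arm$effect_mean_younger
  pre_gap <- p * arm$gap_mean_older + (1 - p) * arm$gap_mean_younger
  d_ca <- arm$followup_mean / 12
  list(pre_gap = pre_gap,
       post_gap = pre_gap + d_bba - d_ca,
       d_bba = d_bba, d_ca = d_ca,
       d_bba_older = arm$effect_mean_older,
       d_bba_younger = arm$effect_mean_younger)
}
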