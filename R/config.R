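#' Standard 10-20 channel labels used by the study montage
#'
#' The 19 scalp locations of the International 10-20 system recorded with a
#' linked-ears monopolar montage.
#'
#' @format character vector of length 19.
#' @export
channels_1020 <- c("O1", "O2", "P3", "P4", "Pz", "C3", "C4", "Cz",
                   "T3", "T4", "T5", "T6", "Fz", "F3", "F4", "F7", "F8",
                   "Fp1", "Fp2")

#' Default posterior electrode set for the alpha feature
#'
#' Posterior sites carry the dominant resting alpha rhythm; the alpha
#' center-of-gravity feature is averaged over this set by default.
#'
#' @export
posterior_electrodes <- c("O1", "O2", "P3", "P4", "Pz", "T5", "T6")

#' Build one arm block of a generator configuration
#'
#' The baseline brain-age gap (BBA - CA) is modelled as a two-stratum
#' mixture: a fixed number `round(n_subjects * p_older)` of subjects have a
#' positive gap (brain older than CA) drawn from a truncated normal on the
#' positive half-line, the rest a negative gap. Within each stratum the
#' truncated-normal location is solved so the realised stratum mean equals
#' the configured mean despite the physiological bounds (BBA in 16..100).
#' The true intervention effect on BBA is drawn per subject from a normal
#' whose mean depends on the baseline stratum.
#'
#' @param n_subjects number of subjects in the arm.
#' @param ca_mean,ca_sd chronological-age distribution (years), truncated to
#'   `ca_range`.
#' @param ca_range inclusive CA truncation bounds (years).
#' @param female_fraction proportion of females.
#' @param p_older probability (realised as a fixed count) that a subject's
#'   baseline BBA exceeds their CA.
#' @param gap_mean_older,gap_sd_older baseline gap distribution (years) in
#'   the older-brain stratum (gap > 0).
#' @param gap_mean_younger,gap_sd_younger baseline gap distribution (years)
#'   in the younger-brain stratum (gap <= 0).
#' @param effect_mean_older,effect_mean_younger mean true post-minus-pre
#'   change in BBA (years; negative = rejuvenation) per baseline stratum.
#' @param effect_sd SD of the true change (years).
#' @param followup_mean,followup_sd follow-up duration (months), truncated
#'   to `followup_range`.
#' @param followup_range inclusive follow-up bounds (months).
#' @param symptom_rate_pre,symptom_rate_post probability that a subject
#'   reports current health symptoms at each visit (categorical covariate).
#' @return named list (one arm block).
#' @export
arm_config <- function(n_subjects,
                       ca_mean, ca_sd, ca_range = c(25, 77),
                       female_fraction,
                       p_older,
                       gap_mean_older, gap_sd_older,
                       gap_mean_younger, gap_sd_younger,
                       effect_mean_older, effect_mean_younger, effect_sd,
                       followup_mean, followup_sd, followup_range = c(6, 18),
                       symptom_rate_pre = 0.4, symptom_rate_post = 0.3) {
  as.list(environment())
}

#' Default EEG block of the generator configuration
#'
#' Parameters of the synthetic resting-state EEG (signal fidelity) and of
#' the feature-level noise model (feature fidelity). The alpha-age mapping
#' is `f(bba) = alpha_anchor_hz + alpha_age_slope * (bba - 16)`, spanning
#' roughly 10.8 to 8.3 Hz over ages 16-100 so the feature stays inside the
#' 7-13 Hz analysis band.
#'
#' @param duration_s recording length in seconds.
#' @param n_channels,fs_hz montage size and sampling rate.
#' @param alpha_age_slope slope of the alpha-age mapping (Hz/year, <= 0).
#' @param alpha_anchor_hz alpha frequency at brain age 16 (Hz).
#' @param alpha_amp_uV,alpha_amp_anterior_uV alpha amplitude over posterior
#'   and anterior channels (microvolts).
#' @param am_depth fractional depth of the slow random amplitude modulation.
#' @param pink_noise_exponent spectral exponent beta of the 1/f^beta
#'   background.
#' @param pink_noise_amp_uV RMS amplitude of the background (microvolts).
#' @param line_noise_amp_uV,line_freq_hz mains interference sinusoid.
#' @param artifact_rate_per_min Poisson rate of injected artifact events.
#' @param feature_noise_sd_hz SD of the per-visit alpha-feature measurement
#'   noise (Hz); physiological session-to-session variation.
#' @param within_subject_corr correlation of the feature noise between a
#'   subject's two visits (shared-component model).
#' @return named list (EEG block).
#' @export
eeg_config <- function(duration_s = 360, n_channels = 19, fs_hz = 256,
                       alpha_age_slope = -0.03, alpha_anchor_hz = 10.8,
                       alpha_amp_uV = 20, alpha_amp_anterior_uV = 8,
                       am_depth = 0.3,
                       pink_noise_exponent = 1, pink_noise_amp_uV = 5,
                       line_noise_amp_uV = 2, line_freq_hz = 50,
                       artifact_rate_per_min = 2,
                       feature_noise_sd_hz = 0.075,
                       within_subject_corr = 0.6) {
  as.list(environment())
}

#' Generator configuration emulating the published study conditions
#'
#' Encodes the two-arm structure: a nutraceuticals arm (n = 42, CA
#' 54.1 +/- 13 y, 73.8% female, baseline gap mean -7.86 y with 15/42
#' subjects in the older-brain stratum, stratum effects -6.77 / -0.64 y,
#' follow-up 13 +/- 1.13 months) and a lifestyle arm (n = 47, CA 45.2 +/-
#' 7.3 y, 53.2% female, baseline gap mean -7.49 y with 13/47 older-brain,
#' stratum effects +0.25 / -0.13 y, follow-up 13.5 +/- 1.10 months).
#' Older-stratum gap moments (mean +8.82, sd 7.73 y) derive from the pooled
#' stratified baseline table (BR -10.5 +/- 9.2 % on the 84-year scale); each
#' arm's younger-stratum mean is solved so the arm-level baseline gap mean
#' is reproduced exactly:
#' `gap_mean_younger = (arm_gap - p_older * gap_mean_older) / (1 - p_older)`.
#'
#' @param seed integer seed stored in the configuration.
#' @param fidelity `"feature"` (emit the alpha feature directly) or
#'   `"signal"` (synthesize raw EEG and run the full signal chain).
#' @param eeg optional EEG block overriding [eeg_config()] defaults.
#' @return a generator configuration list with blocks `arms`, `eeg`,
#'   `reference`, `band`, `electrodes`, `age_range`.
#' @export
paper_profile <- function(seed = 1L, fidelity = "feature", eeg = eeg_config()) {
  gap_old_mean <- 0.84 * 10.5   # Table-2 older stratum BR -10.5% on 84-y scale
  gap_old_sd <- 0.84 * 9.2
  gap_young_sd <- 0.84 * 11.0
  young_mean <- function(arm_gap, p_older) {
    (arm_gap - p_older * gap_old_mean) / (1 - p_older)
  }
  cfg <- list(
    seed = as.integer(seed),
    fidelity = fidelity,
    arms = list(
      nutraceuticals = arm_config(
        n_subjects = 42, ca_mean = 54.1, ca_sd = 13,
        female_fraction = 0.738, p_older = 15 / 42,
        gap_mean_older = gap_old_mean, gap_sd_older = gap_old_sd,
        gap_mean_younger = young_mean(-7.86, 15 / 42),
        gap_sd_younger = gap_young_sd,
        effect_mean_older = -6.77, effect_mean_younger = -0.64,
        effect_sd = 2.5,
        followup_mean = 13, followup_sd = 1.13,
        symptom_rate_pre = 0.333, symptom_rate_post = 0.047),
      lifestyle = arm_config(
        n_subjects = 47, ca_mean = 45.2, ca_sd = 7.3,
        female_fraction = 0.532, p_older = 13 / 47,
        gap_mean_older = gap_old_mean, gap_sd_older = gap_old_sd,
        gap_mean_younger = young_mean(-7.49, 13 / 47),
        gap_sd_younger = gap_young_sd,
        effect_mean_older = 0.25, effect_mean_younger = -0.13,
        effect_sd = 2.5,
        followup_mean = 13.5, followup_sd = 1.10,
        symptom_rate_pre = 0.402, symptom_rate_post = 0.32)
    ),
    eeg = eeg,
    reference = list(n = 400, ca_range = c(16, 100)),
    band = c(7, 13),
    electrodes = posterior_electrodes,
    age_range = c(16, 100)
  )
  validate_config(cfg)
  cfg
}

#' Zero-effect (null) configuration
#'
#' The paper profile with all true intervention effects and their spread set
#' to zero and deterministic follow-up; used for type-I-error and null
#' recovery simulations.
#'
#' @inheritParams paper_profile
#' @param zero_followup_sd if `TRUE` the follow-up duration is fixed at its
#'   mean.
#' @export
null_profile <- function(seed = 1L, fidelity = "feature",
                         zero_followup_sd = FALSE) {
  cfg <- paper_profile(seed = seed, fidelity = fidelity)
  for (a in names(cfg$arms)) {
    cfg$arms[[a]]$effect_mean_older <- 0
    cfg$arms[[a]]$effect_mean_younger <- 0
    cfg$arms[[a]]$effect_sd <- 0
    if (zero_followup_sd) cfg$arms[[a]]$followup_sd <- 0
  }
  cfg
}

#' Validate a generator configuration
#'
#' @param cfg configuration list as returned by [paper_profile()].
#' @return `cfg`, invisibly; errors name the offending field.
#' @export
validate_config <- function(cfg) {
  ee <- cfg$eeg
  if (is.null(ee$fs_hz) || ee$fs_hz <= 0) stop_cfg("eeg$fs_hz", "must be > 0")
  if (ee$alpha_age_slope > 0) {
    stop_cfg("eeg$alpha_age_slope", "alpha slows with age; slope must be <= 0")
  }
  if (ee$duration_s <= 2) {
    stop_cfg("eeg$duration_s", "must exceed the 2-s segment length")
  }
  if (ee$within_subject_corr < 0 || ee$within_subject_corr > 1) {
    stop_cfg("eeg$within_subject_corr", "must lie in [0, 1]")
  }
  if (ee$feature_noise_sd_hz < 0) {
    stop_cfg("eeg$feature_noise_sd_hz", "must be >= 0")
  }
  # Feature must stay inside the analysis band across the believable ages.
  fr <- alpha_from_bba(cfg$age_range, ee)
  if (any(fr <= cfg$band[1]) || any(fr >= cfg$band[2])) {
    stop_cfg("eeg$alpha_anchor_hz/alpha_age_slope",
             "alpha-age mapping leaves the analysis band over ages ",
             paste(cfg$age_range, collapse = "-"))
  }
  for (a in names(cfg$arms)) {
    arm <- cfg$arms[[a]]
    pre <- function(f) paste0("arms$", a, "$", f)
    if (arm$n_subjects < 1) stop_cfg(pre("n_subjects"), "must be >= 1")
    if (arm$ca_sd <= 0) stop_cfg(pre("ca_sd"), "must be > 0")
    if (arm$female_fraction < 0 || arm$female_fraction > 1) {
      stop_cfg(pre("female_fraction"), "must lie in [0, 1]")
    }
    if (arm$p_older < 0 || arm$p_older > 1) {
      stop_cfg(pre("p_older"), "must lie in [0, 1]")
    }
    if (arm$effect_sd < 0) stop_cfg(pre("effect_sd"), "must be >= 0")
    if (arm$gap_sd_older <= 0 || arm$gap_sd_younger <= 0) {
      stop_cfg(pre("gap_sd_*"), "must be > 0")
    }
    if (arm$followup_sd < 0) stop_cfg(pre("followup_sd"), "must be >= 0")
    if (diff(arm$followup_range) <= 0) {
      stop_cfg(pre("followup_range"), "must be an increasing interval")
    }
  }
  invisible(cfg)
}

#' Read / write a generator configuration as YAML
#'
#' @param path file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$band <- as.numeric(cfg$band)
  cfg$age_range <- as.numeric(cfg$age_range)
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param cfg configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
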