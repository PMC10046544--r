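# Longitudinal two-arm cohort simulation with ground-truth brain-age
# trajectories. The generator draws, per subject: chronological age (CA)
# from a truncated normal; a baseline brain-age gap (BBA - CA) from a
# two-stratum truncated-normal mixture (older- vs younger-brain phenotype);
# a true intervention effect on BBA whose mean depends on the baseline
# stratum; and a follow-up duration. Post-visit CA advances by exactly
# followup/12 years.

#' Alpha-age mapping
#'
#' Individual alpha frequency implied by a (true) brain biological age:
#' `f(bba) = anchor + slope * (bba - 16)`, about 10.8 Hz at age 16 slowing
#' to 8.3 Hz at 100 with the defaults.
#'
#' @param bba brain age in years.
#' @param eeg EEG block (see [eeg_config()]).
#' @return frequency in Hz.
#' @export
alpha_from_bba <- function(bba, eeg = eeg_config()) {
  eeg$alpha_anchor_hz + eeg$alpha_age_slope * (bba - 16)
}

#' Inverse of the alpha-age mapping
#' @param f_hz alpha frequency (Hz).
#' @inheritParams alpha_from_bba
#' @export
bba_from_alpha <- function(f_hz, eeg = eeg_config()) {
  16 + (f_hz - eeg$alpha_anchor_hz) / eeg$alpha_age_slope
}

# Draw one arm at one replicate. Returns a per-subject data.frame in long
# (visit) format plus truth columns.
generate_arm <- function(arm_name, arm, eeg, age_range, seed) {
  with_seed(seed, {
    n <- arm$n_subjects
    ca <- rtnorm(n, arm$ca_mean, arm$ca_sd, arm$ca_range[1], arm$ca_range[2])
    sex <- ifelse(seq_len(n) <= round(n * arm$female_fraction), "F", "M")
    sex <- sample(sex)

    # Baseline gap: fixed stratum sizes, per-subject truncation keeping
    # BBA inside [16, 100], location solved to realise the stratum mean.
    n_old <- round(n * arm$p_older)
    stratum <- sample(rep(c("older", "younger"), c(n_old, n - n_old)))
    gap <- numeric(n)
    io <- stratum == "older"
    if (any(io)) {
      lo <- rep(0, sum(io)); hi <- age_range[2] - ca[io]
      mu <- solve_tnorm_location(arm$gap_mean_older, arm$gap_sd_older, lo, hi)
      gap[io] <- rtnorm(sum(io), mu, arm$gap_sd_older, lo, hi)
    }
    if (any(!io)) {
      lo <- age_range[1] - ca[!io]; hi <- rep(0, sum(!io))
      mu <- solve_tnorm_location(arm$gap_mean_younger, arm$gap_sd_younger,
                                 lo, hi)
      gap[!io] <- rtnorm(sum(!io), mu, arm$gap_sd_younger, lo, hi)
    }
    bba_pre <- ca + gap

    effect_mean <- ifelse(io, arm$effect_mean_older, arm$effect_mean_younger)
    change <- stats::rnorm(n, effect_mean, arm$effect_sd)
    followup <- rtnorm(n, arm$followup_mean, arm$followup_sd,
                       arm$followup_range[1], arm$followup_range[2])
    ca_post <- ca + followup / 12
    bba_post_raw <- bba_pre + change
    bba_post <- pmin(pmax(bba_post_raw, age_range[1]), age_range[2])

    symptoms_pre <- stats::runif(n) < arm$symptom_rate_pre
    symptoms_post <- stats::runif(n) < arm$symptom_rate_post

    # Feature measurement noise: shared-component model so that the
    # correlation between a subject's two visits equals within_subject_corr
    # while each visit's marginal SD is feature_noise_sd_hz.
    rho <- eeg$within_subject_corr
    u <- stats::rnorm(n)
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    sd_f <- eeg$feature_noise_sd_hz
    e_pre <- sd_f * (sqrt(rho) * u + sqrt(1 - rho) * z1)
    e_post <- sd_f * (sqrt(rho) * u + sqrt(1 - rho) * z2)

    id <- sprintf("%s_%03d", substr(arm_name, 1, 3), seq_len(n))
    long <- function(visit, ca_v, bba_v, err, sympt) {
      data.frame(
        subject_id = id, arm = arm_name, sex = sex, visit = visit,
        ca = ca_v, followup_months = followup,
        true_bba = bba_v, true_gap = bba_v - ca_v,
        baseline_stratum = stratum,
        true_feature = alpha_from_bba(bba_v, eeg) + err,
        symptoms = sympt,
        bba_clamped = (visit == "post") &
          (bba_post_raw < age_range[1] | bba_post_raw > age_range[2]),
        stringsAsFactors = FALSE)
    }
    rbind(long("pre", ca, bba_pre, e_pre, symptoms_pre),
          long("post", ca_post, bba_post, e_post, symptoms_post))
  })
}

#' Generate a longitudinal two-arm cohort
#'
#' Draws subject metadata, ground-truth brain-age trajectories and (at
#' feature fidelity) noisy alpha-feature measurements for every subject and
#' visit. Deterministic given `cfg$seed`; the post-visit CA equals the
#' pre-visit CA plus exactly `followup_months / 12`.
#'
#' @param cfg generator configuration (see [paper_profile()]).
#' @return list with elements `cohort` (one row per subject-visit with
#'   columns `subject_id, arm, sex, visit, ca, followup_months, feature`)
#'   and `truth` (same keys plus `true_bba`, `true_gap`, `true_feature`,
#'   `baseline_stratum`, `bba_clamped`).
#' @export
generate_cohort <- function(cfg) {
  validate_config(cfg)
  arms <- names(cfg$arms)
  parts <- lapply(seq_along(arms), function(i) {
    generate_arm(arms[i], cfg$arms[[i]], cfg$eeg, cfg$age_range,
                 child_seed(cfg$seed, i))
  })
  truth <- do.call(rbind, parts)
  truth <- truth[order(truth$arm, truth$subject_id,
                       match(truth$visit, c("pre", "post"))), ]
  rownames(truth) <- NULL
  cohort <- truth[, c("subject_id", "arm", "sex", "visit", "ca",
                      "followup_months", "symptoms")]
  cohort$feature <- truth$true_feature
  list(cohort = cohort, truth = truth)
}

#' Sample a noisy alpha-feature measurement
#'
#' Feature-fidelity observation model: the alpha feature implied by the true
#' brain age plus a subject-shared noise component plus per-visit noise. The
#' marginal per-visit SD is `eeg$feature_noise_sd_hz` and the correlation
#' between a subject's visits is `eeg$within_subject_corr` (so at
#' `within_subject_corr = 1` the pre and post noise coincide and paired
#' differences carry no feature noise).
#'
#' @param true_bba true brain age (years).
#' @param eeg EEG block.
#' @param subject_effect the subject-shared noise component in Hz (draw as
#'   `feature_noise_sd_hz * sqrt(within_subject_corr) * rnorm(1)`).
#' @param seed optional seed for the per-visit component.
#' @return feature value in Hz.
#' @export
sample_feature <- function(true_bba, eeg = eeg_config(), subject_effect = 0,
                           seed = NULL) {
  with_seed(seed, {
    sd_v <- eeg$feature_noise_sd_hz * sqrt(1 - eeg$within_subject_corr)
    alpha_from_bba(true_bba, eeg) + subject_effect +
      stats::rnorm(length(true_bba), 0, sd_v)
  })
}

#' Write / read cohort and truth tables as delimited text
#'
#' @param x data.frame.
#' @param path file path (tab-separated).
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
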