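# Cohort-level scoring and the full comparison battery: within-arm
# pre/post tests, BBA-vs-CA tests, between-arm delta tests, sex- and
# baseline-gap-stratified repeats, duration correlations, and categorical
# outcomes. P-values are reported uncorrected by default.

#' Generate a normative reference cohort and calibrate the age model
#'
#' Draws a reference sample with chronological ages uniform over the
#' meaningful age span, alpha features from the age mapping plus
#' measurement noise, and fits the feature-to-age calibration. Kept
#' separate (disjoint seed) from any analysis cohort so recovery results
#' are not inflated by train/test leakage.
#'
#' @param cfg generator configuration.
#' @param seed integer seed (defaults to a stream derived from
#'   `cfg$seed`).
#' @return a `calibration_model`.
#' @export
calibrate_reference <- function(cfg, seed = child_seed(cfg$seed, 9991L)) {
  with_seed(seed, {
    n <- cfg$reference$n
    ca <- stats::runif(n, cfg$reference$ca_range[1], cfg$reference$ca_range[2])
    feat <- alpha_from_bba(ca, cfg$eeg) +
      stats::rnorm(n, 0, cfg$eeg$feature_noise_sd_hz)
    fit_calibration(feat, ca)
  })
}

#' Score a cohort table with a calibration model
#'
#' Adds estimated BBA (clamped to the age range, with flag), brain-age gap
#' and BR columns.
#'
#' @param cohort cohort data.frame with `feature` and `ca` columns.
#' @param model a `calibration_model`.
#' @param age_range clamping bounds (years).
#' @return the cohort with `bba_est`, `gap_est`, `br_est`, `est_clamped`.
#' @export
score_cohort <- function(cohort, model, age_range = c(16, 100)) {
  raw <- model$intercept + model$slope * cohort$feature
  cohort$est_clamped <- raw < age_range[1] | raw > age_range[2]
  cohort$bba_est <- pmin(pmax(raw, age_range[1]), age_range[2])
  cohort$gap_est <- cohort$bba_est - cohort$ca
  cohort$br_est <- 100 * (cohort$ca - cohort$bba_est) / diff(age_range)
  cohort
}

#' Reshape a scored cohort to one row per subject
#'
#' @param scored long cohort (pre/post rows) after [score_cohort()].
#' @return data.frame with per-visit columns and deltas.
#' @export
cohort_wide <- function(scored) {
  pre <- scored[scored$visit == "pre", ]
  post <- scored[scored$visit == "post", ]
  post <- post[match(pre$subject_id, post$subject_id), ]
  ok <- !is.na(post$subject_id)
  if (!all(ok)) {
    message("excluded ", sum(!ok), " subject(s) with a missing visit")
  }
  pre <- pre[ok, ]; post <- post[ok, ]
  data.frame(subject_id = pre$subject_id, arm = pre$arm, sex = pre$sex,
             followup_months = pre$followup_months,
             ca_pre = pre$ca, ca_post = post$ca,
             bba_pre = pre$bba_est, bba_post = post$bba_est,
             gap_pre = pre$gap_est, gap_post = post$gap_est,
             br_pre = pre$br_est, br_post = post$br_est,
             symptoms_pre = pre$symptoms, symptoms_post = post$symptoms,
             d_bba = post$bba_est - pre$bba_est,
             d_ca = post$ca - pre$ca,
             d_gap = post$gap_est - pre$gap_est,
             stringsAsFactors = FALSE)
}

#' Stratify a per-subject table
#'
#' @param wide output of [cohort_wide()].
#' @param by `"sex"`, `"baseline_gap_sign"` (estimated pre-visit BBA older
#'   vs younger than CA; a gap of exactly zero counts as younger), or
#'   `"arm"`.
#' @return named list of data.frames.
#' @export
stratify <- function(wide, by = c("sex", "baseline_gap_sign", "arm")) {
  by <- match.arg(by)
  key <- switch(by,
                sex = wide$sex,
                arm = wide$arm,
                baseline_gap_sign = ifelse(wide$gap_pre > 0,
                                           "older", "younger"))
  if (by == "baseline_gap_sign" && any(wide$gap_pre == 0)) {
    message("baseline gap exactly 0 for ",
            sum(wide$gap_pre == 0), " subject(s); assigned to 'younger'")
  }
  out <- split(wide, key)
  empty <- setdiff(unique(key), names(out))
  if (length(empty)) warning("empty stratum: ", paste(empty, collapse = ", "))
  out
}

battery_row <- function(comparison, stratum, res) {
  data.frame(comparison = comparison, stratum = stratum,
             test = res$name, n = paste(res$n, collapse = "+"),
             statistic = res$statistic,
             z = res$z_value, p = res$p_value,
             notes = res$method_notes, stringsAsFactors = FALSE)
}

#' Run the full comparison battery on a scored cohort
#'
#' Executes, in order: within-arm Wilcoxon signed-rank tests (BBA pre vs
#' post, BR pre vs post, BBA vs CA at each visit); between-arm
#' Mann-Whitney tests on the pre/post changes in BBA, gap and CA; the same
#' between-arm change tests repeated within sex strata and within baseline
#' older/younger-brain strata; a Pearson correlation of the BBA change with
#' intervention duration per arm; and a chi-square test of the categorical
#' symptom outcome pre vs post per arm. P-values are not corrected for
#' multiple comparisons by default (`p_adjust = "none"`), matching the
#' reporting convention of the source analyses.
#'
#' @param scored long scored cohort (see [score_cohort()]).
#' @param p_adjust one of `p.adjust.methods`; applied to a copy of the
#'   p-value column only when not `"none"`.
#' @return data.frame of class `analysis_battery`, one row per comparison.
#' @export
run_battery <- function(scored, p_adjust = "none") {
  wide <- cohort_wide(scored)
  arms <- sort(unique(wide$arm))
  rows <- list()
  add <- function(comparison, stratum, res) {
    rows[[length(rows) + 1]] <<- battery_row(comparison, stratum, res)
  }
  safely <- function(comparison, stratum, expr) {
    res <- tryCatch(expr, error = function(e) NULL)
    if (!is.null(res)) add(comparison, stratum, res)
  }

  for (a in arms) {
    w <- wide[wide$arm == a, ]
    safely(paste0(a, ": BBA pre vs post"), "all",
           wilcoxon_signed_rank(w$bba_pre, w$bba_post))
    safely(paste0(a, ": BR pre vs post"), "all",
           wilcoxon_signed_rank(w$br_pre, w$br_post))
    safely(paste0(a, ": BBA vs CA at pre"), "all",
           wilcoxon_signed_rank(w$bba_pre, w$ca_pre))
    safely(paste0(a, ": BBA vs CA at post"), "all",
           wilcoxon_signed_rank(w$bba_post, w$ca_post))
  }
  if (length(arms) == 2) {
    x <- wide[wide$arm == arms[1], ]; y <- wide[wide$arm == arms[2], ]
    between <- function(stratum, xs, ys) {
      if (nrow(xs) == 0 || nrow(ys) == 0) return(invisible(NULL))
      safely("between-arm: delta BBA", stratum,
             mann_whitney_u(xs$d_bba, ys$d_bba))
      safely("between-arm: delta gap", stratum,
             mann_whitney_u(xs$d_gap, ys$d_gap))
      safely("between-arm: delta CA", stratum,
             mann_whitney_u(xs$d_ca, ys$d_ca))
    }
    between("all", x, y)
    for (s in c("F", "M")) {
      between(paste0("sex=", s), x[x$sex == s, ], y[y$sex == s, ])
    }
    between("baseline=older", x[x$gap_pre > 0, ], y[y$gap_pre > 0, ])
    between("baseline=younger", x[x$gap_pre <= 0, ], y[y$gap_pre <= 0, ])
  }
  for (a in arms) {
    w <- wide[wide$arm == a, ]
    safely(paste0(a, ": delta BBA vs duration"), "all",
           pearson_r(w$d_bba, w$followup_months))
    tab <- rbind(pre = c(yes = sum(w$symptoms_pre),
                         no = sum(!w$symptoms_pre)),
                 post = c(yes = sum(w$symptoms_post),
                          no = sum(!w$symptoms_post)))
    safely(paste0(a, ": symptoms pre vs post"), "all", chi_square(tab))
  }

  out <- do.call(rbind, rows)
  if (!identical(p_adjust, "none")) {
    out$p_adjusted <- stats::p.adjust(out$p, method = p_adjust)
  }
  class(out) <- c("analysis_battery", class(out))
  out
}
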