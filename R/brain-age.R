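# Alpha-band age feature, linear age calibration, brain-biological-age
# prediction and the brain-resources (BR) index.

#' Extract the alpha center-of-gravity feature
#'
#' Per channel, the power-weighted mean frequency over bins with
#' `band[1] <= f <= band[2]` (inclusive); the feature value is the
#' unweighted mean over the electrode set. Channels with zero band power
#' are excluded with a warning.
#'
#' @param spec a `power_spectrum`.
#' @param band analysis band in Hz (default 7-13, the alpha band).
#' @param electrodes channel labels to average over (default posterior
#'   set).
#' @return object of class `alpha_feature`: `value_hz`, `per_channel`
#'   (named numeric), `electrode_set`, `band`.
#' @export
extract_alpha_feature <- function(spec, band = c(7, 13),
                                  electrodes = posterior_electrodes) {
  if (band[1] < min(spec$freqs_hz) || band[2] > max(spec$freqs_hz)) {
    stop("argument error: band outside the spectrum range")
  }
  sel <- match(electrodes, spec$channel_labels)
  if (anyNA(sel)) {
    stop("argument error: electrode(s) not in spectrum: ",
         paste(electrodes[is.na(sel)], collapse = ", "))
  }
  inband <- which(spec$freqs_hz >= band[1] & spec$freqs_hz <= band[2])
  f <- spec$freqs_hz[inband]
  per <- vapply(sel, function(ch) {
    p <- spec$power[ch, inband]
    tot <- sum(p)
    if (tot <= 0) return(NA_real_)
    sum(f * p) / tot
  }, numeric(1))
  names(per) <- electrodes
  if (anyNA(per)) {
    warning("channel(s) with zero alpha-band power excluded: ",
            paste(electrodes[is.na(per)], collapse = ", "))
    per_use <- per[!is.na(per)]
    if (!length(per_use)) stop("all electrodes have zero alpha-band power")
  } else {
    per_use <- per
  }
  structure(list(value_hz = mean(per_use), per_channel = per,
                 electrode_set = electrodes, band = band),
            class = "alpha_feature")
}

#' Fit the feature-to-age calibration model
#'
#' Ordinary least-squares regression of chronological age on the alpha
#' feature (prediction-ready direction: the fitted line maps a feature
#' value directly to a predicted age).
#'
#' @param features numeric vector of alpha features (Hz).
#' @param cas chronological ages (years).
#' @return object of class `calibration_model`: `slope` (years/Hz),
#'   `intercept` (years), `n_train`, `feature_range`, `fit_residual_sd`.
#' @export
fit_calibration <- function(features, cas) {
  if (length(features) != length(cas)) stop("argument error: length mismatch")
  if (length(features) < 3) stop("argument error: need n >= 3 to calibrate")
  if (stats::sd(features) <= 0) {
    stop("degenerate-fit error: feature has zero variance")
  }
  fit <- stats::lm(cas ~ features)
  co <- unname(stats::coef(fit))
  structure(list(intercept = co[1], slope = co[2],
                 n_train = length(cas),
                 feature_range = range(features),
                 fit_residual_sd = stats::sd(stats::residuals(fit))),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> BBA = %.2f + %.3f * f_alpha (n=%d, resid sd %.2f y)\n",
              x$intercept, x$slope, x$n_train, x$fit_residual_sd))
  invisible(x)
}

#' Serialize / load a calibration model as JSON
#'
#' @param model a `calibration_model`.
#' @param path file path.
#' @export
write_calibration <- function(model, path) {
  write_json_file(unclass(model), path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "calibration_model")
}

#' Predict brain biological age and brain resources
#'
#' `BBA = intercept + slope * feature`, clamped to the meaningful age range
#' (16-100 years) with a flag; a feature outside the training range raises
#' an extrapolation flag. The brain-age gap `BBA - CA` and the BR index are
#' attached.
#'
#' @param model a `calibration_model`.
#' @param feature alpha feature in Hz (an `alpha_feature` or a number).
#' @param ca chronological age (years).
#' @param age_range clamping bounds (years).
#' @return list of class `bba_result`: `bba_years`, `ca_years`,
#'   `gap_years`, `br_percent`, `clamped`, `confidence_flags`.
#' @export
predict_bba <- function(model, feature, ca, age_range = c(16, 100)) {
  f <- if (inherits(feature, "alpha_feature")) feature$value_hz else feature
  raw <- model$intercept + model$slope * f
  flags <- character(0)
  clamped <- raw < age_range[1] || raw > age_range[2]
  bba <- min(max(raw, age_range[1]), age_range[2])
  if (clamped) flags <- c(flags, "clamped")
  if (f < model$feature_range[1] || f > model$feature_range[2]) {
    flags <- c(flags, "extrapolation")
  }
  structure(list(bba_years = bba, ca_years = ca, gap_years = bba - ca,
                 br_percent = compute_br(ca, bba, age_range),
                 clamped = clamped, confidence_flags = flags),
            class = "bba_result")
}

#' Brain-resources index
#'
#' The BBA-CA difference normalized to the meaningful age span:
#' `BR = 100 * (CA - BBA) / (age_range[2] - age_range[1])` percent (84
#' years by default). Positive values indicate a younger brain phenotype
#' (more preserved resources), negative an older one.
#'
#' @param ca,bba ages in years, both within `age_range`.
#' @param age_range meaningful age span (years).
#' @return percent.
#' @export
compute_br <- function(ca, bba, age_range = c(16, 100)) {
  if (any(ca < age_range[1] | ca > age_range[2]) ||
      any(bba < age_range[1] | bba > age_range[2])) {
    stop("argument error: ages must lie in [", age_range[1], ", ",
         age_range[2], "]")
  }
  100 * (ca - bba) / diff(age_range)
}

#' Classify a pre/post brain-age trajectory
#'
#' Labels the change between two visits: `rejuvenation` when BBA decreased;
#' `deceleration` when BBA rose more slowly than CA; `normal` when the BBA
#' change tracks the CA change within tolerance `tau`; `acceleration` when
#' BBA rose faster than CA.
#'
#' @param pre,post `bba_result` objects for the same subject.
#' @param tau tolerance (years) for the `normal` label.
#' @return character label.
#' @export
classify_trajectory <- function(pre, post, tau = 0.25) {
  d_ca <- post$ca_years - pre$ca_years
  if (d_ca <= 0) stop("data error: post CA must exceed pre CA")
  d_bba <- post$bba_years - pre$bba_years
  if (d_bba < 0) return("rejuvenation")
  if (abs(d_bba - d_ca) <= tau) return("normal")
  if (d_bba < d_ca) return("deceleration")
  "acceleration"
}
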