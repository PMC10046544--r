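# Signal-fidelity EEG synthesis: an age-encoding alpha oscillation with slow
# amplitude modulation over a 1/f^beta background, mains interference, and
# injected artifact events with a ground-truth event log.

# 1/f^beta noise via spectral shaping, scaled to a target RMS.
pink_noise <- function(n, beta = 1, rms_target = 1) {
  nf <- n %/% 2 + 1
  f <- seq_len(nf) - 1
  amp <- c(0, f[-1]^(-beta / 2))           # no DC
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- amp * exp(1i * ph)
  full <- c(spec, Conj(rev(spec[2:(n - nf + 1)])))
  x <- Re(stats::fft(full, inverse = TRUE))
  x <- x - mean(x)
  r <- rms(x)
  if (r > 0) x <- x * (rms_target / r)
  x
}

# Smooth positive envelope: low-pass filtered gaussian noise around 1.
slow_envelope <- function(n, fs, depth, cutoff_hz = 0.2) {
  if (depth <= 0) return(rep(1, n))
  z <- stats::rnorm(n)
  k <- max(3, round(fs / cutoff_hz))
  kern <- stats::dnorm(seq(-3, 3, length.out = k))
  kern <- kern / sum(kern)
  sm <- stats::filter(c(rev(z[seq_len(k)]), z, rev(z[(n - k + 1):n])),
                      kern, sides = 2)
  sm <- as.numeric(sm[(k + 1):(k + n)])
  sm <- sm / max(stats::sd(sm), 1e-12)
  pmax(1 + depth * sm, 0.05)
}

#' Inject artifact events into a multichannel signal
#'
#' Adds eye-blink-like low-frequency high-amplitude half-sine transients on
#' frontal channels and broadband 20-30 Hz muscle bursts on temporal/frontal
#' channels at Poisson event times, and returns the ground-truth event log
#' so rejection performance can be scored against it.
#'
#' @param data channels x samples matrix (microvolts).
#' @param channel_labels channel names (rows of `data`).
#' @param fs_hz sampling rate.
#' @param rate_per_min Poisson event rate.
#' @param seed integer seed.
#' @return list `data` (modified matrix) and `events` (data.frame with
#'   `onset_s`, `duration_s`, `type`).
#' @export
inject_artifacts <- function(data, channel_labels, fs_hz, rate_per_min,
                             seed = NULL) {
  n <- ncol(data)
  dur_s <- n / fs_hz
  if (rate_per_min <= 0) {
    return(list(data = data,
                events = data.frame(onset_s = numeric(0),
                                    duration_s = numeric(0),
                                    type = character(0))))
  }
  with_seed(seed, {
    n_events <- stats::rpois(1, rate_per_min * dur_s / 60)
    if (n_events == 0) {
      return(list(data = data,
                  events = data.frame(onset_s = numeric(0),
                                      duration_s = numeric(0),
                                      type = character(0))))
    }
    onset <- sort(stats::runif(n_events, 0, max(dur_s - 1.5, 0)))
    type <- sample(c("blink", "muscle"), n_events, replace = TRUE)
    frontal <- channel_labels %in% c("Fp1", "Fp2", "F7", "F8", "F3", "F4", "Fz")
    temporal <- channel_labels %in% c("T3", "T4", "T5", "T6", "F7", "F8")
    dur <- numeric(n_events)
    for (k in seq_len(n_events)) {
      if (type[k] == "blink") {
        f0 <- stats::runif(1, 0.5, 2)           # half-sine of 150-300 uV
        dur[k] <- 0.5 / f0
        amp <- stats::runif(1, 150, 300)
        idx <- round(onset[k] * fs_hz) + seq_len(round(dur[k] * fs_hz))
        idx <- idx[idx >= 1 & idx <= n]
        wave <- amp * sin(pi * seq_along(idx) / length(idx))
        rowsel <- which(frontal)
        if (!length(rowsel)) rowsel <- seq_len(nrow(data))
        for (r in rowsel) data[r, idx] <- data[r, idx] + wave
      } else {
        dur[k] <- stats::runif(1, 0.3, 0.8)     # 20-30 Hz burst, ~50 uV
        idx <- round(onset[k] * fs_hz) + seq_len(round(dur[k] * fs_hz))
        idx <- idx[idx >= 1 & idx <= n]
        f0 <- stats::runif(1, 20, 30)
        t <- idx / fs_hz
        rowsel <- which(temporal)
        if (!length(rowsel)) rowsel <- seq_len(nrow(data))
        for (r in rowsel) {
          burst <- 50 * sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi)) *
            stats::runif(length(idx), 0.8, 1.2)
          data[r, idx] <- data[r, idx] + burst
        }
      }
    }
    list(data = data,
         events = data.frame(onset_s = onset, duration_s = dur, type = type))
  })
}

#' Synthesize a resting-state EEG recording encoding a brain age
#'
#' Each channel carries an alpha oscillation whose frequency is
#' `alpha_hz` (by default the alpha-age mapping of `true_bba`), with larger
#' amplitude over posterior channels (O/P/T5/T6), slow random amplitude
#' modulation, a 1/f^beta background, a mains sinusoid, and injected
#' artifacts. Units are microvolts; channel labels are the 19 names of the
#' 10-20 montage.
#'
#' @param true_bba true brain age in years.
#' @param eeg EEG block (see [eeg_config()]).
#' @param seed integer seed.
#' @param subject_id,visit identifiers stored in the recording.
#' @param alpha_hz optional oscillation frequency overriding the mapping
#'   (used to carry per-visit physiological feature noise into the signal).
#' @return a `recording` object (see [new_recording()]); artifact events are
#'   kept in `annotations`.
#' @export
synthesize_recording <- function(true_bba, eeg = eeg_config(), seed = NULL,
                                 subject_id = "sim", visit = "pre",
                                 alpha_hz = NULL) {
  f0 <- if (is.null(alpha_hz)) alpha_from_bba(true_bba, eeg) else alpha_hz
  if (f0 <= 7 || f0 >= 13) {
    stop_cfg("eeg$alpha_anchor_hz/alpha_age_slope",
             "implied alpha frequency ", round(f0, 2),
             " Hz falls outside the 7-13 Hz analysis band")
  }
  fs <- eeg$fs_hz
  n <- round(eeg$duration_s * fs)
  labels <- channels_1020[seq_len(eeg$n_channels)]
  posterior <- labels %in% c("O1", "O2", "P3", "P4", "Pz", "T5", "T6")
  with_seed(seed, {
    t <- seq_len(n) / fs
    data <- matrix(0, nrow = length(labels), ncol = n)
    for (ch in seq_along(labels)) {
      amp <- if (posterior[ch]) eeg$alpha_amp_uV else eeg$alpha_amp_anterior_uV
      env <- slow_envelope(n, fs, eeg$am_depth)
      x <- amp * env * sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi))
      if (eeg$pink_noise_amp_uV > 0) {
        x <- x + pink_noise(n, eeg$pink_noise_exponent, eeg$pink_noise_amp_uV)
      }
      if (eeg$line_noise_amp_uV > 0) {
        x <- x + eeg$line_noise_amp_uV *
          sin(2 * pi * eeg$line_freq_hz * t + stats::runif(1, 0, 2 * pi))
      }
      data[ch, ] <- x
    }
    art <- inject_artifacts(data, labels, fs, eeg$artifact_rate_per_min)
    ann <- if (nrow(art$events)) {
      data.frame(onset_s = art$events$onset_s,
                 duration_s = art$events$duration_s,
                 label = paste0("artifact_", art$events$type))
    } else {
      data.frame(onset_s = numeric(0), duration_s = numeric(0),
                 label = character(0))
    }
    new_recording(art$data, labels, fs, reference = "linked-ears",
                  subject_id = subject_id, visit = visit, annotations = ann)
  })
}
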