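# Independent brute-force oracles for the rank tests, deliberately written
# along different lines than the package implementation (sign patterns via
# expand.grid; U via direct pair counting) so agreement is informative.

oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  t_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  tps <- as.vector(signs %*% r)
  min(1, 2 * min(mean(tps <= t_obs), mean(tps >= t_obs)))
}

# U statistic by pair counting: #(x_i > y_j) + 0.5 * #(x_i == y_j).
oracle_u_stat <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

oracle_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- oracle_u_stat(x, y)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(ix) {
    oracle_u_stat(pooled[ix], pooled[-ix])
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Small helper: synthetic sinusoidal recording.
tone_recording <- function(freq_hz, amp = 1, fs = 256, dur_s = 20,
                           labels = "O1") {
  t <- seq_len(fs * dur_s) / fs
  data <- matrix(rep(amp * sin(2 * pi * freq_hz * t), length(labels)),
                 nrow = length(labels), byrow = TRUE)
  new_recording(data, labels, fs)
}

# Quiet EEG block for fast signal-fidelity tests.
quiet_eeg <- function(duration_s = 60, ...) {
  eeg_config(duration_s = duration_s, pink_noise_amp_uV = 0,
             line_noise_amp_uV = 0, artifact_rate_per_min = 0, am_depth = 0,
             feature_noise_sd_hz = 0, ...)
}
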