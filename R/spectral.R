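# Averaged windowed periodogram: mean-subtracted, Hann-windowed, Fourier
# transformed segments averaged into one power spectrum per channel.

#' Averaged power spectrum over retained segments
#'
#' Per retained segment and channel: subtract the segment mean, apply a
#' Hann window, take the DFT, and form the one-sided power `2|X_k|^2 /
#' (L * sum(w^2))` (microvolts squared per bin; DC and Nyquist bins are not
#' doubled). Powers are averaged across segments. With this window-power
#' normalization the band sum of the spectrum matches the time-domain
#' variance (Parseval) for stationary inputs.
#'
#' @param segs a `segment_set` (after rejection; all segments used if no
#'   rejection was run).
#' @return object of class `power_spectrum`: `freqs_hz` (0 .. fs/2, spacing
#'   `fs/L` = 0.5 Hz for 2-s segments), `power` (channels x freqs), plus
#'   `n_segments_used`, `window`, `channel_labels`.
#' @export
compute_spectrum <- function(segs) {
  keep <- which(segs$retained_mask)
  if (!length(keep)) stop("zero retained segments; spectrum undefined")
  L <- segs$L
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / L)    # Hann (periodic)
  w2 <- sum(w^2)
  nf <- L %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * segs$fs_hz / L
  nchan <- length(segs$channel_labels)
  acc <- matrix(0, nrow = nchan, ncol = nf)
  for (i in keep) {
    m <- segs$segments[[i]]
    for (ch in seq_len(nchan)) {
      x <- m[ch, ]
      x <- (x - mean(x)) * w
      X <- stats::fft(x)[seq_len(nf)]
      p <- (Mod(X)^2) / (L * w2)    # two-sided; sums to variance (Parseval)
      p <- 2 * p
      p[1] <- p[1] / 2
      if (L %% 2 == 0) p[nf] <- p[nf] / 2
      acc[ch, ] <- acc[ch, ] + p
    }
  }
  structure(list(freqs_hz = freqs, power = acc / length(keep),
                 n_segments_used = length(keep), window = "hann",
                 channel_labels = segs$channel_labels),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d channels, %d bins (%.2f Hz spacing), %d segments, %s window\n",
              nrow(x$power), length(x$freqs_hz), diff(x$freqs_hz[1:2]),
              x$n_segments_used, x$window))
  invisible(x)
}

#' Export a power spectrum as delimited text
#'
#' Frequency column plus one column per channel.
#'
#' @param spec a `power_spectrum`.
#' @param path output path (tab-separated).
#' @export
write_spectrum_tsv <- function(spec, path) {
  df <- data.frame(freq_hz = spec$freqs_hz, t(spec$power))
  names(df) <- c("freq_hz", spec$channel_labels)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
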