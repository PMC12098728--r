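#' Analysis frequency bands
#'
#' Nine band-power bands (1-4, 4-8, 8-12, 15-25, 35-50, 70-110, 130-170,
#' 190-230, 250-290 Hz) and the eight functional-connectivity bands (the
#' same set without 1-4 Hz). The bands skirt 60 Hz and its harmonics so
#' residual line noise has minimal impact.
#'
#' @return A data frame with columns `low`, `high` (Hz) and `tag`.
#' @export
psd_bands <- function() {
  b <- rbind(c(1, 4), c(4, 8), c(8, 12), c(15, 25), c(35, 50),
             c(70, 110), c(130, 170), c(190, 230), c(250, 290))
  data.frame(low = b[, 1], high = b[, 2],
             tag = sprintf("%g_%g", b[, 1], b[, 2]))
}

#' @rdname psd_bands
#' @export
fc_bands <- function() psd_bands()[-1, , drop = FALSE]

#' Welch power spectral density
#'
#' Mean modified periodogram over Hann-windowed segments with 50% overlap.
#' One-sided density in uV^2/Hz.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param window_s Segment length in seconds (default 2).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
pwelch <- function(x, fs, window_s = 2, overlap = 0.5) {
  nwin <- round(window_s * fs)
  if (length(x) < nwin) stop("signal shorter than one Welch window")
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nwin) - 1) / (nwin - 1)))
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  nfreq <- nwin %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)] * w
    P <- Mod(stats::fft(seg))^2 / (fs * sum(w^2))
    p1 <- P[seq_len(nfreq)]
    ## fold two-sided density into one-sided (DC and Nyquist not doubled)
    if (nwin %% 2 == 0) p1[2:(nfreq - 1L)] <- 2 * p1[2:(nfreq - 1L)]
    else p1[2:nfreq] <- 2 * p1[2:nfreq]
    acc <- acc + p1
  }
  list(freq = (seq_len(nfreq) - 1) * fs / nwin, psd = acc / length(starts))
}

#' Band power features by Welch's method
#'
#' Per channel and band, the mean Welch PSD (2-s Hann windows, 50% overlap)
#' across in-band frequency bins, in dB relative to 1 uV^2/Hz
#' (`10 * log10`).
#'
#' @param rec An [ieeg_recording()] of at least 2 s.
#' @param bands Band definition data frame as from [psd_bands()].
#' @param window_s,overlap Welch parameters.
#' @return Channels x bands numeric matrix (dB), columns named
#'   `psd_<low>_<high>`.
#' @export
welch_band_psd <- function(rec, bands = psd_bands(), window_s = 2,
                           overlap = 0.5) {
  stopifnot(inherits(rec, "ieeg_recording"))
  if (max(bands$high) >= rec$fs / 2) {
    stop("configuration error: band edge ", max(bands$high),
         " Hz is at or above Nyquist")
  }
  out <- matrix(NA_real_, n_channels(rec), nrow(bands),
                dimnames = list(NULL, paste0("psd_", bands$tag)))
  for (ch in seq_len(n_channels(rec))) {
    sp <- pwelch(rec$data[ch, ], rec$fs, window_s, overlap)
    for (b in seq_len(nrow(bands))) {
      sel <- sp$freq >= bands$low[b] & sp$freq <= bands$high[b]
      out[ch, b] <- 10 * log10(mean(sp$psd[sel]))
    }
  }
  out
}
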