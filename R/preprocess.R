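#' Preprocessing configuration
#'
#' @param line_freq Power-line fundamental frequency in Hz.
#' @param n_harmonics Number of harmonics above the fundamental to remove;
#'   the default 5 removes 60 Hz plus 120-360 Hz.
#' @param interp_halfwidth Half-width in Hz of the spectral neighborhood
#'   interpolated around each target frequency.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(line_freq = 60, n_harmonics = 5,
                              interp_halfwidth = 1) {
  stopifnot(line_freq > 0, n_harmonics >= 0, interp_halfwidth > 0)
  structure(list(line_freq = line_freq, n_harmonics = n_harmonics,
                 interp_halfwidth = interp_halfwidth),
            class = "preprocess_config")
}

#' Drop channels flagged as bad
#'
#' Restricts a recording and its annotation to channels with `bad = FALSE`,
#' preserving channel order. Bad-channel flags are inputs (expert review in
#' clinical practice); no automated detection is attempted.
#'
#' @param rec An [ieeg_recording()].
#' @param ann A [channel_annotation()] aligned with `rec`.
#' @return List with elements `recording` and `annotation`.
#' @export
drop_bad_channels <- function(rec, ann) {
  stopifnot(inherits(rec, "ieeg_recording"))
  if (nrow(ann) != n_channels(rec)) {
    stop("annotation length does not match channel count")
  }
  keep <- !ann$bad
  if (!any(keep)) stop("all channels are flagged bad; empty recording")
  out <- ieeg_recording(rec$data[keep, , drop = FALSE], rec$fs,
                        rec$channel_labels[keep], rec$patient_id)
  list(recording = out,
       annotation = channel_annotation(ann$soz[keep], ann$rz[keep],
                                       ann$bad[keep]))
}

#' Remove power-line noise by spectral interpolation
#'
#' Per channel, the full-record amplitude spectrum within
#' `interp_halfwidth` Hz of the line frequency and each of its harmonics is
#' replaced by linear interpolation of the magnitude between the flanking
#' frequency bins; phase is retained. Chosen over a notch filter because it
#' does not ring in the time domain: distant bands are untouched.
#'
#' @param rec An [ieeg_recording()].
#' @param cfg A [preprocess_config()].
#' @return The cleaned [ieeg_recording()], same length as the input.
#' @export
remove_line_noise <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "ieeg_recording"))
  targets <- cfg$line_freq * seq_len(cfg$n_harmonics + 1)
  if (max(targets) >= rec$fs / 2) {
    stop("configuration error: target frequency ", max(targets),
         " Hz is at or above Nyquist (", rec$fs / 2, " Hz)")
  }
  n <- n_samples(rec)
  freqs <- (seq_len(n) - 1) * rec$fs / n
  half <- floor(n / 2)
  X <- t(stats::mvfft(t(rec$data)))       # channels x freq bins
  for (f0 in targets) {
    idx <- which(freqs[2:(half + 1)] >= f0 - cfg$interp_halfwidth &
                 freqs[2:(half + 1)] <= f0 + cfg$interp_halfwidth) + 1L
    if (length(idx) == 0) next
    lo <- min(idx) - 1L; hi <- max(idx) + 1L
    w <- (freqs[idx] - freqs[lo]) / (freqs[hi] - freqs[lo])
    for (ch in seq_len(nrow(X))) {
      mag <- (1 - w) * Mod(X[ch, lo]) + w * Mod(X[ch, hi])
      old <- X[ch, idx]
      ph <- ifelse(Mod(old) > 0, old / Mod(old), 1)
      X[ch, idx] <- mag * ph
      conj_idx <- n - idx + 2L          # mirror bins, Hermitian symmetry
      X[ch, conj_idx] <- Conj(X[ch, idx])
    }
  }
  data <- Re(t(stats::mvfft(t(X), inverse = TRUE))) / n
  ieeg_recording(data, rec$fs, rec$channel_labels, rec$patient_id)
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean across channels from every channel,
#' so the cross-channel mean of the output is zero everywhere.
#'
#' @param rec An [ieeg_recording()] with at least two channels.
#' @return The re-referenced [ieeg_recording()].
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "ieeg_recording"))
  if (n_channels(rec) < 2) {
    stop("common average reference requires at least 2 channels")
  }
  data <- sweep(rec$data, 2, colMeans(rec$data))
  ieeg_recording(data, rec$fs, rec$channel_labels, rec$patient_id)
}

#' Full preprocessing chain
#'
#' Bad-channel drop, then power-line removal, then common average
#' referencing, in that fixed order.
#'
#' @inheritParams drop_bad_channels
#' @param cfg A [preprocess_config()].
#' @return List with `recording` and `annotation`.
#' @export
preprocess <- function(rec, ann, cfg = preprocess_config()) {
  dropped <- drop_bad_channels(rec, ann)
  cleaned <- remove_line_noise(dropped$recording, cfg)
  list(recording = common_average_reference(cleaned),
       annotation = dropped$annotation)
}
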