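#' Configuration for a synthetic iEEG cohort
#'
#' Defines the study conditions a generated cohort emulates: an awake
#' interictal iEEG cohort of ~26 patients with 41-121 subdural/depth
#' channels each, 30-minute samples at 1000 Hz, a seizure onset zone (SOZ)
#' of 3-45 channels nested inside a resection zone (RZ) of 8-50 channels,
#' elevated gamma-band amplitude-envelope coupling and elevated spike/HFO
#' rates in SOZ channels, 60 Hz line noise with harmonics, and occasional
#' high-amplitude artifact segments.
#'
#' Coupling strengths are variance shares in [0, 1] of a shared
#' amplitude-modulated narrow-band source: 0 gives independent band
#' activity, 1 makes the group's band activity fully shared.
#'
#' @param n_patients Number of patients.
#' @param channels_per_patient Integer range (length-2) of channel counts.
#' @param soz_channels Integer range of SOZ sizes (clipped per patient so
#'   SOZ < RZ <= channel count).
#' @param rz_channels Integer range of RZ sizes; the RZ always contains the
#'   SOZ.
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz; must exceed 580 Hz so the 250-290 Hz
#'   analysis band is representable.
#' @param gamma_coupling_soz,gamma_coupling_bg Gamma-band (70-110 Hz) shared-
#'   source variance share among SOZ channels / among all channels.
#' @param band_coupling_bg Upper bound of the per-channel coupling weight
#'   to each band's shared background source. Every analysis band has a
#'   shared amplitude-modulated source that channel i couples to with
#'   weight drawn uniformly from \[0, band_coupling_bg\], producing the
#'   heterogeneous, temporally stable functional-connectivity structure
#'   characteristic of cortical recordings.
#' @param spike_rate_soz,spike_rate_bg Injected spike rates, events/minute.
#' @param hfo_rate_soz,hfo_rate_bg Injected HFO rates, events/minute.
#' @param line_noise_amp Amplitude (uV) of the 60 Hz fundamental; harmonic k
#'   has amplitude `line_noise_amp / k`.
#' @param artifact_epoch_fraction Fraction of 12-s epochs hit by a 1-5 s
#'   rectangular >3000 uV artifact on one channel.
#' @param background_rms Root-mean-square amplitude (uV) of the 1/f^2
#'   background noise.
#' @param coupling_mode `"shared_source"` (default): SOZ channels share a
#'   common gamma-band source, raising both amplitude-envelope correlation
#'   and phase locking; `"shared_envelope"`: SOZ channels share only the
#'   slow amplitude envelope on independent carriers, raising AEC without
#'   phase locking (an AEC-specific effect).
#' @param seed Master RNG seed for the cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 26,
                          channels_per_patient = c(41, 121),
                          soz_channels = c(3, 45),
                          rz_channels = c(8, 50),
                          duration_s = 1800,
                          fs = 1000,
                          gamma_coupling_soz = 0.5,
                          gamma_coupling_bg = 0.05,
                          band_coupling_bg = 0.9,
                          spike_rate_soz = 2,
                          spike_rate_bg = 0.5,
                          hfo_rate_soz = 1.5,
                          hfo_rate_bg = 0.3,
                          line_noise_amp = 20,
                          artifact_epoch_fraction = 0.02,
                          background_rms = 25,
                          coupling_mode = c("shared_source", "shared_envelope"),
                          seed = 1L) {
  coupling_mode <- match.arg(coupling_mode)
  cfg <- list(n_patients = n_patients,
              channels_per_patient = channels_per_patient,
              soz_channels = soz_channels, rz_channels = rz_channels,
              duration_s = duration_s, fs = fs,
              gamma_coupling_soz = gamma_coupling_soz,
              gamma_coupling_bg = gamma_coupling_bg,
              band_coupling_bg = band_coupling_bg,
              spike_rate_soz = spike_rate_soz, spike_rate_bg = spike_rate_bg,
              hfo_rate_soz = hfo_rate_soz, hfo_rate_bg = hfo_rate_bg,
              line_noise_amp = line_noise_amp,
              artifact_epoch_fraction = artifact_epoch_fraction,
              background_rms = background_rms,
              coupling_mode = coupling_mode,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  rng_ok <- function(r) length(r) == 2 && r[1] >= 1 && r[1] <= r[2]
  if (cfg$n_patients < 1) stop("n_patients must be >= 1")
  if (!rng_ok(cfg$channels_per_patient) || !rng_ok(cfg$soz_channels) ||
      !rng_ok(cfg$rz_channels)) {
    stop("channel/SOZ/RZ ranges must be increasing length-2 integer ranges")
  }
  if (cfg$soz_channels[1] > cfg$rz_channels[2]) {
    stop("infeasible ranges: minimum SOZ count exceeds maximum RZ count")
  }
  if (cfg$soz_channels[1] > cfg$channels_per_patient[2]) {
    stop("infeasible ranges: minimum SOZ count exceeds maximum channel count")
  }
  if (cfg$fs <= 2 * 290) stop("fs must exceed 580 Hz to represent the 250-290 Hz band")
  if (cfg$duration_s <= 0) stop("duration_s must be positive")
  couplings <- c(cfg$gamma_coupling_soz, cfg$gamma_coupling_bg, cfg$band_coupling_bg)
  if (any(couplings < 0 | couplings > 1)) stop("coupling strengths must lie in [0, 1]")
  if (cfg$artifact_epoch_fraction < 0 || cfg$artifact_epoch_fraction > 1) {
    stop("artifact_epoch_fraction must lie in [0, 1]")
  }
  invisible(cfg)
}

## 1/f^2-shaped Gaussian background noise via spectral shaping.
## Frequencies below 1 Hz are flattened to avoid a divergent DC component.
pink_noise <- function(n, fs, rms, exponent = 2) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)           # two-sided spectrum, symmetric scale
  scale <- pmax(f_fold, 1) ^ (-exponent / 2)
  scale[1] <- 0                        # remove DC
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  x * (rms / stats::sd(x))
}

## Standardized Gaussian modulation signal with ~`tau`-second correlation
## time, generated at a decimated rate and interpolated for speed.
slow_modulation <- function(n, fs, tau = 0.15) {
  rate <- 50
  m <- ceiling(n / fs * rate) + 8L
  z <- stats::rnorm(m)
  k_sd <- max(1, tau * rate)
  kt <- seq(-ceiling(3 * k_sd), ceiling(3 * k_sd))
  kern <- exp(-kt^2 / (2 * k_sd^2)); kern <- kern / sum(kern)
  sm <- stats::convolve(z, kern, type = "open")
  sm <- sm[(length(kt) %/% 2) + seq_len(m)]
  t_lo <- (seq_len(m) - 1) / rate
  out <- stats::approx(t_lo, sm, xout = (seq_len(n) - 1) / fs, rule = 2)$y
  (out - mean(out)) / stats::sd(out)
}

## Narrow-band amplitude-modulated signal of unit RMS: envelope
## 1 + 0.7 z(t) (clipped at 0) on a sinusoidal carrier in `band`.
am_band_signal <- function(n, fs, band, modulation = NULL) {
  f0 <- stats::runif(1, band[1], band[2])
  phi <- stats::runif(1, 0, 2 * pi)
  if (is.null(modulation)) modulation <- slow_modulation(n, fs)
  env <- pmax(0, 1 + 0.7 * modulation)
  t <- (seq_len(n) - 1) / fs
  s <- env * cos(2 * pi * f0 * t + phi)
  s / sqrt(mean(s^2))
}

## Amplitude-modulated narrow-band source with its own carrier and
## envelope; shared across a channel group it induces both AEC (through
## the common envelope) and PLV (through the common carrier).
am_band_source <- function(n, fs, band) am_band_signal(n, fs, band)

## Biphasic epileptiform spike: scaled difference of Gaussians, total
## duration 20-70 ms, peak-to-peak amplitude 100-400 uV, random polarity.
spike_waveform <- function(fs, duration_s, amplitude) {
  n <- max(8L, round(duration_s * fs))
  t <- seq(-1, 1, length.out = n)
  w <- exp(-(t + 0.25)^2 / (2 * 0.12^2)) - 0.6 * exp(-(t - 0.3)^2 / (2 * 0.25^2))
  w <- w - mean(w)
  w * (amplitude / (max(w) - min(w)))
}

## HFO burst: Tukey-windowed sinusoid, centre frequency 100-200 Hz,
## duration 30-80 ms, peak amplitude 10-40 uV.
hfo_waveform <- function(fs, duration_s, freq, amplitude) {
  n <- max(8L, round(duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  r <- 0.5                             # Tukey taper fraction
  k <- (seq_len(n) - 1) / (n - 1)
  win <- ifelse(k < r / 2, 0.5 * (1 + cos(pi * (2 * k / r - 1))),
         ifelse(k > 1 - r / 2, 0.5 * (1 + cos(pi * (2 * k / r - 2 / r + 1))), 1))
  amplitude * win * sin(2 * pi * freq * t)
}

#' Generate one synthetic iEEG recording with ground truth
#'
#' Builds a channels x samples signal as the sum of 1/f^2 background noise,
#' shared amplitude-modulated narrow-band sources (a global alpha-band
#' source, a global gamma-band source, and an extra gamma-band source shared
#' only by SOZ channels), injected biphasic spikes and 100-200 Hz HFO
#' bursts at class-dependent Poisson rates, 60 Hz line noise with its first
#' five harmonics, and rare rectangular >3000 uV artifact segments.
#' Identical `params` and `seed` reproduce the output bit for bit.
#'
#' @param params List of per-patient parameters: `n_channels`, `n_soz`,
#'   `n_rz`, plus the scalar fields of [cohort_config()] (`duration_s`,
#'   `fs`, couplings, event rates, `line_noise_amp`,
#'   `artifact_epoch_fraction`, `background_rms`) and optional `patient_id`.
#'   Missing fields fall back to the [cohort_config()] defaults.
#' @param seed Integer RNG seed.
#' @return A list with elements `recording` ([ieeg_recording()]),
#'   `annotation` ([channel_annotation()]) and `provenance`: a list holding
#'   the SOZ/RZ index sets, a data frame of injected events (channel, class,
#'   time_s, amplitude_uV) and a data frame of artifact windows.
#' @export
generate_recording <- function(params, seed = 1L) {
  defaults <- list(n_channels = 12L, n_soz = 2L, n_rz = 4L,
                   duration_s = 300, fs = 1000,
                   gamma_coupling_soz = 0.5, gamma_coupling_bg = 0.05,
                   band_coupling_bg = 0.9,
                   spike_rate_soz = 2, spike_rate_bg = 0.5,
                   hfo_rate_soz = 1.5, hfo_rate_bg = 0.3,
                   line_noise_amp = 20, artifact_epoch_fraction = 0.02,
                   background_rms = 25, coupling_mode = "shared_source",
                   patient_id = "P1")
  p <- utils::modifyList(defaults, params[!vapply(params, is.null, logical(1))])
  if (p$n_soz > p$n_rz) stop("configuration error: SOZ count exceeds RZ count")
  if (p$n_rz > p$n_channels) stop("configuration error: RZ count exceeds channel count")
  if (p$n_channels < 1 || p$duration_s <= 0 || p$fs <= 0) {
    stop("configuration error: counts, duration and fs must be positive")
  }

  set.seed(as.integer(seed))
  n <- round(p$duration_s * p$fs)
  nc <- p$n_channels
  t <- (seq_len(n) - 1) / p$fs

  rz_idx <- sort(sample.int(nc, p$n_rz))
  soz_idx <- sort(sample(rz_idx, p$n_soz))
  soz <- seq_len(nc) %in% soz_idx
  rz <- seq_len(nc) %in% rz_idx

  gamma_band <- c(70, 110)
  bg_bands <- fc_bands()
  ## band-source RMS tracks the in-band 1/f^2 background level (low-band
  ## rhythms are large, gamma rhythms small) so every band carries
  ## comparable network structure above its noise floor
  amp_band <- 8 + 1.2 * p$background_rms *
    sqrt(pmax(0, 1 / bg_bands$low - 1 / bg_bands$high))
  amp_gamma <- 5                      # uV RMS of the SOZ/global gamma sources

  ## structured background connectivity: every analysis band has a shared
  ## AM source that each channel couples to with its own random weight,
  ## giving the heterogeneous, temporally stable FC structure seen in
  ## cortical recordings
  src_bg <- lapply(seq_len(nrow(bg_bands)), function(b)
    am_band_source(n, p$fs, c(bg_bands$low[b], bg_bands$high[b])))
  w_bg <- matrix(stats::runif(nc * nrow(bg_bands), 0, p$band_coupling_bg),
                 nc, nrow(bg_bands))
  src_gamma_glob <- am_band_source(n, p$fs, gamma_band)
  src_gamma_soz <- am_band_source(n, p$fs, gamma_band)
  mod_gamma_soz <- slow_modulation(n, p$fs)

  data <- matrix(0, nc, n)
  for (ch in seq_len(nc)) {
    x <- pink_noise(n, p$fs, p$background_rms)
    for (b in seq_len(nrow(bg_bands))) {
      cb <- w_bg[ch, b]
      x <- x + amp_band[b] *
        (sqrt(cb) * src_bg[[b]] +
         sqrt(1 - cb) * am_band_source(n, p$fs,
                                       c(bg_bands$low[b], bg_bands$high[b])))
    }
    if (soz[ch]) {
      cs <- p$gamma_coupling_soz
      if (p$coupling_mode == "shared_source") {
        ## common source: correlates both envelopes and phases
        x <- x + amp_gamma * (sqrt(cs) * src_gamma_soz +
                              sqrt(1 - cs) * am_band_source(n, p$fs, gamma_band))
      } else {
        ## common envelope on an independent carrier: correlates the
        ## amplitude envelopes (AEC) without phase locking (PLV)
        mod_i <- sqrt(cs) * mod_gamma_soz +
          sqrt(1 - cs) * slow_modulation(n, p$fs)
        x <- x + amp_gamma * am_band_signal(n, p$fs, gamma_band, mod_i)
      }
    } else {
      cb <- p$gamma_coupling_bg
      x <- x + amp_gamma * (sqrt(cb) * src_gamma_glob +
                            sqrt(1 - cb) * am_band_source(n, p$fs, gamma_band))
    }
    data[ch, ] <- x
  }

  ## injected events, logged for oracle tests
  ev <- list()
  inject <- function(ch, class, rate_per_min) {
    n_ev <- stats::rpois(1, rate_per_min * p$duration_s / 60)
    if (n_ev == 0) return(NULL)
    out <- vector("list", n_ev)
    for (k in seq_len(n_ev)) {
      if (class == "spike") {
        dur <- stats::runif(1, 0.02, 0.07)
        amp <- stats::runif(1, 100, 400)
        w <- spike_waveform(p$fs, dur, amp) * sample(c(-1, 1), 1)
      } else {
        dur <- stats::runif(1, 0.03, 0.08)
        amp <- stats::runif(1, 10, 40)
        w <- hfo_waveform(p$fs, dur, stats::runif(1, 100, 200), amp)
      }
      t0 <- stats::runif(1, 0, p$duration_s - dur)
      i0 <- round(t0 * p$fs) + 1L
      idx <- i0:(i0 + length(w) - 1L)
      data[ch, idx] <<- data[ch, idx] + w
      out[[k]] <- data.frame(channel = ch, class = class, time_s = t0 + dur / 2,
                             amplitude_uV = amp)
    }
    do.call(rbind, out)
  }
  for (ch in seq_len(nc)) {
    ev[[length(ev) + 1L]] <- inject(ch, "spike",
      if (soz[ch]) p$spike_rate_soz else p$spike_rate_bg)
    ev[[length(ev) + 1L]] <- inject(ch, "hfo",
      if (soz[ch]) p$hfo_rate_soz else p$hfo_rate_bg)
  }
  events <- do.call(rbind, ev)
  if (is.null(events)) {
    events <- data.frame(channel = integer(), class = character(),
                         time_s = numeric(), amplitude_uV = numeric())
  }

  ## 60 Hz line noise + first five harmonics (120..360 Hz), amplitude 1/k
  if (p$line_noise_amp > 0) {
    line <- numeric(n)
    for (k in 1:6) {
      fk <- 60 * k
      if (fk < p$fs / 2) {
        line <- line + (p$line_noise_amp / k) *
          sin(2 * pi * fk * t + stats::runif(1, 0, 2 * pi))
      }
    }
    data <- sweep(data, 2, line, "+")
  }

  ## rectangular high-amplitude artifacts (one random channel, 1-5 s)
  artifacts <- data.frame(channel = integer(), start_s = numeric(),
                          end_s = numeric(), amplitude_uV = numeric())
  n_ep <- floor(p$duration_s / 12)
  if (p$artifact_epoch_fraction > 0 && n_ep > 0) {
    hit <- which(stats::runif(n_ep) < p$artifact_epoch_fraction)
    for (e in hit) {
      len <- min(stats::runif(1, 1, 5), 12)
      start <- (e - 1) * 12 + stats::runif(1, 0, 12 - len)
      ch <- sample.int(nc, 1)
      amp <- 4000 * sample(c(-1, 1), 1)
      idx <- (round(start * p$fs) + 1L):min(n, round((start + len) * p$fs))
      data[ch, idx] <- data[ch, idx] + amp
      artifacts <- rbind(artifacts,
        data.frame(channel = ch, start_s = start, end_s = start + len,
                   amplitude_uV = amp))
    }
  }

  rec <- ieeg_recording(data, fs = p$fs, patient_id = p$patient_id)
  ann <- channel_annotation(soz, rz)
  prov <- list(patient_id = p$patient_id, n_channels = nc,
               soz_idx = soz_idx, rz_idx = rz_idx,
               events = events, artifacts = artifacts, seed = as.integer(seed))
  list(recording = rec, annotation = ann, provenance = prov)
}

#' Generate a synthetic iEEG cohort
#'
#' Draws per-patient channel, SOZ and RZ counts within the configured ranges
#' and calls [generate_recording()] per patient with a per-patient seed
#' derived from the master seed. Ground-truth event times, zone index sets
#' and artifact windows are retained in a provenance log.
#'
#' @param cfg A [cohort_config()].
#' @return A list of class `ieeg_cohort`: one element per patient with
#'   `recording`, `annotation`, `provenance`; the per-patient provenance
#'   entries are also collected in `attr(, "provenance")`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max, cfg$n_patients)
  draw_in <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)
  patients <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    nc <- draw_in(cfg$channels_per_patient[1], cfg$channels_per_patient[2])
    rz_max <- min(cfg$rz_channels[2], nc)
    rz_min <- min(cfg$rz_channels[1], rz_max)
    n_rz <- draw_in(rz_min, rz_max)
    soz_max <- min(cfg$soz_channels[2], n_rz)
    soz_min <- min(cfg$soz_channels[1], soz_max)
    n_soz <- draw_in(soz_min, soz_max)
    params <- c(list(n_channels = nc, n_soz = n_soz, n_rz = n_rz,
                     patient_id = sprintf("P%02d", i)),
                cfg[c("duration_s", "fs", "gamma_coupling_soz",
                      "gamma_coupling_bg", "band_coupling_bg",
                      "spike_rate_soz", "spike_rate_bg",
                      "hfo_rate_soz", "hfo_rate_bg", "line_noise_amp",
                      "artifact_epoch_fraction", "background_rms",
                      "coupling_mode")])
    patients[[i]] <- generate_recording(params, seed = seeds[i])
  }
  structure(patients, class = "ieeg_cohort",
            provenance = lapply(patients, `[[`, "provenance"))
}

#' @export
print.ieeg_cohort <- function(x, ...) {
  nc <- vapply(x, function(p) nrow(p$recording$data), integer(1))
  cat(sprintf("synthetic iEEG cohort: %d patients, %d channels total (%d-%d per patient)\n",
              length(x), sum(nc), min(nc), max(nc)))
  invisible(x)
}

#' Write a cohort provenance log as JSON
#' @param cohort An `ieeg_cohort`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(cohort, path) {
  jsonlite::write_json(attr(cohort, "provenance"), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}
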