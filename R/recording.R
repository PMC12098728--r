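#' Multichannel iEEG recording
#'
#' Container for a block of intracranial EEG: a channels x samples numeric
#' matrix in microvolts, its sampling rate, channel labels and a patient
#' identifier.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per channel.
#' @param patient_id Single string identifying the patient.
#' @return An object of class `ieeg_recording`.
#' @export
ieeg_recording <- function(data, fs, channel_labels = NULL, patient_id = "P1") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (any(!is.finite(data))) stop("recording contains non-finite samples")
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("number of channel labels (", length(channel_labels),
         ") does not match channel count (", nrow(data), ")")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  structure(
    list(data = data, fs = fs,
         channel_labels = as.character(channel_labels),
         patient_id = as.character(patient_id)),
    class = "ieeg_recording")
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf("iEEG recording: patient %s, %d channels, %.1f s at %g Hz\n",
              x$patient_id, nrow(x$data), ncol(x$data) / x$fs, x$fs))
  invisible(x)
}

#' @export
dim.ieeg_recording <- function(x) dim(x$data)

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Per-channel SOZ / RZ / bad-channel annotation
#'
#' Binary flags per channel: membership in the clinically defined seizure
#' onset zone (SOZ) and resection zone (RZ), and a bad-channel exclusion
#' flag. In clinical and synthetic cohorts used here the SOZ is contained
#' in the RZ.
#'
#' @param soz,rz,bad Logical (or 0/1) vectors of equal length, one entry per
#'   channel. `bad` defaults to all-FALSE.
#' @return An object of class `channel_annotation` (a data frame).
#' @export
channel_annotation <- function(soz, rz, bad = NULL) {
  soz <- as.logical(soz); rz <- as.logical(rz)
  if (is.null(bad)) bad <- rep(FALSE, length(soz))
  bad <- as.logical(bad)
  if (length(rz) != length(soz) || length(bad) != length(soz)) {
    stop("soz, rz and bad flags must have the same length")
  }
  if (anyNA(soz) || anyNA(rz) || anyNA(bad)) stop("annotation flags must not be NA")
  structure(data.frame(soz = soz, rz = rz, bad = bad),
            class = c("channel_annotation", "data.frame"))
}

#' @export
print.channel_annotation <- function(x, ...) {
  cat(sprintf("channel annotation: %d channels (%d SOZ, %d RZ, %d bad)\n",
              nrow(x), sum(x$soz), sum(x$rz), sum(x$bad)))
  invisible(x)
}

#' Write a recording as a delimited matrix plus JSON sidecar
#'
#' The signal matrix is written as a tab-delimited text file (channels x
#' samples, no header) and the metadata (sampling rate, channel labels,
#' patient id) as `<prefix>.json`.
#'
#' @param rec An [ieeg_recording()].
#' @param prefix Path prefix; files `<prefix>.tsv` and `<prefix>.json` are
#'   written.
#' @return The prefix, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "ieeg_recording"))
  utils::write.table(rec$data, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(fs = rec$fs, channel_labels = rec$channel_labels,
               patient_id = rec$patient_id)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a recording written by [write_recording()]
#' @param prefix Path prefix used when writing.
#' @return An [ieeg_recording()].
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  data <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(data) <- NULL
  ieeg_recording(data, fs = meta$fs, channel_labels = meta$channel_labels,
                 patient_id = meta$patient_id)
}

#' Write / read channel annotations as CSV
#'
#' Three-column CSV: channel label, soz flag, rz flag (plus bad flag).
#' @param ann A [channel_annotation()].
#' @param path CSV file path.
#' @param labels Optional channel labels (default `ch<k>`).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(ann)))
  utils::write.csv(
    data.frame(channel = labels, soz = as.integer(ann$soz),
               rz = as.integer(ann$rz), bad = as.integer(ann$bad)),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- utils::read.csv(path)
  channel_annotation(df$soz, df$rz, if ("bad" %in% names(df)) df$bad else NULL)
}
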