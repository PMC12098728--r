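#' Segment a recording into non-overlapping epochs
#'
#' Consecutive `epoch_s`-second epochs starting at sample 1; any remainder
#' is discarded. A 30-minute recording yields 150 epochs of 12 s.
#'
#' @param rec An [ieeg_recording()].
#' @param epoch_s Epoch length in seconds (default 12).
#' @return A data frame of class `epoch_set` with sample-index columns
#'   `start`, `end`, a logical `artifact` flag column (initially all
#'   FALSE), and attributes `fs` and `epoch_s`.
#' @export
segment_epochs <- function(rec, epoch_s = 12) {
  stopifnot(inherits(rec, "ieeg_recording"))
  len <- round(epoch_s * rec$fs)
  n_ep <- floor(n_samples(rec) / len)
  if (n_ep < 1) stop("recording shorter than one epoch (", epoch_s, " s)")
  start <- (seq_len(n_ep) - 1L) * len + 1L
  structure(data.frame(start = start, end = start + len - 1L,
                       artifact = FALSE),
            fs = rec$fs, epoch_s = epoch_s, selected = NULL,
            class = c("epoch_set", "data.frame"))
}

#' Flag epochs containing high-amplitude artifacts
#'
#' An epoch is flagged if any sample on any channel of the unfiltered
#' (pre-band-pass) recording has absolute amplitude strictly greater than
#' the threshold.
#'
#' @param raw The pre-band-pass [ieeg_recording()] aligned with `epochs`.
#' @param epochs An [segment_epochs()] result.
#' @param threshold_uV Exclusion threshold, strict (default 3000 uV).
#' @return `epochs` with its `artifact` column updated.
#' @export
flag_artifact_epochs <- function(raw, epochs, threshold_uV = 3000) {
  stopifnot(inherits(raw, "ieeg_recording"), inherits(epochs, "epoch_set"))
  flags <- vapply(seq_len(nrow(epochs)), function(e) {
    any(abs(raw$data[, epochs$start[e]:epochs$end[e]]) > threshold_uV)
  }, logical(1))
  epochs$artifact <- flags
  epochs
}

#' Randomly select clean epochs
#'
#' Uniform sample without replacement among unflagged epochs; deterministic
#' under `seed`.
#'
#' @param epochs An `epoch_set` (flags set by [flag_artifact_epochs()]).
#' @param n Number of epochs to select (default 100).
#' @param seed RNG seed.
#' @param allow_fewer If TRUE and fewer than `n` clean epochs exist, all of
#'   them are selected with a warning; otherwise this is an error.
#' @return `epochs` with an attribute `selected` (sorted epoch indices).
#' @export
select_epochs <- function(epochs, n = 100, seed = 1L, allow_fewer = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  clean <- which(!epochs$artifact)
  if (length(clean) < n) {
    if (!allow_fewer) {
      stop("only ", length(clean), " clean epochs available, ", n,
           " requested (shortfall ", n - length(clean), ")")
    }
    warning("only ", length(clean), " clean epochs available; using all")
    sel <- clean
  } else {
    set.seed(as.integer(seed))
    sel <- sort(sample(clean, n))
  }
  attr(epochs, "selected") <- sel
  epochs
}

selected_epochs <- function(epochs) {
  sel <- attr(epochs, "selected")
  if (is.null(sel)) which(!epochs$artifact) else sel
}

#' Amplitude envelope correlation of one epoch
#'
#' Pearson correlation of two Hilbert amplitude envelopes. Undefined
#' (returns NA) when either envelope has zero variance; such epochs are
#' excluded from epoch averages rather than zero-filled.
#'
#' @param env_x,env_y Numeric envelope vectors of equal length.
#' @return Correlation in \[-1, 1\], or NA.
#' @export
aec <- function(env_x, env_y) {
  stopifnot(length(env_x) == length(env_y))
  if (stats::sd(env_x) == 0 || stats::sd(env_y) == 0) return(NA_real_)
  stats::cor(env_x, env_y)
}

#' Phase locking value of one epoch
#'
#' Magnitude of the time-averaged unit phasor of the phase difference:
#' `|mean(exp(i (phase_x - phase_y)))|`, in \[0, 1\].
#'
#' @param phase_x,phase_y Instantaneous-phase vectors (radians) of equal
#'   length.
#' @return PLV in \[0, 1\].
#' @export
plv <- function(phase_x, phase_y) {
  stopifnot(length(phase_x) == length(phase_y))
  Mod(mean(exp(1i * (phase_x - phase_y))))
}

## Pairwise AEC matrix from an envelope matrix (samples x channels).
## Zero-variance channels give NA rows/columns (diagonal stays 1).
aec_matrix <- function(env) {
  sds <- apply(env, 2, stats::sd)
  m <- suppressWarnings(stats::cor(env))
  m[sds == 0, ] <- NA_real_
  m[, sds == 0] <- NA_real_
  diag(m) <- 1
  m
}

## Pairwise PLV matrix from a phase matrix (samples x channels).
plv_matrix <- function(phase) {
  z <- exp(1i * phase)
  m <- Mod(t(Conj(z)) %*% z) / nrow(phase)
  diag(m) <- 1
  (m + t(m)) / 2
}

#' Epoch-averaged functional connectivity stack
#'
#' For each measure (AEC, PLV) and frequency band, band-pass filters the
#' recording (two-pass zero-phase FIR), computes the mirror-padded analytic
#' signal per selected epoch, forms the pairwise connectivity matrix, and
#' averages over epochs. Per-epoch AEC entries that are undefined
#' (zero-variance envelope) are excluded from the average. No thresholding
#' of connectivity values is performed.
#'
#' @param rec A preprocessed [ieeg_recording()].
#' @param epochs An `epoch_set` with selected epochs.
#' @param bands Band definitions (default [fc_bands()]).
#' @param measures Character subset of `c("aec", "plv")`.
#' @param keep_epochs If TRUE, per-epoch matrices are retained (needed by
#'   epoch-count and stability analyses).
#' @return An object of class `connectivity_stack`: nested list
#'   `x[[measure]][[band_tag]]` of N x N symmetric epoch-averaged matrices
#'   with unit diagonal, with attributes `n_epochs`, `bands`, `measures`,
#'   and (optionally) `epochwise`.
#' @export
connectivity_stack <- function(rec, epochs, bands = fc_bands(),
                               measures = c("aec", "plv"),
                               keep_epochs = FALSE) {
  stopifnot(inherits(rec, "ieeg_recording"), inherits(epochs, "epoch_set"))
  measures <- match.arg(measures, c("aec", "plv"), several.ok = TRUE)
  sel <- selected_epochs(epochs)
  if (length(sel) < 1) stop("no selected epochs")
  nc <- n_channels(rec)
  xt <- t(rec$data)                    # samples x channels
  out <- stats::setNames(vector("list", length(measures)), measures)
  epochwise <- stats::setNames(vector("list", length(measures)), measures)
  for (m in measures) {
    out[[m]] <- stats::setNames(vector("list", nrow(bands)), bands$tag)
    epochwise[[m]] <- stats::setNames(vector("list", nrow(bands)), bands$tag)
  }
  for (b in seq_len(nrow(bands))) {
    coefs <- fir_bandpass_coef(c(bands$low[b], bands$high[b]), rec$fs)
    filt <- fir_twopass_matrix(xt, coefs)
    per_ep <- stats::setNames(
      lapply(measures, function(m) array(NA_real_, c(nc, nc, length(sel)))),
      measures)
    for (k in seq_along(sel)) {
      e <- sel[k]
      a <- analytic_epoch(filt[epochs$start[e]:epochs$end[e], , drop = FALSE])
      if ("aec" %in% measures) per_ep$aec[, , k] <- aec_matrix(a$envelope)
      if ("plv" %in% measures) per_ep$plv[, , k] <- plv_matrix(a$phase)
    }
    for (m in measures) {
      avg <- apply(per_ep[[m]], c(1, 2), mean, na.rm = TRUE)
      avg[!is.finite(avg)] <- NA_real_
      diag(avg) <- 1
      out[[m]][[bands$tag[b]]] <- (avg + t(avg)) / 2
      if (keep_epochs) epochwise[[m]][[bands$tag[b]]] <- per_ep[[m]]
    }
  }
  structure(out, class = "connectivity_stack",
            n_epochs = length(sel), bands = bands, measures = measures,
            epochwise = if (keep_epochs) epochwise else NULL)
}

#' @export
print.connectivity_stack <- function(x, ...) {
  cat(sprintf("connectivity stack: measures {%s}, %d bands, %d channels, %d epochs\n",
              paste(attr(x, "measures"), collapse = ", "),
              nrow(attr(x, "bands")), nrow(x[[1]][[1]]), attr(x, "n_epochs")))
  invisible(x)
}

#' Write a connectivity stack as delimited matrices plus JSON metadata
#'
#' One tab-delimited matrix file per measure x band (with channel-label
#' header) and a `meta.json` holding epochs, bands and measures.
#'
#' @param stack A [connectivity_stack()].
#' @param dir Output directory (created if needed).
#' @param labels Optional channel labels.
#' @return `dir`, invisibly.
#' @export
write_connectivity <- function(stack, dir, labels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(stack[[1]][[1]])))
  for (m in attr(stack, "measures")) {
    for (tag in names(stack[[m]])) {
      mt <- stack[[m]][[tag]]
      dimnames(mt) <- list(NULL, labels)
      utils::write.table(mt, file.path(dir, sprintf("%s_%s.tsv", m, tag)),
                         sep = "\t", row.names = FALSE, col.names = TRUE)
    }
  }
  jsonlite::write_json(
    list(n_epochs = attr(stack, "n_epochs"),
         measures = attr(stack, "measures"),
         bands = attr(stack, "bands")),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Normalized node strength
#'
#' Sum of a node's off-diagonal connection weights divided by the channel
#' count N, so values are comparable across patients with different
#' electrode counts. Negative weights are kept as-is (no thresholding).
#'
#' @param m Symmetric N x N connectivity matrix.
#' @return Numeric vector of length N.
#' @export
node_strength <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("node strength needs at least 2 nodes")
  (rowSums(m, na.rm = TRUE) - diag(m)) / nrow(m)
}

#' Eigenvector centrality
#'
#' Leading eigenvector (largest eigenvalue) of the off-diagonal
#' connectivity matrix, sign-fixed non-negative and normalized to unit
#' Euclidean norm. Negative entries are clipped to zero first, since the
#' Perron-Frobenius leading-eigenvector construction requires a
#' non-negative matrix; the number of clipped entries is recorded in the
#' `n_clipped` attribute. An all-zero matrix returns the uniform vector
#' with a warning.
#'
#' @param m Symmetric N x N connectivity matrix.
#' @return Numeric vector of length N (unit norm, non-negative).
#' @export
eigenvector_centrality <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("eigenvector centrality needs at least 2 nodes")
  m[is.na(m)] <- 0
  diag(m) <- 0
  n_clipped <- sum(m < 0)
  m[m < 0] <- 0
  if (all(m == 0)) {
    warning("all-zero connectivity matrix; returning uniform centrality")
    v <- rep(1 / sqrt(nrow(m)), nrow(m))
    return(structure(v, n_clipped = n_clipped))
  }
  es <- eigen(m, symmetric = TRUE)
  v <- es$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v[v < 0] <- 0
  structure(v / sqrt(sum(v^2)), n_clipped = n_clipped)
}

#' Rescale a per-node feature to \[0, 1\] within one patient
#'
#' `(v - min) / (max - min)`; a constant vector maps to all zeros.
#'
#' @param v Numeric vector.
#' @return Rescaled vector in \[0, 1\].
#' @export
rescale_per_patient <- function(v) {
  if (!length(v)) stop("empty feature vector")
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(0, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Per-node graph features from a connectivity stack
#'
#' Node strength and eigenvector centrality for every measure x band,
#' each rescaled to \[0, 1\] at the individual-patient level (separately
#' per feature). With 2 measures x 8 bands x 2 metrics this yields the 32
#' connectivity features per channel.
#'
#' @param stack A [connectivity_stack()].
#' @return N x (2 x bands x measures) matrix with columns named
#'   `<measure>_ns_<band>` and `<measure>_evc_<band>`.
#' @export
graph_features <- function(stack) {
  stopifnot(inherits(stack, "connectivity_stack"))
  measures <- attr(stack, "measures")
  bands <- attr(stack, "bands")
  nc <- nrow(stack[[1]][[1]])
  cols <- list()
  for (m in measures) {
    for (metric in c("ns", "evc")) {
      for (tag in bands$tag) {
        mt <- stack[[m]][[tag]]
        v <- if (metric == "ns") node_strength(mt)
             else as.numeric(eigenvector_centrality(mt))
        cols[[paste(m, metric, tag, sep = "_")]] <- rescale_per_patient(v)
      }
    }
  }
  do.call(cbind, cols)
}
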