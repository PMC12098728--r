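#' Feature schema for the default 45-feature-per-channel table
#'
#' Fixed, documented column order: spike rate and amplitude (2), HFO rate
#' and amplitude (2), nine Welch band powers, then AEC node strength (8
#' bands), AEC eigenvector centrality (8), PLV node strength (8), PLV
#' eigenvector centrality (8) - 45 columns in total under the default
#' bands and measures.
#'
#' @param bands_psd PSD band definitions (default [psd_bands()]).
#' @param bands_fc Connectivity band definitions (default [fc_bands()]).
#' @param measures Connectivity measures included.
#' @return Data frame with columns `column`, `family`, `measure`, `metric`,
#'   `band`.
#' @export
feature_schema <- function(bands_psd = psd_bands(), bands_fc = fc_bands(),
                           measures = c("aec", "plv")) {
  rows <- list(
    data.frame(column = c("spike_rate", "spike_amp"), family = "spike",
               measure = NA, metric = c("rate", "amplitude"), band = NA),
    data.frame(column = c("hfo_rate", "hfo_amp"), family = "hfo",
               measure = NA, metric = c("rate", "amplitude"), band = NA),
    data.frame(column = paste0("psd_", bands_psd$tag), family = "psd",
               measure = NA, metric = "power", band = bands_psd$tag))
  for (m in measures) {
    for (metric in c("ns", "evc")) {
      rows[[length(rows) + 1L]] <- data.frame(
        column = paste(m, metric, bands_fc$tag, sep = "_"),
        family = "fc", measure = m, metric = metric, band = bands_fc$tag)
    }
  }
  do.call(rbind, rows)
}

#' Assemble per-channel feature blocks into a feature table
#'
#' Column-concatenates the four feature families for one patient and
#' attaches channel metadata and SOZ/RZ labels.
#'
#' @param spikes,hfos [summarize_events()] outputs for the spike and HFO
#'   event sets.
#' @param psd Channels x 9 band-power matrix from [welch_band_psd()].
#' @param graph Channels x 32 matrix from [graph_features()].
#' @param annotation A [channel_annotation()].
#' @param patient_id Patient identifier for every row.
#' @param labels Optional channel labels.
#' @return A `feature_table`: data frame with metadata columns
#'   `patient_id`, `channel`, `soz`, `rz` followed by the feature columns;
#'   the schema is attached as attribute `"schema"`.
#' @export
assemble_features <- function(spikes, hfos, psd, graph, annotation,
                              patient_id, labels = NULL) {
  nc <- nrow(psd)
  if (nrow(spikes) != nc || nrow(hfos) != nc || nrow(graph) != nc ||
      nrow(annotation) != nc) {
    stop("alignment error: feature blocks have differing channel counts")
  }
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nc))
  feat <- cbind(spike_rate = spikes$rate_per_min,
                spike_amp = spikes$mean_amplitude_uV,
                hfo_rate = hfos$rate_per_min,
                hfo_amp = hfos$mean_amplitude_uV,
                psd, graph)
  if (anyNA(feat)) stop("feature table contains missing values")
  df <- data.frame(patient_id = patient_id, channel = labels,
                   soz = annotation$soz, rz = annotation$rz,
                   feat, check.names = FALSE)
  measures <- unique(stats::na.omit(sub("_(ns|evc)_.*$", "",
    grep("_(ns|evc)_", colnames(graph), value = TRUE))))
  schema <- feature_schema(measures = measures)
  schema <- schema[schema$column %in% colnames(feat), ]
  structure(df, schema = schema, class = c("feature_table", "data.frame"))
}

feature_columns <- function(table) {
  setdiff(colnames(table), c("patient_id", "channel", "soz", "rz"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature table: %d channels x %d features, %d patients (%d SOZ, %d RZ channels)\n",
              nrow(x), length(feature_columns(x)),
              length(unique(x$patient_id)), sum(x$soz), sum(x$rz)))
  invisible(x)
}

#' @export
summary.feature_table <- function(object, ...) {
  fam <- attr(object, "schema")$family
  cat("feature families:\n")
  print(table(fam))
  invisible(object)
}

#' Extract the full feature set for one patient
#'
#' Runs the per-patient pipeline: preprocessing (bad-channel drop,
#' power-line removal, common average reference), Welch band power, spike
#' and HFO detection, epoch segmentation with artifact exclusion and random
#' epoch selection, connectivity estimation in the eight bands, graph
#' metrics, and feature assembly.
#'
#' @param rec Raw [ieeg_recording()].
#' @param ann [channel_annotation()].
#' @param n_epochs Number of clean epochs used for connectivity (default
#'   100); fewer are used with a warning if not enough are available.
#' @param measures Connectivity measures (`"aec"`, `"plv"`).
#' @param epoch_seed Seed for the random epoch selection.
#' @param preprocess_cfg A [preprocess_config()].
#' @return A `feature_table` with one row per retained channel.
#' @export
extract_features <- function(rec, ann, n_epochs = 100,
                             measures = c("aec", "plv"), epoch_seed = 1L,
                             preprocess_cfg = preprocess_config()) {
  pp <- preprocess(rec, ann, preprocess_cfg)
  clean <- pp$recording
  psd <- welch_band_psd(clean)
  spikes <- summarize_events(detect_spikes(clean))
  hfos <- summarize_events(detect_hfos(clean))
  epochs <- segment_epochs(clean)
  epochs <- flag_artifact_epochs(clean, epochs)
  epochs <- suppressWarnings(
    select_epochs(epochs, n = n_epochs, seed = epoch_seed, allow_fewer = TRUE))
  stack <- connectivity_stack(clean, epochs, measures = measures)
  graph <- graph_features(stack)
  assemble_features(spikes, hfos, psd, graph, pp$annotation,
                    clean$patient_id, clean$channel_labels)
}

#' Extract features for a whole cohort
#'
#' @param cohort An `ieeg_cohort` from [generate_cohort()] (or any list of
#'   `recording`/`annotation` pairs).
#' @param seed Master seed; per-patient epoch-selection seeds are derived
#'   from it.
#' @param ... Passed to [extract_features()].
#' @return A combined `feature_table`.
#' @export
extract_cohort_features <- function(cohort, seed = 1L, ...) {
  set.seed(as.integer(seed))
  ep_seeds <- sample.int(.Machine$integer.max, length(cohort))
  tabs <- lapply(seq_along(cohort), function(i) {
    extract_features(cohort[[i]]$recording, cohort[[i]]$annotation,
                     epoch_seed = ep_seeds[i], ...)
  })
  out <- do.call(rbind, lapply(tabs, as.data.frame))
  structure(out, schema = attr(tabs[[1]], "schema"),
            class = c("feature_table", "data.frame"))
}

#' Scale features by their maximum across patients
#'
#' Divides every feature column by its maximum absolute value over
#' `fit_rows`, minimizing magnitude differences across features while
#' preserving the rank order of each feature. The default fits on all rows
#' (the whole-cohort convention); inside cross-validation the leakage-safe
#' choice is to pass the training rows.
#'
#' @param table A `feature_table`.
#' @param fit_rows Row indices used to fit the scaling (default all rows).
#' @return The scaled `feature_table`.
#' @export
scale_across_patients <- function(table, fit_rows = seq_len(nrow(table))) {
  if (!length(fit_rows)) stop("fit_rows must be non-empty")
  for (col in feature_columns(table)) {
    mx <- max(abs(table[[col]][fit_rows]))
    if (mx == 0) {
      warning("feature '", col, "' is all zero over fit rows; left unchanged")
      next
    }
    table[[col]] <- table[[col]] / mx
  }
  table
}

#' Named feature subsets
#'
#' The feature subsets used for classifier comparisons, with their column
#' counts under the default schema: All (45), All AEC (16), All PLV (16),
#' High Gamma AEC (6; node strength and eigenvector centrality in
#' 70-110, 130-170, 190-230 Hz), Theta-Beta AEC (6; 4-8, 8-12, 15-25 Hz),
#' Gamma AEC NS (4; node strength in 35-50, 70-110, 130-170, 190-230 Hz),
#' Gamma AEC EVC (4), Spike + HFO (4), PSD (9), PSD + Spike + HFO (13).
#'
#' @return Named list of character vectors of column names.
#' @export
feature_subsets <- function() {
  hg <- c("70_110", "130_170", "190_230")
  tb <- c("4_8", "8_12", "15_25")
  gm <- c("35_50", "70_110", "130_170", "190_230")
  all_fc_bands <- fc_bands()$tag
  aec_cols <- function(metric, bands) paste("aec", metric, bands, sep = "_")
  plv_cols <- function(metric, bands) paste("plv", metric, bands, sep = "_")
  psd_cols <- paste0("psd_", psd_bands()$tag)
  ev_cols <- c("spike_rate", "spike_amp", "hfo_rate", "hfo_amp")
  list(
    "All" = c(ev_cols, psd_cols,
              aec_cols("ns", all_fc_bands), aec_cols("evc", all_fc_bands),
              plv_cols("ns", all_fc_bands), plv_cols("evc", all_fc_bands)),
    "All AEC" = c(aec_cols("ns", all_fc_bands), aec_cols("evc", all_fc_bands)),
    "All PLV" = c(plv_cols("ns", all_fc_bands), plv_cols("evc", all_fc_bands)),
    "High Gamma AEC" = c(aec_cols("ns", hg), aec_cols("evc", hg)),
    "Theta-Beta AEC" = c(aec_cols("ns", tb), aec_cols("evc", tb)),
    "Gamma AEC NS" = aec_cols("ns", gm),
    "Gamma AEC EVC" = aec_cols("evc", gm),
    "Spike + HFO" = ev_cols,
    "PSD" = psd_cols,
    "PSD + Spike + HFO" = c(psd_cols, ev_cols))
}

normalize_subset_name <- function(name) {
  tolower(gsub("[^a-z0-9]+", "", tolower(name)))
}

#' Restrict a feature table to a named subset of columns
#'
#' @param table A `feature_table`.
#' @param subset Either a subset name from [feature_subsets()]
#'   (case/punctuation-insensitive) or a character vector of feature column
#'   names.
#' @return The column-projected `feature_table` (values unchanged).
#' @export
select_feature_subset <- function(table, subset) {
  if (length(subset) == 1 &&
      normalize_subset_name(subset) %in%
        vapply(names(feature_subsets()), normalize_subset_name, "")) {
    subs <- feature_subsets()
    key <- which(vapply(names(subs), normalize_subset_name, "") ==
                   normalize_subset_name(subset))
    cols <- subs[[key]]
  } else {
    cols <- subset
  }
  missing <- setdiff(cols, colnames(table))
  if (length(missing)) {
    stop("unknown feature columns: ", paste(missing, collapse = ", "))
  }
  out <- table[, c("patient_id", "channel", "soz", "rz", cols)]
  schema <- attr(table, "schema")
  structure(out, schema = schema[schema$column %in% cols, ],
            class = c("feature_table", "data.frame"))
}

#' Write / read a feature table as CSV plus JSON schema sidecar
#'
#' @param table A `feature_table`.
#' @param path CSV path; the schema is written next to it as
#'   `<path>.schema.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  jsonlite::write_json(attr(table, "schema"), paste0(path, ".schema.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  df$soz <- as.logical(df$soz); df$rz <- as.logical(df$rz)
  schema <- jsonlite::read_json(paste0(path, ".schema.json"),
                                simplifyVector = TRUE)
  structure(df, schema = schema, class = c("feature_table", "data.frame"))
}
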