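# Shared fixtures, generated once per session and cached. Sizes follow the
# scaled study conditions: 6-8 patients, 10-14 channels, 4-minute
# recordings, 15 connectivity epochs.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Strong-effect cohort: elevated SOZ gamma coupling (shared source) plus
# elevated spike/HFO rates.
strong_cohort <- function(seed = 101) {
  cached(paste0("strong_cohort_", seed), {
    cfg <- cohort_config(
      n_patients = 6, channels_per_patient = c(10, 14),
      soz_channels = c(2, 4), rz_channels = c(4, 6), duration_s = 240,
      gamma_coupling_soz = 0.8, gamma_coupling_bg = 0.05,
      spike_rate_soz = 2, spike_rate_bg = 0.5,
      hfo_rate_soz = 1.5, hfo_rate_bg = 0.3, seed = seed)
    generate_cohort(cfg)
  })
}

strong_features <- function(seed = 101) {
  cached(paste0("strong_features_", seed), {
    extract_cohort_features(strong_cohort(seed), n_epochs = 15, seed = seed)
  })
}

# Effect-free cohorts: zero zone-specific coupling and equal event rates,
# so SOZ channels differ from the rest in nothing but the label. Several
# small cohorts are generated; single-cohort CV AUCs at this scale have
# sd ~0.1 (node-level CV also exploits chance within-patient correlations),
# so null calibration checks average across cohorts.
null_tables <- function(n_cohorts = 4) {
  cached(paste0("null_tables_", n_cohorts), {
    lapply(seq_len(n_cohorts), function(s) {
      cfg <- cohort_config(
        n_patients = 5, channels_per_patient = c(10, 12),
        soz_channels = c(2, 4), rz_channels = c(4, 6), duration_s = 180,
        gamma_coupling_soz = 0, gamma_coupling_bg = 0,
        spike_rate_soz = 0.5, spike_rate_bg = 0.5,
        hfo_rate_soz = 0.3, hfo_rate_bg = 0.3, seed = 880 + s)
      extract_cohort_features(generate_cohort(cfg), n_epochs = 10,
                              seed = 880 + s)
    })
  })
}

# The null cohorts pooled into one table with disambiguated patient ids,
# for the group-level comparison null.
combined_null_table <- function() {
  cached("combined_null", {
    tabs <- null_tables()
    for (i in seq_along(tabs)) {
      tabs[[i]]$patient_id <- paste0("C", i, "_", tabs[[i]]$patient_id)
    }
    out <- do.call(rbind, lapply(tabs, as.data.frame))
    structure(out, schema = attr(tabs[[1]], "schema"),
              class = c("feature_table", "data.frame"))
  })
}

# Feature table with iid noise features and per-patient labels; no signal.
random_feature_table <- function(n_patients = 8, channels = 24, seed = 1) {
  set.seed(seed)
  n <- n_patients * channels
  feats <- matrix(rnorm(n * 45), n, 45)
  schema <- feature_schema()
  colnames(feats) <- schema$column
  soz <- as.logical(rbinom(n, 1, 0.2))
  rz <- soz | as.logical(rbinom(n, 1, 0.15))
  structure(
    data.frame(patient_id = rep(sprintf("P%02d", seq_len(n_patients)),
                                each = channels),
               channel = rep(sprintf("ch%02d", seq_len(channels)), n_patients),
               soz = soz, rz = rz, feats, check.names = FALSE),
    schema = schema, class = c("feature_table", "data.frame"))
}

# Feature table with a linearly separable SOZ signal in a few columns.
separable_feature_table <- function(n_patients = 6, channels = 20, seed = 2,
                                    effect = 3) {
  tab <- random_feature_table(n_patients, channels, seed)
  for (col in c("aec_ns_70_110", "aec_evc_70_110", "spike_rate")) {
    tab[[col]] <- tab[[col]] + effect * tab$soz
  }
  tab
}

# Cascaded AR(1) surrogate for 1/f^2-like background noise (test-side,
# independent of the package generator).
ar1_noise <- function(n, rms = 25, phi = 0.9) {
  x <- as.numeric(stats::filter(rnorm(n), phi, "recursive"))
  x <- as.numeric(stats::filter(x, phi, "recursive"))
  x * (rms / sd(x))
}
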