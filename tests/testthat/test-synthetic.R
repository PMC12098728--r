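test_that("identical config and seed reproduce a recording bit for bit", {
  params <- list(n_channels = 4, n_soz = 1, n_rz = 2, duration_s = 20)
  a <- generate_recording(params, seed = 7)
  b <- generate_recording(params, seed = 7)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$provenance$events, b$provenance$events)
})

test_that("infeasible zone configurations are rejected", {
  expect_error(generate_recording(list(n_channels = 4, n_soz = 3, n_rz = 2)),
               "SOZ count exceeds RZ")
  expect_error(generate_recording(list(n_channels = 4, n_soz = 4, n_rz = 5)),
               "RZ count exceeds channel")
  expect_error(cohort_config(soz_channels = c(60, 70), rz_channels = c(8, 50)),
               "infeasible")
  expect_error(cohort_config(fs = 500), "580")
})

test_that("annotation flags are consistent: SOZ inside RZ, sizes as configured", {
  g <- generate_recording(list(n_channels = 10, n_soz = 3, n_rz = 6,
                               duration_s = 15), seed = 2)
  expect_equal(sum(g$annotation$soz), 3)
  expect_equal(sum(g$annotation$rz), 6)
  expect_true(all(g$annotation$rz[g$annotation$soz]))
  expect_false(any(g$annotation$bad))
})

test_that("uncoupled, event-free channels have near-zero gamma AEC", {
  # independent channels; 100 x 12-s epochs so slow-envelope noise averages out
  g <- generate_recording(list(
    n_channels = 3, n_soz = 1, n_rz = 1, duration_s = 1210,
    gamma_coupling_soz = 0, gamma_coupling_bg = 0, band_coupling_bg = 0,
    spike_rate_soz = 0, spike_rate_bg = 0, hfo_rate_soz = 0, hfo_rate_bg = 0,
    line_noise_amp = 0, artifact_epoch_fraction = 0), seed = 31)
  ep <- segment_epochs(g$recording)
  ep <- select_epochs(flag_artifact_epochs(g$recording, ep), n = 100, seed = 1)
  st <- connectivity_stack(g$recording, ep, bands = fc_bands()[5, ],
                           measures = "aec")
  m <- st$aec[["70_110"]]
  expect_lt(max(abs(m[upper.tri(m)])), 0.1)
})

test_that("SOZ spike injection rate is three times background within Poisson error", {
  g <- generate_recording(list(
    n_channels = 12, n_soz = 6, n_rz = 8, duration_s = 240,
    spike_rate_soz = 6, spike_rate_bg = 2, hfo_rate_soz = 0, hfo_rate_bg = 0,
    artifact_epoch_fraction = 0), seed = 5)
  ev <- g$provenance$events[g$provenance$events$class == "spike", ]
  soz_idx <- g$provenance$soz_idx
  n_soz_ev <- sum(ev$channel %in% soz_idx)
  n_bg_ev <- sum(!ev$channel %in% soz_idx)
  mean_soz <- n_soz_ev / 6; mean_bg <- n_bg_ev / 6
  # lambda = 24 per SOZ channel, 8 per background channel; 3 SE tolerance
  expect_lt(abs(mean_soz - 3 * mean_bg),
            3 * sqrt(24 / 6 + 9 * 8 / 6))
  expect_gt(mean_soz, mean_bg)
})

test_that("generated cohorts respect per-patient ranges and conserve channel counts", {
  cfg <- cohort_config(n_patients = 3, channels_per_patient = c(8, 12),
                       soz_channels = c(2, 3), rz_channels = c(3, 5),
                       duration_s = 15, seed = 9)
  coh <- generate_cohort(cfg)
  expect_length(coh, 3)
  nc <- vapply(coh, function(p) nrow(p$recording$data), integer(1))
  expect_true(all(nc >= 8 & nc <= 12))
  prov <- attr(coh, "provenance")
  expect_equal(sum(nc), sum(vapply(prov, `[[`, integer(1), "n_channels")))
  # single patient, fixed channel count
  coh1 <- generate_cohort(cohort_config(n_patients = 1,
    channels_per_patient = c(4, 4), soz_channels = c(1, 1),
    rz_channels = c(2, 2), duration_s = 15, seed = 1))
  expect_equal(nrow(coh1[[1]]$recording$data), 4)
})

test_that("line noise produces a local PSD maximum at 60 Hz", {
  g <- generate_recording(list(n_channels = 2, n_soz = 1, n_rz = 1,
                               duration_s = 30, line_noise_amp = 20,
                               artifact_epoch_fraction = 0), seed = 3)
  sp <- pwelch(g$recording$data[1, ], g$recording$fs)
  i60 <- which.min(abs(sp$freq - 60))
  expect_true(all(sp$psd[i60] > sp$psd[c(i60 - 3, i60 + 3)]))
})

test_that("artifact segments exceed the 3000 uV exclusion threshold", {
  g <- generate_recording(list(n_channels = 6, n_soz = 2, n_rz = 3,
                               duration_s = 120, artifact_epoch_fraction = 0.5),
                          seed = 13)
  expect_gt(nrow(g$provenance$artifacts), 0)
  expect_gt(max(abs(g$recording$data)), 3000)
})

test_that("raising SOZ gamma coupling raises SOZ-internal gamma AEC monotonically", {
  mean_soz_aec <- function(coupling) {
    vals <- vapply(1:2, function(s) {
      g <- generate_recording(list(
        n_channels = 8, n_soz = 4, n_rz = 5, duration_s = 60,
        gamma_coupling_soz = coupling, spike_rate_soz = 0, spike_rate_bg = 0,
        hfo_rate_soz = 0, hfo_rate_bg = 0, artifact_epoch_fraction = 0),
        seed = 400 + s)
      ep <- segment_epochs(g$recording)
      ep <- select_epochs(flag_artifact_epochs(g$recording, ep), n = 5, seed = 1)
      st <- connectivity_stack(g$recording, ep, bands = fc_bands()[5, ],
                               measures = "aec")
      soz <- which(g$annotation$soz)
      m <- st$aec[["70_110"]][soz, soz]
      mean(m[upper.tri(m)])
    }, numeric(1))
    mean(vals)
  }
  levels <- vapply(c(0.1, 0.4, 0.8), mean_soz_aec, numeric(1))
  expect_true(all(diff(levels) > 0))
})

test_that("recordings and annotations round-trip through the text formats", {
  g <- generate_recording(list(n_channels = 3, n_soz = 1, n_rz = 2,
                               duration_s = 2), seed = 21)
  prefix <- file.path(withr::local_tempdir(), "rec")
  write_recording(g$recording, prefix)
  back <- read_recording(prefix)
  expect_equal(back$data, g$recording$data, tolerance = 1e-12)
  expect_equal(back$fs, g$recording$fs)
  apath <- file.path(dirname(prefix), "ann.csv")
  write_annotation(g$annotation, apath)
  expect_equal(read_annotation(apath)$soz, g$annotation$soz)
})
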