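test_that("band-pass filter preserves in-band tones and rejects out-of-band", {
  fs <- 1000; t <- (0:9999) / fs
  x <- sin(2 * pi * 10 * t)
  rec <- ieeg_recording(rbind(x), fs)
  inband <- bandpass_filter(rec, c(8, 12))$data[1, ]
  # fit a sinusoid to the interior to measure gain and phase
  mid <- 2000:8000
  fit <- lm(inband[mid] ~ sin(2 * pi * 10 * t[mid]) + cos(2 * pi * 10 * t[mid]) - 1)
  amp <- sqrt(sum(coef(fit)^2))
  phase_deg <- atan2(coef(fit)[2], coef(fit)[1]) * 180 / pi
  expect_lt(abs(amp - 1), 0.05)
  expect_lt(abs(phase_deg), 1)
  # far out-of-band rejection
  outband <- bandpass_filter(rec, c(70, 110))$data[1, ]
  expect_lt(sqrt(mean(outband^2)) / sqrt(mean(x^2)), 0.01)
  expect_error(bandpass_filter(rec, c(400, 600)), "Nyquist")
})

test_that("FIR impulse response is symmetric about its centre", {
  b <- fir_bandpass_coef(c(8, 12), 1000)
  expect_equal(b, rev(b), tolerance = 1e-12)
  b2 <- fir_bandpass_coef(c(70, 110), 1000)
  expect_equal(b2, rev(b2), tolerance = 1e-12)
})

test_that("epoch segmentation floors to whole epochs and rejects short records", {
  rec30 <- ieeg_recording(matrix(0, 1, 1800 * 100), fs = 100)
  expect_equal(nrow(segment_epochs(rec30)), 150)
  rec60 <- ieeg_recording(matrix(0, 1, 60 * 100), fs = 100)
  expect_equal(nrow(segment_epochs(rec60)), 5)
  rec11 <- ieeg_recording(matrix(0, 1, 11 * 100), fs = 100)
  expect_error(segment_epochs(rec11), "shorter than one epoch")
})

test_that("artifact flagging is strict at the 3000 uV threshold", {
  data <- matrix(0, 2, 12 * 100 * 10)
  data[2, 12 * 100 * 6 + 5] <- 3001   # inside epoch 7
  data[1, 3] <- 3000                  # exactly at threshold: not flagged
  rec <- ieeg_recording(data, fs = 100)
  ep <- flag_artifact_epochs(rec, segment_epochs(rec))
  expect_equal(which(ep$artifact), 7)
  clean <- flag_artifact_epochs(ieeg_recording(matrix(0, 1, 2400), 100),
                                segment_epochs(ieeg_recording(matrix(0, 1, 2400), 100)))
  expect_false(any(clean$artifact))
})

test_that("epoch selection is deterministic, avoids flagged epochs, and handles shortfall", {
  rec <- ieeg_recording(matrix(0, 1, 150 * 1200), fs = 100)
  ep <- segment_epochs(rec)
  s1 <- select_epochs(ep, n = 100, seed = 5)
  s2 <- select_epochs(ep, n = 100, seed = 5)
  expect_identical(attr(s1, "selected"), attr(s2, "selected"))
  expect_length(attr(s1, "selected"), 100)

  ep$artifact[1:55] <- TRUE           # 95 clean epochs remain
  expect_error(select_epochs(ep, n = 100), "shortfall 5")
  expect_warning(s3 <- select_epochs(ep, n = 100, allow_fewer = TRUE),
                 "95 clean")
  expect_length(attr(s3, "selected"), 95)
  expect_true(all(!ep$artifact[attr(s3, "selected")]))
})

test_that("analytic signal recovers envelope and phase of a tone", {
  fs <- 1000; t <- (0:11999) / fs; A <- 3.7; f <- 10
  x <- A * cos(2 * pi * f * t)
  a <- analytic_epoch(cbind(x))
  interior <- 1000:11000
  expect_lt(max(abs(a$envelope[interior, 1] - A)) / A, 0.02)
  slope <- mean(diff(signal::unwrap(a$phase[interior, 1]))) * fs
  expect_lt(abs(slope - 2 * pi * f) / (2 * pi * f), 0.01)
  expect_equal(nrow(a$envelope), length(x))
  expect_true(all(a$phase > -pi & a$phase <= pi))
})

test_that("AEC obeys its identities and null distribution", {
  set.seed(21)
  e <- abs(rnorm(12000)) + 1
  expect_equal(aec(e, e), 1.0)
  expect_equal(aec(e, 2 * e + 5), 1.0)
  expect_true(is.na(aec(e, rep(1, 12000))))
  draws <- vapply(1:50, function(i)
    abs(aec(abs(rnorm(12000)), abs(rnorm(12000)))), numeric(1))
  expect_gte(mean(draws < 0.05), 0.98)
})

test_that("PLV obeys its identities and the Rayleigh null magnitude", {
  set.seed(22)
  ph <- runif(12000, -pi, pi)
  expect_equal(plv(ph, ph), 1.0)
  expect_equal(plv(ph, ph + pi / 3), 1.0)
  n <- 12000
  draws <- vapply(1:200, function(i)
    plv(runif(n, -pi, pi), runif(n, -pi, pi)), numeric(1))
  expect_equal(mean(draws), sqrt(pi / (4 * n)), tolerance = 0.1)
  expect_gte(mean(draws < 0.03), 0.99)
})

test_that("connectivity stack equals the brute-force epoch average", {
  set.seed(23)
  g <- generate_recording(list(n_channels = 4, n_soz = 2, n_rz = 2,
                               duration_s = 60, artifact_epoch_fraction = 0),
                          seed = 77)
  rec <- g$recording
  ep <- select_epochs(flag_artifact_epochs(rec, segment_epochs(rec)),
                      n = 4, seed = 3)
  bands <- fc_bands()[c(1, 4), ]
  st <- connectivity_stack(rec, ep, bands = bands)
  # brute force: loop epochs/pairs with scalar aec()/plv()
  sel <- attr(ep, "selected")
  b <- fir_bandpass_coef(c(bands$low[2], bands$high[2]), rec$fs)
  filt <- sozpipe:::fir_twopass_matrix(t(rec$data), b)
  acc_a <- acc_p <- matrix(0, 4, 4)
  for (e in sel) {
    a <- analytic_epoch(filt[ep$start[e]:ep$end[e], ])
    for (i in 1:4) for (j in 1:4) {
      acc_a[i, j] <- acc_a[i, j] + aec(a$envelope[, i], a$envelope[, j])
      acc_p[i, j] <- acc_p[i, j] + plv(a$phase[, i], a$phase[, j])
    }
  }
  expect_equal(st$aec[[bands$tag[2]]], acc_a / length(sel), tolerance = 1e-10)
  expect_equal(st$plv[[bands$tag[2]]], acc_p / length(sel), tolerance = 1e-10)
  # duplicated channels give unit connectivity in every band
  dup <- ieeg_recording(rec$data[c(1, 1), ], rec$fs)
  st_dup <- connectivity_stack(dup, ep, bands = bands)
  expect_equal(st_dup$aec[[bands$tag[1]]][1, 2], 1, tolerance = 1e-10)
  expect_equal(st_dup$plv[[bands$tag[1]]][1, 2], 1, tolerance = 1e-10)
  # single-epoch stack equals that epoch's matrix
  attr(ep, "selected") <- sel[1]
  st1 <- connectivity_stack(rec, ep, bands = bands)
  a1 <- analytic_epoch(filt[ep$start[sel[1]]:ep$end[sel[1]], ])
  expect_equal(st1$aec[[bands$tag[2]]],
               sozpipe:::aec_matrix(a1$envelope), tolerance = 1e-10)
})

test_that("AEC is invariant to per-channel gain and matrices are symmetric", {
  set.seed(24)
  g <- generate_recording(list(n_channels = 4, n_soz = 1, n_rz = 2,
                               duration_s = 36, artifact_epoch_fraction = 0),
                          seed = 99)
  rec <- g$recording
  ep <- select_epochs(flag_artifact_epochs(rec, segment_epochs(rec)),
                      n = 3, seed = 1)
  bands <- fc_bands()[4, ]
  st <- connectivity_stack(rec, ep, bands = bands, measures = "aec")
  scaled <- rec; scaled$data[2, ] <- 7.3 * scaled$data[2, ]
  st2 <- connectivity_stack(scaled, ep, bands = bands, measures = "aec")
  expect_equal(st$aec[[1]], st2$aec[[1]], tolerance = 1e-10)
  expect_identical(st$aec[[1]], t(st$aec[[1]]))
  pl <- connectivity_stack(rec, ep, bands = bands, measures = "plv")$plv[[1]]
  expect_true(all(pl >= 0 & pl <= 1))
})

test_that("node strength matches the analytic and brute-force values", {
  m <- matrix(0.5, 4, 4); diag(m) <- 1
  expect_equal(node_strength(m), rep(0.375, 4))
  expect_equal(node_strength(diag(0, 5)), rep(0, 5))
  set.seed(25)
  for (i in 1:5) {
    r <- matrix(runif(100, -0.5, 1), 10); r <- (r + t(r)) / 2; diag(r) <- 1
    brute <- vapply(1:10, function(k) sum(r[k, -k]) / 10, numeric(1))
    expect_equal(node_strength(r), brute, tolerance = 1e-12)
  }
  expect_error(node_strength(matrix(1, 1, 1)), "at least 2")
})

test_that("eigenvector centrality matches eigen/power-iteration oracles", {
  n <- 6
  complete <- matrix(1, n, n)
  expect_equal(as.numeric(eigenvector_centrality(complete)),
               rep(1 / sqrt(n), n), tolerance = 1e-10)
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  v <- eigenvector_centrality(star)
  expect_true(all(v[1] > v[2:5]))
  set.seed(26)
  for (i in 1:5) {
    r <- matrix(runif(100), 10); r <- (r + t(r)) / 2; diag(r) <- 0
    v1 <- as.numeric(eigenvector_centrality(r))
    # power iteration oracle
    w <- rep(1, 10)
    for (it in 1:500) { w <- r %*% w; w <- w / sqrt(sum(w^2)) }
    expect_equal(v1, as.numeric(w), tolerance = 1e-8)
    # independent library oracle (igraph scales the maximum to 1)
    gi <- igraph::graph_from_adjacency_matrix(r, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    vi <- igraph::eigen_centrality(gi)$vector
    expect_equal(v1 / max(v1), as.numeric(vi), tolerance = 1e-6)
  }
  expect_warning(u <- eigenvector_centrality(matrix(0, 4, 4)), "all-zero")
  expect_equal(as.numeric(u), rep(0.5, 4))
})

test_that("per-patient rescaling maps to [0,1] with the degenerate convention", {
  expect_equal(rescale_per_patient(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(rescale_per_patient(rep(3, 5)), rep(0, 5))
  set.seed(27)
  v <- rnorm(20)
  r <- rescale_per_patient(v)
  expect_equal(range(r), c(0, 1))
  expect_equal(order(r), order(v))
})
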