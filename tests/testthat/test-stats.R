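test_that("paired Wilcoxon agrees with the exact sign-flip enumeration", {
  # exact null: enumerate all 2^n sign assignments of the ranked |d|
  exact_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- signs %*% r
    ev <- n * (n + 1) / 4
    mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-9)
  }
  set.seed(51)
  for (i in 1:8) {
    n <- sample(5:12, 1)
    a <- rnorm(n); b <- rnorm(n)
    res <- sozpipe:::paired_signed_rank(a, b)
    expect_equal(res$p.value, exact_p(a - b), tolerance = 1e-10)
  }
  # all-same-sign differences, n = 10: exact two-sided p = 2/2^10
  res <- sozpipe:::paired_signed_rank(seq(0.1, 1, by = 0.1) + 10, rep(10, 10))
  expect_equal(res$p.value, 2 / 2^10, tolerance = 1e-12)
  # identical samples: no evidence
  res0 <- sozpipe:::paired_signed_rank(1:5, 1:5)
  expect_equal(res0$p.value, 1)
})

test_that("Bonferroni correction never lowers a p-value and caps at 1", {
  p <- c(0.001, 0.04, 0.5)
  expect_true(all(bonferroni(p, 45) >= p))
  expect_equal(bonferroni(0.5, 45), 1)
})

test_that("feature-set comparison uses the paired repetition medians", {
  fake_cv <- function(medians, feats) {
    structure(list(rep_medians = medians, mean_auc = mean(medians),
                   scheme = cv_scheme("node_4fold", length(medians)),
                   target = "soz", features = feats),
              class = "cv_result")
  }
  a <- fake_cv(seq(0.7, 0.88, length.out = 10), "All AEC")
  b <- fake_cv(seq(0.7, 0.88, length.out = 10) - 0.1, "All PLV")
  cmp <- compare_feature_sets(a, b, family_size = 3)
  expect_equal(cmp$p_raw, 2 / 2^10, tolerance = 1e-12)
  expect_equal(cmp$p_corrected, 3 * 2 / 2^10, tolerance = 1e-12)
  same <- compare_feature_sets(a, a)
  expect_equal(same$p_raw, 1)
  expect_error(compare_feature_sets(a, fake_cv(rep(0.5, 5), "x")),
               "repetition counts")
})

test_that("null-effect group comparisons stay near the nominal error rate", {
  tab <- random_feature_table(n_patients = 10, channels = 30, seed = 52)
  res <- group_feature_comparison(tab)
  expect_lte(sum(res$significant), 3)
  expect_true(all(res$p_corrected >= res$p_raw - 1e-12))
  # identical paired samples: p = 1
  tab2 <- tab
  for (p in unique(tab2$patient_id)) {
    rows <- tab2$patient_id == p
    tab2[rows, 5:49] <- matrix(rep(as.numeric(tab2[which(rows)[1], 5:49]),
                                   sum(rows)), sum(rows), byrow = TRUE)
  }
  res2 <- group_feature_comparison(tab2)
  expect_true(all(res2$p_raw == 1))
})

test_that("power-curve fit recovers known parameters and is monotone", {
  set.seed(53)
  k <- sample(1:45, 150, replace = TRUE)
  auc_true <- 0.9 - 0.3 * k^(-0.7)
  fit <- fit_power_curve(k, auc_true + rnorm(150, sd = 0.01))
  cf <- fit$coefficients
  expect_lt(abs(cf[["a"]] - 0.9) / 0.9, 0.1)
  expect_lt(abs(cf[["b"]] - 0.3) / 0.3, 0.1)
  expect_lt(abs(cf[["c"]] - 0.7) / 0.7, 0.1)
  # noiseless self-consistency
  fit0 <- fit_power_curve(k, auc_true)
  expect_lt(max(abs(fit0$residuals)), 1e-8)
  expect_gte(predict(fit0, 45), predict(fit0, 4))
})

test_that("optimal operating point matches the analytic intersections", {
  # chance diagonal
  r_diag <- roc_auc(rep(0.5, 10), c(rep(1, 5), rep(0, 5)))
  oop <- optimal_operating_point(r_diag)
  expect_equal(c(oop$fpr, oop$tpr), c(0.5, 0.5))
  # perfect classifier passes through (0, 1)
  r_perf <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  oop2 <- optimal_operating_point(r_perf)
  expect_equal(c(oop2$fpr, oop2$tpr), c(0, 1))
  # three-vertex curve (0,0)-(0.2,0.9)-(1,1): intersection at (2/11, 9/11)
  roc3 <- structure(list(fpr = c(0, 0.2, 1), tpr = c(0, 0.9, 1),
                         thresholds = c(Inf, 0.8, 0.1),
                         auc = NA, n_pos = 10, n_neg = 10),
                    class = "roc_curve")
  oop3 <- optimal_operating_point(roc3)
  expect_equal(oop3$fpr, 2 / 11, tolerance = 1e-12)
  expect_equal(oop3$tpr, 9 / 11, tolerance = 1e-12)
})

test_that("RZ enrichment z is standard normal under the uniform null", {
  n <- 400
  ann <- channel_annotation(soz = seq_len(n) <= 60,
                            rz = seq_len(n) <= 120)
  zs <- vapply(1:60, function(i) {
    set.seed(5400 + i)
    scores <- rnorm(n) + 2 * ann$soz   # informative but FP placement uniform
    rz_enrichment_test(scores, ann, n_perm = 500, seed = i)$z
  }, numeric(1))
  zs <- zs[!is.na(zs)]
  expect_lt(abs(mean(zs)), 2.5 / sqrt(length(zs)))
  expect_lt(abs(sd(zs) - 1), 0.25)
})

test_that("forced RZ false positives give a large z and the binomial scale", {
  n <- 200
  ann <- channel_annotation(soz = seq_len(n) <= 30,
                            rz = seq_len(n) <= 64)  # RZ\SOZ = 34 of 170 = 20%
  # imperfect SOZ classifier (18/30 hits) whose operating point admits
  # exactly the 20 planted false positives, all inside RZ\SOZ
  scores <- rep(-10, n)
  scores[1:18] <- 10
  scores[which(ann$rz & !ann$soz)[1:20]] <- 5
  res <- rz_enrichment_test(scores, ann, n_perm = 2000, seed = 9)
  expect_equal(res$n_fp, 20)
  expect_equal(res$observed_pct, 100)
  expect_gt(res$z, 3)
  # null mean matches the hypergeometric expectation 100*|RZ\SOZ|/|non-SOZ|
  expect_equal(res$null_mean, 100 * 34 / 170, tolerance = 0.05)
  # binomial SD scale for 20 draws at p = 0.2 (without-replacement
  # correction makes the empirical SD slightly smaller)
  expect_equal(res$null_sd, 100 * sqrt(0.2 * 0.8 / 20), tolerance = 0.1)
})

test_that("zero false positives are reported as an undefined statistic", {
  ann <- channel_annotation(soz = c(TRUE, TRUE, FALSE, FALSE),
                            rz = c(TRUE, TRUE, TRUE, FALSE))
  res <- rz_enrichment_test(c(5, 4, -2, -3), ann, n_perm = 100, seed = 1)
  expect_equal(res$n_fp, 0)
  expect_true(is.na(res$z))
})

test_that("connectivity stability attains r-squared 1 when all epochs are used", {
  g <- generate_recording(list(n_channels = 6, n_soz = 2, n_rz = 3,
                               duration_s = 60, artifact_epoch_fraction = 0),
                          seed = 61)
  st <- fc_stability(g$recording, k = 5, n_total = 5,
                     bands = fc_bands()[c(2, 5), ], seed = 1)
  expect_equal(st$aec$mean_r2, 1, tolerance = 1e-10)
  expect_error(fc_stability(g$recording, k = 1), "at least 2")
})

test_that("epoch-count analysis is deterministic with SE = SD/sqrt(reps)", {
  coh <- strong_cohort()[1:2]
  class(coh) <- "ieeg_cohort"
  res1 <- epoch_count_analysis(coh, counts = c(4, 8), n_selections = 2,
                               n_repetitions = 2, budget = 4,
                               measures = "aec", seed = 5)
  res2 <- epoch_count_analysis(coh, counts = c(4, 8), n_selections = 2,
                               n_repetitions = 2, budget = 4,
                               measures = "aec", seed = 5)
  expect_equal(res1$mean_auc, res2$mean_auc, tolerance = 1e-12)
  per_rep <- attr(res1, "per_repetition")
  expect_equal(res1$se, apply(per_rep, 2, sd) / sqrt(2), ignore_attr = TRUE)
  expect_error(epoch_count_analysis(coh, counts = 500), "clean epochs")
})

test_that("random subset curve draws, evaluates and fits end to end", {
  tab <- separable_feature_table(n_patients = 4, channels = 12, seed = 71,
                                 effect = 3)
  fit <- random_subset_curve(tab, cv_scheme("node_4fold", 1, seed = 2),
                             n_draws = 10, budget = 3, seed = 3)
  expect_s3_class(fit, "power_fit")
  expect_equal(nrow(fit$points), 10)
  expect_true(all(fit$points$k >= 1 & fit$points$k <= 45))
  expect_true(all(fit$points$auc >= 0 & fit$points$auc <= 1))
  expect_error(random_subset_curve(tab, n_draws = 5), "at least 10")
})

test_that("connectivity stability improves with the epoch budget", {
  r2_at <- function(k, s) {
    g <- generate_recording(list(n_channels = 6, n_soz = 2, n_rz = 3,
                                 duration_s = 84, artifact_epoch_fraction = 0),
                            seed = 700 + s)
    fc_stability(g$recording, k = k, n_total = 7,
                 bands = fc_bands()[c(2, 6), ], seed = s)$aec$mean_r2
  }
  ks <- c(2, 4, 6)
  means <- vapply(ks, function(k)
    mean(vapply(1:4, function(s) r2_at(k, s), numeric(1))), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("more connectivity epochs do not hurt classification on a strong cohort", {
  res <- epoch_count_analysis(strong_cohort(), counts = c(3, 15),
                              n_selections = 2, n_repetitions = 2,
                              budget = 5, measures = "aec", seed = 11)
  expect_gte(res$mean_auc[res$count == 15], res$mean_auc[res$count == 3] - 0.05)
})
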