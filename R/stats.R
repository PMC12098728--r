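## Paired Wilcoxon signed-rank test. Zero differences are dropped (the
## standard signed-rank convention). For n <= 14 the exact two-sided
## sign-flip distribution is computed (with midranks, so tied absolute
## differences are handled exactly); larger samples use the normal
## approximation of stats::wilcox.test.
paired_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  nz <- d[d != 0]
  n <- length(nz)
  if (!n) {
    return(list(statistic = NA_real_, p.value = 1, n_eff = 0L))
  }
  r <- rank(abs(nz))
  v_obs <- sum(r[nz > 0])
  if (n <= 14) {
    ## exact null by dynamic programming over 2 x midranks (integers)
    r2 <- round(2 * r)
    dist <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), dist)
      dist <- c(dist, numeric(ri)) + shifted
    }
    dist <- dist / sum(dist)
    v2 <- round(2 * v_obs)
    p_lo <- sum(dist[seq_len(v2 + 1)])
    p_hi <- sum(dist[(v2 + 1):length(dist)])
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, exact = FALSE))
    p <- wt$p.value
  }
  list(statistic = v_obs, p.value = p, n_eff = n)
}

#' Bonferroni-corrected p-value
#' @param p Raw p-value(s).
#' @param family_size Number of tests in the correction family.
#' @return `min(1, p * family_size)`.
#' @export
bonferroni <- function(p, family_size) pmin(1, p * family_size)

#' Group-level SOZ vs non-SOZ feature comparison
#'
#' Per feature and patient, the mean over SOZ channels and the mean over
#' non-SOZ channels are compared across patients with a paired Wilcoxon
#' signed-rank test, Bonferroni-corrected over the number of features
#' (45 under the default schema). Patients lacking either class are
#' excluded with a warning.
#'
#' @param table A `feature_table`.
#' @param alpha Significance level applied to the corrected p-values.
#' @return Data frame of class `group_comparison`: one row per feature
#'   with mean paired difference, test statistic, raw and corrected p, and
#'   a significance flag.
#' @export
group_feature_comparison <- function(table, alpha = 0.05) {
  cols <- feature_columns(table)
  pats <- unique(table$patient_id)
  usable <- vapply(pats, function(p) {
    s <- table$soz[table$patient_id == p]
    any(s) && !all(s)
  }, logical(1))
  if (any(!usable)) {
    warning(sum(!usable), " patient(s) lacking SOZ or non-SOZ channels excluded")
  }
  pats <- pats[usable]
  if (length(pats) < 6) stop("need at least 6 usable patients")
  soz_means <- nonsoz_means <- matrix(
    NA_real_, length(pats), length(cols), dimnames = list(pats, cols))
  for (i in seq_along(pats)) {
    rows <- table$patient_id == pats[i]
    soz_means[i, ] <- colMeans(table[rows & table$soz, cols, drop = FALSE])
    nonsoz_means[i, ] <- colMeans(table[rows & !table$soz, cols, drop = FALSE])
  }
  res <- lapply(seq_along(cols), function(j)
    paired_signed_rank(soz_means[, j], nonsoz_means[, j]))
  p_raw <- vapply(res, `[[`, numeric(1), "p.value")
  out <- data.frame(
    feature = cols,
    mean_diff = colMeans(soz_means - nonsoz_means),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p_raw = p_raw,
    p_corrected = bonferroni(p_raw, length(cols)))
  out$significant <- out$p_corrected < alpha
  structure(out, n_patients = length(pats), family_size = length(cols),
            class = c("group_comparison", "data.frame"))
}

#' Compare two feature subsets by paired CV performance
#'
#' Paired Wilcoxon signed-rank test on the per-repetition median AUCs of
#' two cross-validation results (same scheme, target and repetition
#' count), Bonferroni-corrected by the number of comparisons in the
#' analysis family.
#'
#' @param result_a,result_b `cv_result` objects with equal repetition
#'   counts.
#' @param family_size Bonferroni family size (default 1).
#' @return List of class `paired_comparison`.
#' @export
compare_feature_sets <- function(result_a, result_b, family_size = 1) {
  stopifnot(inherits(result_a, "cv_result"), inherits(result_b, "cv_result"))
  if (length(result_a$rep_medians) != length(result_b$rep_medians)) {
    stop("repetition counts differ between results")
  }
  if (result_a$scheme$kind != result_b$scheme$kind ||
      result_a$target != result_b$target) {
    stop("results come from different CV schemes or targets")
  }
  ts <- paired_signed_rank(result_a$rep_medians, result_b$rep_medians)
  structure(list(set_a = result_a$features, set_b = result_b$features,
                 mean_a = result_a$mean_auc, mean_b = result_b$mean_auc,
                 medians_a = result_a$rep_medians,
                 medians_b = result_b$rep_medians,
                 statistic = ts$statistic, p_raw = ts$p.value,
                 p_corrected = bonferroni(ts$p.value, family_size),
                 family_size = family_size),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("'%s' (mean AUC %.4f) vs '%s' (mean AUC %.4f)\n",
              x$set_a, x$mean_a, x$set_b, x$mean_b))
  cat(sprintf("  Wilcoxon signed-rank V = %s, raw p = %.4g, corrected p = %.4g (family %d)\n",
              format(x$statistic), x$p_raw, x$p_corrected, x$family_size))
  invisible(x)
}

#' Saturating power fit of AUC against feature count
#'
#' Fits `AUC(k) = a - b * k^(-c)` by nonlinear least squares
#' ([minpack.lm::nlsLM()]); with b, c > 0 the curve is monotone
#' non-decreasing and saturates at `a`, matching the observed plateau of
#' classifier performance with growing feature counts. On non-convergence
#' a log-linear fallback `AUC ~ log(k)` is reported with a warning.
#'
#' @param k Feature counts.
#' @param auc Observed AUC values.
#' @return Object of class `power_fit` with `coefficients`, `residuals`,
#'   `points` and `method` (`"power"` or `"loglinear"`).
#' @export
fit_power_curve <- function(k, auc) {
  stopifnot(length(k) == length(auc), length(k) >= 3)
  df <- data.frame(k = k, auc = auc)
  fit <- try(minpack.lm::nlsLM(
    auc ~ a - b * k^(-c), data = df,
    start = list(a = max(auc), b = max(max(auc) - min(auc), 0.1), c = 0.7),
    lower = c(-Inf, 1e-8, 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (!inherits(fit, "try-error")) {
    cf <- stats::coef(fit)
    structure(list(coefficients = cf, points = df,
                   residuals = stats::resid(fit), method = "power"),
              class = "power_fit")
  } else {
    warning("power fit did not converge; falling back to log-linear fit")
    lf <- stats::lm(auc ~ log(k), data = df)
    structure(list(coefficients = stats::coef(lf), points = df,
                   residuals = stats::resid(lf), method = "loglinear"),
              class = "power_fit")
  }
}

#' @export
predict.power_fit <- function(object, k, ...) {
  cf <- object$coefficients
  if (object$method == "power") cf[["a"]] - cf[["b"]] * k^(-cf[["c"]])
  else cf[[1]] + cf[[2]] * log(k)
}

#' @export
print.power_fit <- function(x, ...) {
  if (x$method == "power") {
    cat(sprintf("power fit AUC(k) = %.4f - %.4f * k^(-%.4f) on %d points\n",
                x$coefficients[["a"]], x$coefficients[["b"]],
                x$coefficients[["c"]], nrow(x$points)))
  } else {
    cat("log-linear fallback fit on", nrow(x$points), "points\n")
  }
  invisible(x)
}

#' @export
plot.power_fit <- function(x, ...) {
  plot(x$points$k, x$points$auc, xlab = "feature count", ylab = "AUC", ...)
  ks <- seq(min(x$points$k), max(x$points$k), length.out = 100)
  graphics::lines(ks, predict(x, ks))
  invisible(x)
}

#' AUC as a function of random feature-subset size
#'
#' Draws random feature subsets (size uniform on 1..p, then columns
#' uniform without replacement), evaluates each by cross-validation, and
#' fits the saturating power curve to the (size, AUC) points.
#'
#' @param table A `feature_table`.
#' @param scheme A [cv_scheme()] (one repetition per draw is typical).
#' @param model Model kind.
#' @param n_draws Number of random subsets (150 in the full-scale design).
#' @param budget Hyperparameter budget per fold.
#' @param target `"soz"` or `"rz"`.
#' @param seed RNG seed for the subset draws.
#' @return A `power_fit` whose `points` hold the per-draw (k, AUC) pairs.
#' @export
random_subset_curve <- function(table, scheme = cv_scheme("node_4fold", 1),
                                model = "gsvm", n_draws = 150, budget = 10,
                                target = "soz", seed = 1L) {
  if (n_draws < 10) stop("n_draws must be at least 10")
  cols <- feature_columns(table)
  set.seed(as.integer(seed))
  sizes <- sample.int(length(cols), n_draws, replace = TRUE)
  subsets <- lapply(sizes, function(k) sample(cols, k))
  draw_seeds <- sample.int(.Machine$integer.max, n_draws)
  aucs <- vapply(seq_len(n_draws), function(i) {
    run_cv(table, scheme, target = target, model = model,
           features = subsets[[i]], budget = budget,
           seed = draw_seeds[i])$mean_auc
  }, numeric(1))
  fit_power_curve(sizes, aucs)
}

#' Optimal operating point of a ROC curve
#'
#' The intersection of the piecewise-linear ROC curve with the
#' anti-diagonal line from (0,1) to (1,0), i.e. the point where
#' TPR = 1 - FPR, found by linear interpolation between ROC vertices.
#' If a whole segment lies on the line its midpoint is returned. The
#' decision threshold is interpolated between the vertex thresholds
#' (taking the finite endpoint when one vertex threshold is infinite).
#'
#' @param roc A [roc_auc()] result.
#' @return List with `fpr`, `tpr`, `threshold`.
#' @export
optimal_operating_point <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  g <- roc$tpr + roc$fpr - 1          # non-decreasing along the curve
  j <- which(g >= 0)[1]
  interp_thr <- function(t1, t2, w) {
    if (!is.finite(t1)) return(t2)
    if (!is.finite(t2)) return(t1)
    t1 + w * (t2 - t1)
  }
  if (g[j] == 0) {
    if (j < length(g) && g[j + 1] == 0) {      # segment on the line
      return(list(fpr = (roc$fpr[j] + roc$fpr[j + 1]) / 2,
                  tpr = (roc$tpr[j] + roc$tpr[j + 1]) / 2,
                  threshold = interp_thr(roc$thresholds[j],
                                         roc$thresholds[j + 1], 0.5)))
    }
    return(list(fpr = roc$fpr[j], tpr = roc$tpr[j],
                threshold = roc$thresholds[j]))
  }
  w <- -g[j - 1] / (g[j] - g[j - 1])
  list(fpr = roc$fpr[j - 1] + w * (roc$fpr[j] - roc$fpr[j - 1]),
       tpr = roc$tpr[j - 1] + w * (roc$tpr[j] - roc$tpr[j - 1]),
       threshold = interp_thr(roc$thresholds[j - 1], roc$thresholds[j], w))
}

#' Permutation test for false-positive enrichment in the resection zone
#'
#' Thresholds SOZ-classifier scores at the optimal operating point; false
#' positives are non-SOZ channels called positive. The observed statistic
#' is the percentage of false positives lying inside the resection zone
#' but outside the SOZ. The null distribution draws the same number of
#' channels uniformly from all non-SOZ channels `n_perm` times; the
#' z statistic compares the observation to the null mean and SD, with a
#' two-sided normal p-value.
#'
#' @param scores SOZ-classifier scores, one per channel.
#' @param annotation A [channel_annotation()] (or data frame with logical
#'   `soz` and `rz`) aligned with `scores`.
#' @param n_perm Number of null draws (default 5000).
#' @param seed RNG seed.
#' @return Object of class `permutation_result` with the observed
#'   percentage, null mean/SD, `z`, `p`, and the false-positive count. If
#'   there are no false positives the statistic is reported as undefined
#'   (NA) with `n_fp = 0`.
#' @export
rz_enrichment_test <- function(scores, annotation, n_perm = 5000, seed = 1L) {
  soz <- as.logical(annotation$soz); rzf <- as.logical(annotation$rz)
  stopifnot(length(scores) == length(soz))
  roc <- roc_auc(scores, soz)
  oop <- optimal_operating_point(roc)
  fp <- which(!soz & scores >= oop$threshold)
  non_soz <- which(!soz)
  rz_only <- rzf & !soz
  if (!length(fp)) {
    return(structure(list(observed_pct = NA_real_, null_mean = NA_real_,
                          null_sd = NA_real_, z = NA_real_, p = NA_real_,
                          n_fp = 0L, n_perm = n_perm, oop = oop),
                     class = "permutation_result"))
  }
  observed <- 100 * mean(rz_only[fp])
  set.seed(as.integer(seed))
  null_pct <- vapply(seq_len(n_perm), function(i) {
    100 * mean(rz_only[sample(non_soz, length(fp))])
  }, numeric(1))
  z <- (observed - mean(null_pct)) / stats::sd(null_pct)
  structure(list(observed_pct = observed, null_mean = mean(null_pct),
                 null_sd = stats::sd(null_pct), z = z,
                 p = 2 * stats::pnorm(-abs(z)), n_fp = length(fp),
                 n_perm = n_perm, oop = oop),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  if (x$n_fp == 0) {
    cat("RZ enrichment test: no false positives at the operating point; statistic undefined\n")
  } else {
    cat(sprintf("RZ enrichment: %.1f%% of %d false positives inside RZ (null %.1f%% +/- %.1f%%), Z = %.3f, p = %.3g\n",
                x$observed_pct, x$n_fp, x$null_mean, x$null_sd, x$z, x$p))
  }
  invisible(x)
}

#' Classifier performance against the number of epochs used for FC
#'
#' Recomputes connectivity features from varying numbers of randomly
#' selected epochs and evaluates a node-level 4-fold classifier per epoch
#' count and selection, keeping the channel partition identical across
#' counts within a repetition. Per-epoch connectivity matrices are
#' computed once per patient and reused across counts and selections.
#'
#' @param cohort An `ieeg_cohort`.
#' @param counts Epoch counts to evaluate (default 6, 12, 25, 50, 100).
#' @param n_selections Random epoch selections per count (default 5).
#' @param n_repetitions Repetitions with fresh partitions and selections
#'   (default 5); mean and standard error are taken across repetitions.
#' @param model,budget,target Passed to the classifier.
#' @param measures Connectivity measures used.
#' @param seed Master seed.
#' @return Data frame of class `epoch_count_result`: `count`, `mean_auc`,
#'   `se`.
#' @export
epoch_count_analysis <- function(cohort, counts = c(6, 12, 25, 50, 100),
                                 n_selections = 5, n_repetitions = 5,
                                 model = "gsvm", budget = 10,
                                 target = "soz",
                                 measures = c("aec", "plv"), seed = 1L) {
  set.seed(as.integer(seed))
  ## per patient: fixed feature blocks + per-epoch connectivity matrices
  prep <- lapply(cohort, function(pat) {
    pp <- preprocess(pat$recording, pat$annotation)
    clean <- pp$recording
    epochs <- flag_artifact_epochs(clean, segment_epochs(clean))
    clean_idx <- which(!epochs$artifact)
    if (length(clean_idx) < max(counts)) {
      stop("patient ", clean$patient_id, " has only ", length(clean_idx),
           " clean epochs; max(counts) = ", max(counts))
    }
    attr(epochs, "selected") <- clean_idx
    stack <- connectivity_stack(clean, epochs, measures = measures,
                                keep_epochs = TRUE)
    list(psd = welch_band_psd(clean),
         spikes = summarize_events(detect_spikes(clean)),
         hfos = summarize_events(detect_hfos(clean)),
         epochwise = attr(stack, "epochwise"),
         n_clean = length(clean_idx),
         annotation = pp$annotation, patient_id = clean$patient_id,
         labels = clean$channel_labels)
  })
  features_for <- function(pat, ep_subset) {
    stack <- structure(
      lapply(pat$epochwise, function(bands)
        lapply(bands, function(arr) {
          avg <- apply(arr[, , ep_subset, drop = FALSE], c(1, 2), mean,
                       na.rm = TRUE)
          avg[!is.finite(avg)] <- NA_real_
          diag(avg) <- 1
          (avg + t(avg)) / 2
        })),
      class = "connectivity_stack", n_epochs = length(ep_subset),
      bands = fc_bands()[fc_bands()$tag %in% names(pat$epochwise[[1]]), ],
      measures = names(pat$epochwise))
    assemble_features(pat$spikes, pat$hfos, pat$psd, graph_features(stack),
                      pat$annotation, pat$patient_id, pat$labels)
  }
  res <- expand.grid(count = counts, rep = seq_len(n_repetitions))
  res$auc <- NA_real_
  per_rep <- matrix(NA_real_, n_repetitions, length(counts),
                    dimnames = list(NULL, counts))
  for (r in seq_len(n_repetitions)) {
    part_seed <- sample.int(.Machine$integer.max, 1)
    for (ci in seq_along(counts)) {
      sel_aucs <- numeric(n_selections)
      for (s in seq_len(n_selections)) {
        tabs <- lapply(prep, function(pat)
          features_for(pat, sample.int(pat$n_clean, counts[ci])))
        tab <- structure(do.call(rbind, lapply(tabs, as.data.frame)),
                         schema = attr(tabs[[1]], "schema"),
                         class = c("feature_table", "data.frame"))
        ## identical channel partition across counts: same scheme seed
        cv <- run_cv(tab, cv_scheme("node_4fold", 1, seed = part_seed),
                     target = target, model = model, budget = budget,
                     features = NULL, seed = part_seed)
        sel_aucs[s] <- cv$mean_auc
      }
      per_rep[r, ci] <- mean(sel_aucs)
    }
  }
  out <- data.frame(count = counts,
                    mean_auc = colMeans(per_rep),
                    se = apply(per_rep, 2, stats::sd) / sqrt(n_repetitions))
  structure(out, per_repetition = per_rep,
            class = c("epoch_count_result", "data.frame"))
}

#' Stability of connectivity estimates against epoch count
#'
#' Squared Pearson correlation between the upper-triangle entries of the
#' connectivity matrix averaged over `k` randomly chosen clean epochs and
#' the matrix averaged over all available epochs, per band; also reported
#' averaged over bands per measure.
#'
#' @param rec A preprocessed [ieeg_recording()].
#' @param k Number of epochs in the reduced estimate (>= 2).
#' @param n_total Maximum number of clean epochs in the reference estimate
#'   (default 150).
#' @param measures Connectivity measures.
#' @param bands Band definitions.
#' @param seed RNG seed for the epoch draw.
#' @return List per measure: `per_band` (named r-squared vector) and
#'   `mean_r2`.
#' @export
fc_stability <- function(rec, k, n_total = 150, measures = "aec",
                         bands = fc_bands(), seed = 1L) {
  if (k < 2) stop("k must be at least 2")
  epochs <- flag_artifact_epochs(rec, segment_epochs(rec))
  clean <- which(!epochs$artifact)
  if (length(clean) > n_total) clean <- clean[seq_len(n_total)]
  if (k > length(clean)) stop("k exceeds the number of clean epochs")
  attr(epochs, "selected") <- clean
  stack <- connectivity_stack(rec, epochs, bands = bands,
                              measures = measures, keep_epochs = TRUE)
  set.seed(as.integer(seed))
  sub <- sample(seq_along(clean), k)
  ut <- upper.tri(stack[[1]][[1]])
  out <- list()
  for (m in measures) {
    r2 <- vapply(names(stack[[m]]), function(tag) {
      arr <- attr(stack, "epochwise")[[m]][[tag]]
      full <- apply(arr, c(1, 2), mean, na.rm = TRUE)
      part <- apply(arr[, , sub, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
      stats::cor(full[ut], part[ut])^2
    }, numeric(1))
    out[[m]] <- list(per_band = r2, mean_r2 = mean(r2))
  }
  out
}
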