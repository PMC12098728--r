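#' ROC curve and AUC
#'
#' ROC by descending-score threshold sweep; tied scores form a single
#' vertex (a diagonal segment). AUC is the probability that a random
#' positive outscores a random negative, with ties counted one half
#' (rank-statistic form, exactly the trapezoidal area).
#'
#' @param scores Numeric classifier scores, higher = more positive.
#' @param labels Logical or 0/1 labels; both classes must be present.
#' @return Object of class `roc_curve`: list with `fpr`, `tpr`,
#'   `thresholds` (score at or above which a case is called positive;
#'   `Inf` for the (0,0) vertex), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels must not be NA")
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- c(which(diff(s) != 0), length(s))  # last index of each tied block
  structure(list(fpr = c(0, cumsum(!y)[last] / nn),
                 tpr = c(0, cumsum(y)[last] / np),
                 thresholds = c(Inf, s[last]),
                 auc = auc, n_pos = np, n_neg = nn),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Cross-validation scheme
#'
#' Three designs: `node_4fold` partitions channels freely into 4 folds;
#' `patient_4fold` partitions patients into 4 folds as equally as possible
#' (sizes differing by at most 1, giving {6,6,7,7} for 26 patients);
#' `patient_loo` holds out one patient per fold. Patient-level folds never
#' split a patient's channels across train and test.
#'
#' @param kind One of `"node_4fold"`, `"patient_4fold"`, `"patient_loo"`.
#' @param n_repetitions Number of repeated partitions (default 10 for the
#'   4-fold kinds, 1 for leave-one-out).
#' @param seed RNG seed controlling all partitions.
#' @return List of class `cv_scheme`.
#' @export
cv_scheme <- function(kind = c("node_4fold", "patient_4fold", "patient_loo"),
                      n_repetitions = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(n_repetitions)) {
    n_repetitions <- if (kind == "patient_loo") 1L else 10L
  }
  structure(list(kind = kind, n_repetitions = as.integer(n_repetitions),
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Build cross-validation fold assignments
#'
#' @param table A `feature_table`.
#' @param scheme A [cv_scheme()].
#' @return List with one element per repetition; each is a list of integer
#'   vectors of test-row indices (disjoint, covering all rows).
#' @export
build_folds <- function(table, scheme) {
  stopifnot(inherits(scheme, "cv_scheme"))
  n <- nrow(table)
  pats <- unique(table$patient_id)
  if (scheme$kind == "patient_4fold" && length(pats) < 4) {
    stop("patient-level 4-fold needs at least 4 patients")
  }
  if (scheme$kind == "patient_loo" && length(pats) < 2) {
    stop("leave-one-out needs at least 2 patients")
  }
  set.seed(scheme$seed)
  reps <- vector("list", scheme$n_repetitions)
  for (r in seq_len(scheme$n_repetitions)) {
    if (scheme$kind == "node_4fold") {
      fold_id <- rep_len(1:4, n)[sample.int(n)]
      reps[[r]] <- lapply(1:4, function(f) which(fold_id == f))
    } else if (scheme$kind == "patient_4fold") {
      pat_fold <- rep_len(1:4, length(pats))[sample.int(length(pats))]
      reps[[r]] <- lapply(1:4, function(f)
        which(table$patient_id %in% pats[pat_fold == f]))
    } else {
      reps[[r]] <- lapply(pats, function(p) which(table$patient_id == p))
    }
  }
  reps
}

## ---- sequential model-based hyperparameter search -------------------------

## Gaussian-process expected-improvement proposal over a box; used to pick
## the next hyperparameter point given past (X, loss) evaluations.
propose_next <- function(X, loss, lower, upper, n_cand = 256) {
  d <- length(lower)
  Xs <- sweep(sweep(X, 2, lower), 2, upper - lower, "/")
  mu0 <- mean(loss); sd0 <- stats::sd(loss)
  ys <- if (is.finite(sd0) && sd0 > 0) (loss - mu0) / sd0 else loss * 0
  ell <- 0.3
  sqd <- as.matrix(stats::dist(Xs))^2
  K <- exp(-sqd / (2 * ell^2)) + diag(1e-4, nrow(Xs))
  alpha <- solve(K, ys)
  cand <- matrix(stats::runif(n_cand * d), n_cand, d)
  cross <- matrix(0, nrow(Xs), n_cand)
  for (j in seq_len(n_cand)) {
    cross[, j] <- exp(-colSums((t(Xs) - cand[j, ])^2) / (2 * ell^2))
  }
  mu <- drop(crossprod(cross, alpha))
  Kinv_cross <- solve(K, cross)
  var <- pmax(1e-12, 1 - colSums(cross * Kinv_cross))
  sdv <- sqrt(var)
  best <- min(ys)
  imp <- best - mu
  zz <- imp / sdv
  ei <- imp * stats::pnorm(zz) + sdv * stats::dnorm(zz)
  pick <- cand[which.max(ei), ]
  lower + pick * (upper - lower)
}

## Stratified internal k-fold CV loss (1 - mean AUC) for one
## hyperparameter setting.
internal_cv_loss <- function(x, y, fit_fun, k = 3) {
  pos <- which(y); neg <- which(!y)
  fold_of <- integer(length(y))
  fold_of[pos] <- rep_len(1:k, length(pos))[sample.int(length(pos))]
  fold_of[neg] <- rep_len(1:k, length(neg))[sample.int(length(neg))]
  aucs <- rep(NA_real_, k)
  for (f in 1:k) {
    tr <- fold_of != f; te <- !tr
    if (!any(y[te]) || all(y[te]) || !any(y[tr]) || all(y[tr])) next
    fit <- try(fit_fun(x[tr, , drop = FALSE], y[tr]), silent = TRUE)
    if (inherits(fit, "try-error")) next
    sc <- score_fit(fit, x[te, , drop = FALSE])
    aucs[f] <- roc_auc(sc, y[te])$auc
  }
  if (all(is.na(aucs))) return(1)
  1 - mean(aucs, na.rm = TRUE)
}

svm_fit <- function(x, y, kernel, gamma, cost, cost_ratio) {
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  e1071::svm(x, yf, type = "C-classification", kernel = kernel,
             degree = 3, gamma = gamma, cost = cost, scale = FALSE,
             class.weights = c(neg = 1, pos = cost_ratio))
}

score_fit <- function(fit, x) {
  if (inherits(fit, "svm")) {
    dv <- attr(stats::predict(fit, x, decision.values = TRUE),
               "decision.values")
    sc <- drop(dv)
    if (colnames(dv)[1] == "neg/pos") sc <- -sc
    sc
  } else {
    stats::predict(fit, data.frame(x))$predictions[, "pos"]
  }
}

#' Train an SOZ/RZ channel classifier
#'
#' Hyperparameters are chosen by a sequential model-based (Bayesian-style)
#' search minimizing an internal stratified k-fold loss (1 - AUC) within
#' the given evaluation budget. Class imbalance is handled by scaling the
#' false-negative cost by the training-set negative:positive ratio
#' (multiplied by `cost_scale`).
#'
#' @param x Numeric feature matrix (rows = channels).
#' @param y Logical labels; both classes must be present.
#' @param kind `"gsvm"` (gaussian-kernel SVM), `"csvm"` (cubic-kernel SVM)
#'   or `"ensemble"` (random forest). Additional model kinds can be
#'   plugged in by registering a fit function via the `fit_fun` argument.
#' @param budget Total number of hyperparameter evaluations (300 in the
#'   full-scale design; smaller values give a faster, coarser search).
#' @param seed RNG seed for the search.
#' @param cost_scale Multiplier on the imbalance-derived false-negative
#'   cost.
#' @param fit_fun Optional custom `function(x, y, params)` returning a
#'   fitted object scorable by `predict`; makes the model set extensible.
#' @return Object of class `soz_model` with the fitted model, chosen
#'   hyperparameters and search trace. Scores from [predict.soz_model()]
#'   increase with SOZ likelihood.
#' @export
train_model <- function(x, y, kind = c("gsvm", "csvm", "ensemble"),
                        budget = 30, seed = 1L, cost_scale = 1,
                        fit_fun = NULL) {
  x <- as.matrix(x); y <- as.logical(y)
  if (!any(y) || all(y)) stop("training data must contain both classes")
  kind <- if (is.null(fit_fun)) match.arg(kind) else "custom"
  cost_ratio <- cost_scale * sum(!y) / sum(y)
  set.seed(as.integer(seed))

  if (kind %in% c("gsvm", "csvm")) {
    kernel <- if (kind == "gsvm") "radial" else "polynomial"
    lower <- c(-10, -5); upper <- c(3, 10)   # log2(gamma), log2(cost)
    make_fit <- function(p) function(xx, yy)
      svm_fit(xx, yy, kernel, 2^p[1], 2^p[2], cost_ratio)
  } else if (kind == "ensemble") {
    lower <- c(0, 0); upper <- c(1, 1)       # mtry frac, min-node frac
    make_fit <- function(p) function(xx, yy) {
      yf <- factor(ifelse(yy, "pos", "neg"), levels = c("neg", "pos"))
      ranger::ranger(x = data.frame(xx), y = yf, probability = TRUE,
                     num.trees = 300,
                     mtry = max(1L, round(p[1] * ncol(xx))),
                     min.node.size = max(1L, round(1 + p[2] * 19)),
                     class.weights = c(neg = 1, pos = cost_ratio),
                     num.threads = 1, seed = seed)
    }
  } else {
    lower <- c(0, 0); upper <- c(1, 1)
    make_fit <- function(p) function(xx, yy) fit_fun(xx, yy, p)
  }

  n_init <- max(4L, min(budget, ceiling(budget / 3)))
  X <- matrix(NA_real_, 0, 2); losses <- numeric(0)
  for (i in seq_len(budget)) {
    p <- if (i <= n_init) lower + stats::runif(2) * (upper - lower)
         else propose_next(X, losses, lower, upper)
    l <- internal_cv_loss(x, y, make_fit(p))
    X <- rbind(X, p); losses <- c(losses, l)
  }
  best <- X[which.min(losses), ]
  fit <- make_fit(best)(x, y)
  structure(list(kind = kind, fit = fit, params = best,
                 cost_ratio = cost_ratio,
                 search = data.frame(p1 = X[, 1], p2 = X[, 2], loss = losses)),
            class = "soz_model")
}

#' @export
print.soz_model <- function(x, ...) {
  cat(sprintf("%s classifier (imbalance cost ratio %.2f), search best loss %.4f over %d evaluations\n",
              x$kind, x$cost_ratio, min(x$search$loss), nrow(x$search)))
  invisible(x)
}

#' Score channels with a trained classifier
#' @param object A `soz_model`.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @return Numeric scores, higher = more SOZ-like.
#' @export
predict.soz_model <- function(object, newdata, ...) {
  score_fit(object$fit, as.matrix(newdata))
}

#' Run cross-validated classifier evaluation
#'
#' For each repetition and fold: features are scaled on the fit rows
#' (training rows by default; `scaling = "all"` reproduces the
#' whole-cohort scaling convention), a model is trained on the training
#' rows and scored on the held-out rows, and the fold ROC/AUC is computed.
#' Per repetition the median AUC across folds is recorded; the overall
#' summary is the mean of those medians. In patient-level schemes the
#' disjointness of train and test patients is asserted on every fold.
#'
#' @param table A `feature_table`.
#' @param scheme A [cv_scheme()].
#' @param target `"soz"` or `"rz"`.
#' @param model Model kind for [train_model()].
#' @param features Feature subset name or column vector
#'   (see [select_feature_subset()]); NULL uses every feature column of
#'   `table`.
#' @param budget Hyperparameter search budget per fold.
#' @param scaling `"train"` (leakage-safe, default) or `"all"`.
#' @param seed Master seed; defaults to the scheme seed.
#' @param keep_scores If TRUE, out-of-fold scores are stored (rows x
#'   repetitions), e.g. for the RZ false-positive enrichment test.
#' @return Object of class `cv_result`: fold AUCs per repetition,
#'   per-repetition medians, their mean, ROC curves of the first
#'   repetition, and metadata.
#' @export
run_cv <- function(table, scheme = cv_scheme("node_4fold"),
                   target = c("soz", "rz"), model = "gsvm",
                   features = "All", budget = 10,
                   scaling = c("train", "all"), seed = NULL,
                   keep_scores = FALSE) {
  target <- match.arg(target)
  scaling <- match.arg(scaling)
  if (is.null(seed)) seed <- scheme$seed
  if (is.null(features)) features <- feature_columns(table)
  sub <- select_feature_subset(table, features)
  y <- as.logical(sub[[target]])
  cols <- feature_columns(sub)
  if (scaling == "all") sub <- suppressWarnings(scale_across_patients(sub))
  folds <- build_folds(sub, scheme)
  set.seed(as.integer(seed))
  model_seeds <- sample.int(.Machine$integer.max,
                            scheme$n_repetitions * length(folds[[1]]) + 100L)
  fold_aucs <- vector("list", scheme$n_repetitions)
  rocs <- list()
  oof <- if (keep_scores)
    matrix(NA_real_, nrow(sub), scheme$n_repetitions) else NULL
  si <- 0L
  for (r in seq_len(scheme$n_repetitions)) {
    aucs <- numeric(0)
    for (f in seq_along(folds[[r]])) {
      si <- si + 1L
      test <- folds[[r]][[f]]
      train <- setdiff(seq_len(nrow(sub)), test)
      if (scheme$kind != "node_4fold") {
        overlap <- intersect(unique(sub$patient_id[train]),
                             unique(sub$patient_id[test]))
        if (length(overlap)) stop("patient leakage across folds: ",
                                  paste(overlap, collapse = ", "))
      }
      ## all-zero fit columns (e.g. no HFOs in a small fold) are routine
      ## inside CV; the standalone scaling function still warns
      scaled <- if (scaling == "train")
        suppressWarnings(scale_across_patients(sub, fit_rows = train)) else sub
      xm <- as.matrix(scaled[, cols])
      if (!any(y[train]) || all(y[train])) {
        stop("single-class training data in fold ", f)
      }
      fit <- train_model(xm[train, , drop = FALSE], y[train], kind = model,
                         budget = budget, seed = model_seeds[si])
      sc <- predict(fit, xm[test, , drop = FALSE])
      if (keep_scores) oof[test, r] <- sc
      if (any(y[test]) && !all(y[test])) {
        rc <- roc_auc(sc, y[test])
        aucs <- c(aucs, rc$auc)
        if (r == 1) rocs[[length(rocs) + 1L]] <- rc
      }
    }
    fold_aucs[[r]] <- aucs
  }
  rep_medians <- vapply(fold_aucs, stats::median, numeric(1))
  structure(list(fold_aucs = fold_aucs, rep_medians = rep_medians,
                 mean_auc = mean(rep_medians), rocs = rocs,
                 oof_scores = oof, scheme = scheme, target = target,
                 model = model,
                 features = if (is.character(features) &&
                                length(features) == 1) features else "custom",
                 n_rows = nrow(sub), seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV result: %s, target %s, model %s, features '%s'\n",
              x$scheme$kind, toupper(x$target), x$model, x$features))
  cat(sprintf("  mean AUC over %d repetition(s): %.4f (rep medians %s)\n",
              length(x$rep_medians), x$mean_auc,
              paste(sprintf("%.3f", x$rep_medians), collapse = ", ")))
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) {
  print(object)
  all_aucs <- unlist(object$fold_aucs)
  cat(sprintf("  fold AUCs: n = %d, range %.3f-%.3f, sd %.3f\n",
              length(all_aucs), min(all_aucs), max(all_aucs),
              stats::sd(all_aucs)))
  invisible(object)
}

#' Persist a CV result as JSON
#' @param result A `cv_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(result, path) {
  jsonlite::write_json(
    list(scheme = result$scheme$kind, target = result$target,
         model = result$model, features = result$features,
         fold_aucs = result$fold_aucs, rep_medians = result$rep_medians,
         mean_auc = result$mean_auc,
         rocs = lapply(result$rocs, function(r)
           list(fpr = r$fpr, tpr = r$tpr, auc = r$auc))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
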