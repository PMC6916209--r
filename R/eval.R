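#' Rank-based AUC
#'
#' Area under the ROC curve computed from rank statistics of the scores
#' (equivalent to the Wilcoxon/Mann-Whitney statistic; ties share average
#' ranks).
#'
#' @param scores numeric predicted scores.
#' @param labels binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' NearMiss-1 undersampling
#'
#' Keeps the minority class intact and retains, from the majority class,
#' the samples with the smallest mean Euclidean distance to their `k`
#' nearest minority neighbours, until the classes balance. Already-balanced
#' input is returned unchanged.
#'
#' @param x feature matrix.
#' @param y binary labels.
#' @param k number of nearest minority neighbours (default 3).
#' @return integer vector of retained row indices.
#' @export
nearmiss_undersample <- function(x, y, k = 3) {
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2) stop("both classes must be present")
  x <- as.matrix(x)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  min_lab <- if (n1 <= n0) 1L else 0L
  min_idx <- which(y == min_lab)
  maj_idx <- which(y != min_lab)
  if (length(maj_idx) <= length(min_idx)) return(sort(c(min_idx, maj_idx)))
  xm <- x[min_idx, , drop = FALSE]
  xM <- x[maj_idx, , drop = FALSE]
  d2 <- outer(rowSums(xM^2), rep(1, nrow(xm))) +
    outer(rep(1, nrow(xM)), rowSums(xm^2)) - 2 * xM %*% t(xm)
  d2[d2 < 0] <- 0
  kk <- min(k, nrow(xm))
  mean_near <- apply(sqrt(d2), 1, function(row) mean(sort(row)[seq_len(kk)]))
  keep_maj <- maj_idx[order(mean_near)[seq_len(length(min_idx))]]
  sort(c(min_idx, keep_maj))
}

#' Accuracy and F1 at a decision threshold
#'
#' Predictions are `score >= threshold`; F1 is computed on the positive
#' class (death / comorbidity present).
#'
#' @param scores predicted scores.
#' @param labels binary labels.
#' @param threshold decision threshold.
#' @return list with `accuracy` and `f1`.
#' @export
threshold_metrics <- function(scores, labels, threshold) {
  y <- as.integer(as.logical(labels))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  list(accuracy = mean(pred == y),
       f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
}

# Random undersampling to balance (comparison strategy).
random_undersample <- function(y, seed = 1L) {
  y <- as.integer(as.logical(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  min_lab <- if (n1 <= n0) 1L else 0L
  min_idx <- which(y == min_lab)
  maj_idx <- which(y != min_lab)
  with_seed(seed, sort(c(min_idx, sample(maj_idx, length(min_idx)))))
}

#' Evaluation configuration
#'
#' @param classifier `"svm"` (default), `"rf"`, `"gbdt"`, `"knn"`, `"lr"`
#'   or `"nb"`.
#' @param threshold decision threshold on the predicted score for
#'   accuracy/F1 (0.8 in the reference configuration).
#' @param undersampler `"nearmiss"` (default), `"random"` or `"none"`,
#'   applied to TRAINING folds only when the positive prevalence is below
#'   `undersample_below`.
#' @param undersample_below prevalence trigger (default 0.30).
#' @param folds stratified cross-validation folds (default 5), grouped at
#'   the patient level so all prefix samples of one patient share a fold.
#' @param seed RNG seed for folds, classifiers and undersampling.
#' @return list of class `eval_config`.
#' @export
eval_config <- function(classifier = "svm", threshold = 0.8,
                        undersampler = "nearmiss", undersample_below = 0.30,
                        folds = 5, seed = 1L) {
  stopifnot(threshold > 0, threshold < 1,
            classifier %in% c("svm", "rf", "gbdt", "knn", "lr", "nb"),
            undersampler %in% c("nearmiss", "random", "none"))
  structure(list(classifier = classifier, threshold = threshold,
                 undersampler = undersampler,
                 undersample_below = undersample_below,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "eval_config")
}

# fit/predict wrappers with a common score-for-positive interface.
classifier_backend <- function(name) {
  need <- function(pkg) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("classifier '", name, "' needs the ", pkg, " package")
    }
  }
  switch(name,
    svm = list(
      fit = function(x, y) suppressWarnings(
        e1071::svm(x, factor(y, levels = c(0, 1)),
                   probability = TRUE, kernel = "radial")),
      predict = function(m, x) {
        p <- stats::predict(m, x, probability = TRUE)
        attr(p, "probabilities")[, "1"]
      }),
    lr = list(
      fit = function(x, y) {
        df <- data.frame(y = y, x)
        suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
      },
      predict = function(m, x) {
        suppressWarnings(stats::predict(m, data.frame(x), type = "response"))
      }),
    nb = list(
      fit = function(x, y) e1071::naiveBayes(x, factor(y, levels = c(0, 1))),
      predict = function(m, x) stats::predict(m, x, type = "raw")[, "1"]),
    rf = list(
      fit = function(x, y) { need("randomForest")
        randomForest::randomForest(x, factor(y, levels = c(0, 1)), ntree = 200) },
      predict = function(m, x) stats::predict(m, x, type = "prob")[, "1"]),
    gbdt = list(
      fit = function(x, y) { need("xgboost")
        xgboost::xgboost(data = x, label = y, nrounds = 50, verbose = 0,
                         objective = "binary:logistic", max_depth = 4,
                         nthread = 1) },
      predict = function(m, x) stats::predict(m, x)),
    knn = list(
      fit = function(x, y) { need("class"); list(x = x, y = y) },
      predict = function(m, x) {
        p <- class::knn(m$x, x, factor(m$y, levels = c(0, 1)), k = 5,
                        prob = TRUE)
        pr <- attr(p, "prob")
        ifelse(p == "1", pr, 1 - pr)
      }),
    stop("unknown classifier: ", name))
}

# Patient-level stratified fold assignment: patients shuffled within label
# stratum, dealt round-robin; every prefix sample follows its patient.
make_patient_folds <- function(patient_ids, labels, folds, seed) {
  u <- unique(patient_ids)
  plab <- labels[match(u, patient_ids)]
  with_seed(seed, {
    fold_of <- integer(length(u))
    for (lv in unique(plab)) {
      idx <- which(plab == lv)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold_of[match(patient_ids, u)]
  })
}

# One binary cross-validated task; returns per-fold and mean metrics.
cv_binary_task <- function(features, y, patient_ids, config,
                           train_fraction = 1) {
  y <- as.integer(as.logical(y))
  folds <- make_patient_folds(patient_ids, y, config$folds, config$seed)
  backend <- classifier_backend(config$classifier)
  rows <- list()
  for (f in seq_len(config$folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) {
      warning("fold ", f, " degenerate (single class); skipped")
      next
    }
    if (train_fraction < 1) {
      with_seed(config$seed + f, {
        tr <- sort(sample(tr, max(2, round(length(tr) * train_fraction))))
      })
      if (length(unique(y[tr])) < 2) next
    }
    prev <- mean(y[tr])
    pos_prev <- min(prev, 1 - prev)
    if (config$undersampler != "none" && pos_prev < config$undersample_below) {
      keep <- switch(config$undersampler,
                     nearmiss = nearmiss_undersample(features[tr, , drop = FALSE],
                                                     y[tr]),
                     random = random_undersample(y[tr], seed = config$seed + f))
      tr <- tr[keep]
    }
    model <- with_seed(config$seed + 100 + f,
                       backend$fit(features[tr, , drop = FALSE], y[tr]))
    sc <- with_seed(config$seed + 200 + f,
                    backend$predict(model, features[te, , drop = FALSE]))
    tm <- threshold_metrics(sc, y[te], config$threshold)
    rows[[length(rows) + 1]] <- data.frame(
      fold = f, auc = auc_rank(sc, y[te]), accuracy = tm$accuracy,
      f1 = tm$f1, n_train = length(tr), n_test = length(te))
  }
  if (!length(rows)) stop("all folds degenerate")
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold,
       auc = mean(per_fold$auc), accuracy = mean(per_fold$accuracy),
       f1 = mean(per_fold$f1))
}

#' Cross-validated in-hospital mortality prediction
#'
#' Stratified patient-level k-fold evaluation of a binary classifier on the
#' given representation. AUC comes from rank statistics of the predicted
#' scores; accuracy and F1 (positive = death) are computed at the configured
#' decision threshold (default 0.8).
#'
#' @param features numeric matrix, one row per sample.
#' @param labels 0/1 death flags per sample.
#' @param patient_ids patient id per sample (keeps all prefix samples of a
#'   patient in one fold).
#' @param config an [eval_config()].
#' @param train_fraction fraction of each training fold used for fitting
#'   (for training-size sweeps).
#' @return list with mean `auc`, `accuracy`, `f1` and the `per_fold` table.
#' @export
evaluate_mortality <- function(features, labels, patient_ids,
                               config = eval_config(), train_fraction = 1) {
  cv_binary_task(as.matrix(features), labels, patient_ids, config,
                 train_fraction)
}

#' Cross-validated comorbidity prediction over many tasks
#'
#' One independent binary task per comorbidity label; tasks whose positive
#' prevalence falls below the configured trigger are NearMiss-undersampled
#' in the training folds.
#'
#' @param features numeric matrix, one row per sample.
#' @param label_table data.frame with one logical column per comorbidity
#'   (e.g. `deep_features(...)$labels`).
#' @param tasks character vector of comorbidity column names.
#' @param patient_ids patient id per sample.
#' @param config an [eval_config()].
#' @return data.frame with one row per task: auc, accuracy, f1, prevalence,
#'   undersampled.
#' @export
evaluate_comorbidity <- function(features, label_table, tasks, patient_ids,
                                 config = eval_config()) {
  rows <- list()
  for (task in tasks) {
    if (is.null(label_table[[task]])) {
      warning("task '", task, "' absent from labels; skipped")
      next
    }
    y <- as.integer(label_table[[task]])
    if (length(unique(y)) < 2) {
      warning("task '", task, "' has a single class; skipped")
      next
    }
    res <- cv_binary_task(as.matrix(features), y, patient_ids, config)
    rows[[task]] <- data.frame(
      task = task, auc = res$auc, accuracy = res$accuracy, f1 = res$f1,
      prevalence = mean(y),
      undersampled = mean(y) < config$undersample_below &&
        config$undersampler != "none")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Out-of-fold cross-validated scores for one binary task
#'
#' Same folds, classifier and undersampling behaviour as
#' [evaluate_mortality()], but returns the predicted score each sample
#' received while held out. Used to assemble the patients x comorbidities
#' score matrix for top-k prediction.
#'
#' @inheritParams evaluate_mortality
#' @return numeric vector of scores aligned with the feature rows (`NA` for
#'   samples in degenerate folds).
#' @export
crossval_scores <- function(features, labels, patient_ids,
                            config = eval_config()) {
  features <- as.matrix(features)
  y <- as.integer(as.logical(labels))
  folds <- make_patient_folds(patient_ids, y, config$folds, config$seed)
  backend <- classifier_backend(config$classifier)
  out <- rep(NA_real_, length(y))
  for (f in seq_len(config$folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    if (length(unique(y[tr])) < 2) next
    prev <- mean(y[tr])
    pos_prev <- min(prev, 1 - prev)
    if (config$undersampler != "none" && pos_prev < config$undersample_below) {
      keep <- switch(config$undersampler,
                     nearmiss = nearmiss_undersample(features[tr, , drop = FALSE],
                                                     y[tr]),
                     random = random_undersample(y[tr], seed = config$seed + f))
      tr <- tr[keep]
    }
    model <- with_seed(config$seed + 100 + f,
                       backend$fit(features[tr, , drop = FALSE], y[tr]))
    out[te] <- with_seed(config$seed + 200 + f,
                         backend$predict(model, features[te, , drop = FALSE]))
  }
  out
}

#' Average ranks of representation methods across tasks
#'
#' Ranks methods within each task by AUC (1 = best); ties receive the
#' average of the ranks they span (two methods tied for 4th/5th both get
#' 4.5). Returns the per-method mean rank across tasks.
#'
#' @param auc_matrix tasks x methods numeric matrix of AUCs.
#' @return named numeric vector of average ranks.
#' @export
average_ranks <- function(auc_matrix) {
  auc_matrix <- as.matrix(auc_matrix)
  rk <- t(apply(-auc_matrix, 1, rank, ties.method = "average"))
  colMeans(rk)
}

#' Top-k comorbidity prediction accuracy and its upper bound
#'
#' Per patient, the k highest-scoring comorbidities are predicted; accuracy
#' is the fraction of those k that are truly present, averaged over
#' patients. The theoretical upper bound replaces the prediction with the
#' truth: `min(|true set|, k) / k` averaged over patients — below 1 whenever
#' some patient has fewer than k comorbidities. Patients with no true
#' comorbidity are excluded from both means.
#'
#' @param scores patients x comorbidities score matrix (columns named).
#' @param truth logical matrix of the same shape, TRUE where the patient has
#'   the comorbidity.
#' @param k how many labels to predict per patient.
#' @return list with `accuracy`, `upper_bound`, `k`, `n_used`,
#'   `n_excluded`.
#' @export
topk_comorbidity <- function(scores, truth, k) {
  stopifnot(k >= 1, all(dim(scores) == dim(truth)), all(is.finite(scores)))
  truth <- as.matrix(truth) > 0
  npos <- rowSums(truth)
  use <- npos > 0
  if (any(!use)) {
    message(sum(!use), " patient(s) with no comorbidity excluded from top-k")
  }
  acc <- vapply(which(use), function(i) {
    top <- order(scores[i, ], decreasing = TRUE)[seq_len(k)]
    sum(truth[i, top]) / k
  }, 0)
  ub <- pmin(npos[use], k) / k
  list(accuracy = mean(acc), upper_bound = mean(ub), k = k,
       n_used = sum(use), n_excluded = sum(!use))
}

#' Re-run an evaluation over a configuration grid
#'
#' Supported axes: `classifier`, `undersampler`, `train_fraction` (re-using
#' the supplied features), `window` and `dimension` (which rebuild the
#' representation via `feature_fn`). Folds and seeds are shared across grid
#' points so rows are comparable.
#'
#' @param axis one of `"classifier"`, `"undersampler"`, `"train_fraction"`,
#'   `"window"`, `"dimension"`.
#' @param grid vector of grid values.
#' @param features,labels,patient_ids as in [evaluate_mortality()] (used
#'   directly for the first three axes).
#' @param config base [eval_config()].
#' @param feature_fn for `window`/`dimension`: function(value) returning
#'   `list(features, labels)` rebuilt at that grid value.
#' @return data.frame, one row per grid point with auc/accuracy/f1.
#' @export
sweep_eval <- function(axis, grid, features = NULL, labels = NULL,
                       patient_ids = NULL, config = eval_config(),
                       feature_fn = NULL) {
  ok <- c("classifier", "undersampler", "train_fraction", "window", "dimension")
  if (!axis %in% ok) {
    stop("invalid axis '", axis, "'; valid: ", paste(ok, collapse = ", "))
  }
  rows <- lapply(grid, function(val) {
    cfg <- config
    res <- switch(axis,
      classifier = {
        cfg$classifier <- as.character(val)
        evaluate_mortality(features, labels, patient_ids, cfg)
      },
      undersampler = {
        cfg$undersampler <- as.character(val)
        evaluate_mortality(features, labels, patient_ids, cfg)
      },
      train_fraction = evaluate_mortality(features, labels, patient_ids, cfg,
                                          train_fraction = as.numeric(val)),
      window = , dimension = {
        if (is.null(feature_fn)) stop("axis '", axis, "' needs feature_fn")
        fb <- feature_fn(val)
        evaluate_mortality(fb$features, fb$labels, fb$patient_ids, cfg)
      })
    data.frame(axis = axis, value = as.character(val), auc = res$auc,
               accuracy = res$accuracy, f1 = res$f1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
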