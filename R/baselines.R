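#' Restrict records to an observation window
#'
#' Keeps the records whose admission date lies within `window_days` before
#' (and including) the LAST record's admission date. The last record is
#' always retained, so the result is never empty; widening the window never
#' removes records.
#'
#' @param records list of `ehr_record` in chronological order.
#' @param window_days window length in days (30/60/90/180 in the reference protocol).
#' @return sublist of `records`.
#' @export
window_filter <- function(records, window_days) {
  stopifnot(window_days > 0, length(records) >= 1)
  times <- as.Date(vapply(records, function(r) as.character(r$admission_time), ""))
  anchor <- times[length(times)]
  records[as.numeric(anchor - times) <= window_days]
}

#' Averaged raw-feature ("Hand") representation
#'
#' Elementwise mean of the record rows — the simplest window-based
#' representation. It is invariant to record order by construction, which is
#' exactly the information the sequence encoder adds.
#'
#' @param rows `n x d` matrix of multi-hot rows (already window-filtered).
#' @param stat aggregation statistic: `"mean"` (default), `"sum"` or
#'   `"max"`.
#' @return numeric vector of length `d`.
#' @export
hand_features <- function(rows, stat = c("mean", "sum", "max")) {
  stat <- match.arg(stat)
  rows <- rbind(rows)
  stopifnot(nrow(rows) >= 1)
  switch(stat,
         mean = colMeans(rows),
         sum = colSums(rows),
         max = apply(rows, 2, max))
}

#' Fit a window-based baseline representation model
#'
#' * `pca`: principal components (scores as features).
#' * `kmeans`: cluster centroids (a point is represented by its assigned
#'   centroid).
#' * `gmm`: diagonal-covariance Gaussian mixture (a point is represented by
#'   the diagonal covariance vector of its most responsible component).
#' * `hand`: no fitting; kept so all four methods share one interface.
#'
#' The full-scale reference configuration uses 512 PCA components, 16 k-means clusters and
#' 512 GMM components on the 1309-dim vocabulary; pass smaller values for
#' scaled-down schemas.
#'
#' @param x training matrix (one row per patient window aggregate).
#' @param method `"hand"`, `"pca"`, `"kmeans"` or `"gmm"`.
#' @param n_components components / clusters.
#' @param seed RNG seed for k-means / GMM initialization.
#' @return object of class `baseline_model`.
#' @importFrom mclust mclustBIC
#' @export
fit_baseline <- function(x, method = c("hand", "pca", "kmeans", "gmm"),
                         n_components = 16, seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  fit <- switch(method,
    hand = NULL,
    pca = {
      if (n_components > min(nrow(x), ncol(x))) {
        stop("PCA components must be <= min(n, d) = ", min(nrow(x), ncol(x)))
      }
      stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
    },
    kmeans = {
      if (n_components > nrow(x)) {
        stop("k-means clusters must be <= n = ", nrow(x))
      }
      with_seed(seed, stats::kmeans(x, centers = n_components, nstart = 3,
                                    iter.max = 50))
    },
    gmm = {
      if (n_components > nrow(x)) {
        stop("GMM components must be <= n = ", nrow(x))
      }
      # diagonal covariance structure per component ("XXI" is the
      # single-component spelling of the diagonal model)
      mn <- if (n_components == 1) "XXI" else c("VVI", "VII", "EII")
      with_seed(seed, mclust::Mclust(x, G = n_components, modelNames = mn,
                                     verbose = FALSE))
    })
  structure(list(method = method, fit = fit, n_components = n_components,
                 d = ncol(x)), class = "baseline_model")
}

#' Transform vectors through a fitted baseline model
#'
#' @param x matrix of row vectors in the original `d`-dim space.
#' @param model a fitted [fit_baseline()] model.
#' @return matrix of representation vectors (one row per input row).
#' @export
transform_baseline <- function(x, model) {
  stopifnot(inherits(model, "baseline_model"))
  x <- rbind(as.matrix(x))
  switch(model$method,
    hand = x,
    pca = sweep(x, 2, model$fit$center) %*% model$fit$rotation,
    kmeans = {
      cen <- model$fit$centers
      d2 <- outer(rowSums(x^2), rep(1, nrow(cen))) +
        outer(rep(1, nrow(x)), rowSums(cen^2)) - 2 * x %*% t(cen)
      cen[max.col(-d2, ties.method = "first"), , drop = FALSE]
    },
    gmm = {
      z <- stats::predict(model$fit, newdata = x)$z
      comp <- max.col(z, ties.method = "first")
      # per-component diagonal covariance vectors
      sig <- model$fit$parameters$variance$sigma
      covs <- t(vapply(seq_len(dim(sig)[3]), function(g) diag(sig[, , g]),
                       numeric(model$d)))
      covs[comp, , drop = FALSE]
    })
}

#' Window-based baseline features for a cohort of prefix samples
#'
#' For each prefix sample: filter its records to the observation window,
#' aggregate the multi-hot rows (mean by default), optionally transform
#' through a fitted PCA/k-means/GMM model, then append the demographics
#' `[normalized age, gender]` in front, mirroring the Deep Feature layout.
#'
#' The transformation model is fit on the window aggregates of `fit_idx`
#' rows only (training split) to avoid leakage.
#'
#' @param patients list of `ehr_patient`.
#' @param schema an `ehr_schema`.
#' @param method `"hand"`, `"pca"`, `"kmeans"` or `"gmm"`.
#' @param window_days observation window (default 180).
#' @param n_components see [fit_baseline()].
#' @param stat window aggregation statistic.
#' @param split one row per prefix sample (default) or per patient.
#' @param fit_idx row indices used to fit the transformation (default: all).
#' @param seed RNG seed.
#' @return list with `features`, `labels`, `comorbidities`, `model`.
#' @export
baseline_features <- function(patients, schema, method = "hand",
                              window_days = 180, n_components = 16,
                              stat = "mean", split = TRUE, fit_idx = NULL,
                              seed = 1L) {
  samples <- if (split) {
    unlist(lapply(patients, prefix_split), recursive = FALSE)
  } else {
    lapply(patients, function(p) { p$prefix_length <- length(p$records); p })
  }
  agg <- t(vapply(samples, function(s) {
    recs <- window_filter(s$records, window_days)
    rows <- t(vapply(recs, encode_record, numeric(schema_dim(schema)),
                     schema = schema))
    hand_features(rows, stat)
  }, numeric(schema_dim(schema))))
  if (is.null(fit_idx)) fit_idx <- seq_len(nrow(agg))
  model <- fit_baseline(agg[fit_idx, , drop = FALSE], method,
                        n_components = n_components, seed = seed)
  rep <- transform_baseline(agg, model)
  labels <- data.frame(
    patient_id = vapply(samples, `[[`, "", "patient_id"),
    prefix_length = vapply(samples, `[[`, 0L, "prefix_length"),
    age = vapply(samples, `[[`, 0, "age"),
    gender = vapply(samples, `[[`, 0L, "gender"),
    died = vapply(samples, `[[`, 0L, "died"),
    stringsAsFactors = FALSE
  )
  comorb <- sort(unique(unlist(lapply(samples, `[[`, "comorbidities"))))
  for (cm in comorb) {
    labels[[cm]] <- vapply(samples, function(s) cm %in% s$comorbidities, NA)
  }
  feats <- cbind(normalize_age(labels$age, schema), labels$gender, rep)
  colnames(feats) <- c("age", "gender",
                       paste0(method, seq_len(ncol(rep))))
  list(features = feats, labels = labels, comorbidities = comorb,
       model = model)
}
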