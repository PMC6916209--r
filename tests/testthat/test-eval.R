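test_that("rank-based AUC equals the all-pairs oracle", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_rank(c(0.1, 0.9), c(1, 0)), 0)
  set.seed(1)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_rank(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("AUC of random scores against random labels is near 1/2", {
  set.seed(2)
  n <- 1e4
  expect_lt(abs(auc_rank(runif(n), rbinom(n, 1, 0.3)) - 0.5), 0.03)
})

test_that("threshold metrics follow confusion-matrix arithmetic", {
  m <- threshold_metrics(c(0.9, 0.1), c(1, 0), 0.8)
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)
  # scores (0.85, 0.7, 0.9) vs labels (1, 1, 0) at 0.8:
  # TP = 1, FN = 1, FP = 1 -> acc = 1/3, F1 = 2*1/(2*1+1+1) = 0.5
  m2 <- threshold_metrics(c(0.85, 0.7, 0.9), c(1, 1, 0), 0.8)
  expect_equal(m2$accuracy, 1 / 3)
  expect_equal(m2$f1, 0.5)
})

test_that("NearMiss-1 keeps the closest majority points", {
  # lone minority point at origin, majority at distances 1..4:
  # balancing 1:1 must keep exactly the distance-1 point
  x <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0), c(4, 0))
  y <- c(1, 0, 0, 0, 0)
  keep <- nearmiss_undersample(x, y, k = 3)
  expect_setequal(keep, c(1, 2))

  # balanced input is returned unchanged
  xb <- rbind(c(0, 0), c(1, 1), c(5, 5), c(6, 6))
  expect_equal(nearmiss_undersample(xb, c(1, 1, 0, 0)), 1:4)

  expect_error(nearmiss_undersample(x, rep(1, 5)), "both classes")
})

test_that("NearMiss-1 matches brute force and respects class bounds", {
  set.seed(3)
  for (i in 1:8) {
    n1 <- sample(3:6, 1); n0 <- sample(8:15, 1)
    x <- rbind(matrix(rnorm(n1 * 2), n1), matrix(rnorm(n0 * 2, 2), n0))
    y <- c(rep(1, n1), rep(0, n0))
    keep <- nearmiss_undersample(x, y, k = 3)
    # never removes minority, ends balanced
    expect_true(all(seq_len(n1) %in% keep))
    expect_equal(sum(y[keep] == 0), n1)
    # brute force: mean distance to the 3 nearest minority points
    d <- as.matrix(dist(x))[(n1 + 1):(n1 + n0), seq_len(n1), drop = FALSE]
    md <- apply(d, 1, function(r) mean(sort(r)[seq_len(min(3, n1))]))
    want <- n1 + order(md)[seq_len(n1)]
    expect_setequal(setdiff(keep, seq_len(n1)), want)
  }
})

test_that("the undersampling trigger follows the 30% prevalence rule", {
  set.seed(4)
  n <- 300
  x <- matrix(rnorm(n * 4), n)
  labs <- data.frame(
    common = runif(n) < 0.45,
    rare = runif(n) < 0.08)
  x[labs$rare, 1] <- x[labs$rare, 1] + 2
  x[labs$common, 2] <- x[labs$common, 2] + 2
  pid <- paste0("p", seq_len(n))
  res <- evaluate_comorbidity(x, labs, c("common", "rare"), pid,
                              eval_config(classifier = "lr", folds = 3,
                                          seed = 1))
  expect_false(res$undersampled[res$task == "common"])
  expect_true(res$undersampled[res$task == "rare"])
  expect_true(all(res$auc >= 0 & res$auc <= 1))
})

test_that("separable mortality data evaluates to near-perfect metrics", {
  set.seed(5)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  x <- matrix(rnorm(n * 2), n) + 6 * y
  r <- evaluate_mortality(x, y, paste0("p", 1:n),
                          eval_config(classifier = "lr", folds = 3, seed = 2))
  expect_gt(r$auc, 0.99)
  expect_gt(r$accuracy, 0.9)
  expect_equal(nrow(r$per_fold), 3)
})

test_that("average ranks use the mid-rank convention for ties", {
  aucs <- rbind(
    task1 = c(m1 = 0.9, m2 = 0.8, m3 = 0.7),
    task2 = c(m1 = 0.8, m2 = 0.6, m3 = 0.7))
  expect_equal(unname(average_ranks(aucs)), c(1, 2.5, 2.5))
  # a method best in every task has average rank 1
  best <- rbind(c(0.9, 0.5, 0.4), c(0.95, 0.6, 0.61))
  expect_equal(unname(average_ranks(best))[1], 1)
  # two methods tied mid-table share the average of the spanned ranks
  tied <- rbind(c(0.9, 0.627, 0.627, 0.8, 0.85))
  expect_equal(unname(average_ranks(tied)), c(1, 4.5, 4.5, 3, 2))
})

test_that("top-k accuracy and its upper bound behave as defined", {
  # truth {A,B}; ranking A > C > B; k = 2 predicts {A, C}: accuracy 1/2
  scores <- matrix(c(0.9, 0.2, 0.8), 1, dimnames = list(NULL, c("A", "B", "C")))
  truth <- matrix(c(TRUE, TRUE, FALSE), 1)
  r <- topk_comorbidity(scores, truth, k = 2)
  expect_equal(r$accuracy, 0.5)
  expect_equal(r$upper_bound, 1)

  # perfect ranking with >= k truths: accuracy = upper bound = 1
  s2 <- rbind(c(0.9, 0.8, 0.1), c(0.7, 0.9, 0.2))
  t2 <- rbind(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  r2 <- topk_comorbidity(s2, t2, k = 2)
  expect_equal(r2$accuracy, 1)
  expect_equal(r2$upper_bound, 1)

  # one patient with a single truth pulls the k = 3 bound below 1
  r3 <- topk_comorbidity(scores, matrix(c(TRUE, FALSE, FALSE), 1), k = 3)
  expect_equal(r3$upper_bound, 1 / 3)

  # patients with no comorbidity are excluded
  s4 <- rbind(c(0.9, 0.1), c(0.5, 0.6))
  t4 <- rbind(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_message(r4 <- topk_comorbidity(s4, t4, k = 1), "excluded")
  expect_equal(r4$n_used, 1)
  expect_equal(r4$accuracy, 1)
})

test_that("top-k accuracy never exceeds its upper bound", {
  set.seed(6)
  for (i in 1:30) {
    n <- sample(2:8, 1); m <- sample(3:6, 1)
    scores <- matrix(runif(n * m), n)
    truth <- matrix(runif(n * m) < 0.4, n)
    truth[rowSums(truth) == 0, 1] <- TRUE
    for (k in 1:min(3, m)) {
      r <- topk_comorbidity(scores, truth, k)
      expect_lte(r$accuracy, r$upper_bound + 1e-12)
      expect_lte(r$upper_bound, 1)
    }
  }
})

test_that("sweeps share folds and reduce to direct evaluation", {
  set.seed(7)
  n <- 150
  y <- rbinom(n, 1, 0.4)
  x <- matrix(rnorm(n * 3), n) + 1.5 * y
  pid <- paste0("p", 1:n)
  cfg <- eval_config(classifier = "lr", folds = 3, seed = 9)

  single <- sweep_eval("classifier", "lr", x, y, pid, cfg)
  direct <- evaluate_mortality(x, y, pid, cfg)
  expect_equal(nrow(single), 1)
  expect_equal(single$auc, direct$auc)

  fr <- sweep_eval("train_fraction", seq(0.1, 1, by = 0.1), x, y, pid, cfg)
  expect_equal(nrow(fr), 10)
  expect_true(all(fr$auc >= 0 & fr$auc <= 1))

  expect_error(sweep_eval("bogus", 1, x, y, pid, cfg), "valid")
})
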