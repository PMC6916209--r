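mk_recs <- function(days, dx = "A") {
  lapply(seq_along(days), function(i) {
    clinical_record(paste0("r", i), as.Date("2020-01-01") + days[i],
                    diagnoses = dx)
  })
}

test_that("window filtering anchors on the last admission, inclusive", {
  same_day <- mk_recs(c(0, 0, 0))
  expect_length(window_filter(same_day, 30), 3)

  recs <- mk_recs(c(0, 100, 200))
  kept90 <- window_filter(recs, 90)
  expect_equal(vapply(kept90, `[[`, "", "record_id"), "r3")
  kept180 <- window_filter(recs, 180)
  expect_equal(vapply(kept180, `[[`, "", "record_id"), c("r2", "r3"))

  # widening the window never drops records
  prev <- 0
  for (w in c(30, 60, 90, 180, 400)) {
    n <- length(window_filter(recs, w))
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("hand features average rows and ignore their order", {
  one <- matrix(c(1, 0, 1), 1)
  expect_equal(hand_features(one), c(1, 0, 1))
  two <- rbind(c(1, 0), c(0, 1))
  expect_equal(hand_features(two), c(0.5, 0.5))
  expect_equal(hand_features(two[2:1, ]), hand_features(two))
  expect_equal(hand_features(two, "sum"), c(1, 1))
  expect_equal(hand_features(two, "max"), c(1, 1))
})

test_that("k-means representation returns the assigned centroid", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 8), 20))
  m1 <- fit_baseline(x, "kmeans", n_components = 1)
  expect_equal(as.vector(m1$fit$centers), colMeans(x))
  expect_equal(as.vector(transform_baseline(x[1, , drop = FALSE], m1)),
               colMeans(x))

  m2 <- fit_baseline(x, "kmeans", n_components = 2)
  cen <- m2$fit$centers
  got <- transform_baseline(cen[1, , drop = FALSE], m2)
  expect_equal(as.vector(got), as.vector(cen[1, ]))
  expect_error(fit_baseline(x, "kmeans", n_components = 100), "<= n")
})

test_that("PCA representation centres and projects", {
  set.seed(2)
  t_ <- rnorm(30)
  line <- cbind(t_, 2 * t_, -t_) + rnorm(90, sd = 1e-6)
  m <- fit_baseline(line, "pca", n_components = 2)
  v <- m$fit$sdev^2
  expect_gt(v[1] / sum(v), 0.999)
  # the mean vector projects to the origin
  mu <- matrix(colMeans(line), 1)
  expect_equal(as.vector(transform_baseline(mu, m)), c(0, 0),
               tolerance = 1e-8)
  expect_error(fit_baseline(line, "pca", n_components = 10), "<=")
})

test_that("GMM representation returns the responsible component's variances", {
  set.seed(3)
  a <- matrix(rnorm(100, 0, 1), 50)
  b <- matrix(rnorm(100, 20, 2), 50)
  m1 <- fit_baseline(a, "gmm", n_components = 1)
  r1 <- transform_baseline(a[1, , drop = FALSE], m1)
  # single diagonal component: fitted variances match sample moments
  expect_equal(as.vector(r1), apply(a, 2, function(v) mean((v - mean(v))^2)),
               tolerance = 0.05)

  m2 <- fit_baseline(rbind(a, b), "gmm", n_components = 2)
  deep_in_b <- matrix(c(20, 20), 1)
  rb <- transform_baseline(deep_in_b, m2)
  # the point far inside the wide component gets that component's (larger)
  # covariance vector
  centers <- t(m2$fit$parameters$mean)
  wide <- which.max(centers[, 1])
  sig <- m2$fit$parameters$variance$sigma
  expect_equal(as.vector(rb), diag(sig[, , wide]), tolerance = 1e-8)
})

test_that("every window-based representation is order-invariant", {
  sch <- tiny_schema()
  set.seed(9)
  pats <- lapply(1:40, function(i) {
    recs <- lapply(1:3, function(t) {
      tiny_record(paste0("p", i, "r", t), as.Date("2020-01-01") + 20 * t,
                  dx = sample(c("A", "B", "C"), sample(1:2, 1)),
                  med = sample(c("M1", "M2"), 1),
                  lab = setNames(runif(1, 0, 30), sample(c("T1", "T2"), 1)))
    })
    patient_history(paste0("p", i), 50 + i, i %% 2, recs)
  })
  # reverse the event content of patient 1 while keeping its dates, so the
  # same records arrive in the opposite order
  p <- pats[[1]]
  rev_p <- p
  dates <- lapply(p$records, `[[`, "admission_time")
  rev_p$records <- rev(p$records)
  for (i in seq_along(rev_p$records)) {
    rev_p$records[[i]]$admission_time <- dates[[i]]
  }
  pats_rev <- pats
  pats_rev[[1]] <- rev_p
  for (method in c("hand", "pca", "kmeans", "gmm")) {
    f1 <- baseline_features(pats, sch, method = method,
                            n_components = 2, split = FALSE, seed = 5)
    f2 <- baseline_features(pats_rev, sch, method = method,
                            n_components = 2, split = FALSE, seed = 5)
    expect_identical(f1$features, f2$features)
  }
})
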