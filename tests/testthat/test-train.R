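test_that("analytic gradients match finite differences on a tiny model", {
  set.seed(1)
  tensors <- lapply(c(1, 3, 2), function(n) matrix(rbinom(n * 4, 1, 0.4), n, 4))
  H <- 3; d <- 4
  enc <- init_gru_params(H, d)
  dec <- init_gru_params(H, H)
  proj <- init_output_projection(d, H)
  pb <- deepehr:::pad_batch(tensors)
  loss_fn <- function(e, dd, pr) {
    eo <- deepehr:::encoder_forward(pb$X, pb$lens, e)
    dout <- deepehr:::decoder_forward(eo$c, pb$L, dd, pr)
    tot <- 0
    for (t in seq_len(pb$L)) {
      m <- pb$lens >= t
      tot <- tot + reconstruction_loss(pb$X[[t]][m, , drop = FALSE],
                                       dout$Y[[t]][m, , drop = FALSE])
    }
    tot / pb$B
  }
  eo <- deepehr:::encoder_forward(pb$X, pb$lens, enc)
  dout <- deepehr:::decoder_forward(eo$c, pb$L, dec, proj)
  gr <- deepehr:::dae_backward(pb$X, pb$X, pb$lens, eo, dout, enc, dec, proj)
  eps <- 1e-6
  # probe a random subset of entries in every parameter block
  set.seed(2)
  blocks <- list(
    list(g = gr$enc$W_z, set = function(m) { e <- enc; e$W_z <- m; list(e, dec, proj) }, cur = enc$W_z),
    list(g = gr$enc$W,   set = function(m) { e <- enc; e$W <- m; list(e, dec, proj) },   cur = enc$W),
    list(g = gr$dec$W_r, set = function(m) { dd <- dec; dd$W_r <- m; list(enc, dd, proj) }, cur = dec$W_r),
    list(g = gr$V,       set = function(m) { pr <- proj; pr$V <- m; list(enc, dec, pr) }, cur = proj$V))
  for (bl in blocks) {
    for (i in sample(length(bl$cur), 6)) {
      up <- bl$cur; up[i] <- up[i] + eps
      dn <- bl$cur; dn[i] <- dn[i] - eps
      a1 <- bl$set(up); a2 <- bl$set(dn)
      num <- (loss_fn(a1[[1]], a1[[2]], a1[[3]]) -
              loss_fn(a2[[1]], a2[[2]], a2[[3]])) / (2 * eps)
      expect_equal(bl$g[i], num, tolerance = 1e-5)
    }
  }
})

test_that("training memorizes a single repeated sequence", {
  set.seed(8)
  x <- matrix(rbinom(3 * 10, 1, 0.4), 3, 10)
  tensors <- rep(list(x), 20)
  m <- train_rnn_dae(tensors, latent_dim = 8, noise_var = 0.1,
                     batch_size = 20, epochs = 200, lr = 0.01, seed = 3)
  Y <- decode_sequence(encode_sequence(x, m$encoder)$c, nrow(x),
                       m$decoder, m$projection)
  expect_lt(mean(abs(Y - x)), 0.1)
})

test_that("epoch losses descend on a synthetic cohort", {
  fx <- trained_fixture()
  log <- fx$model$training_log
  expect_lt(log[length(log)], log[1])
  expect_true(all(is.finite(log)))
})

test_that("training is deterministic under its seed", {
  set.seed(10)
  tensors <- lapply(1:12, function(i) {
    matrix(rbinom(2 * 6, 1, 0.4), 2, 6)
  })
  m1 <- train_rnn_dae(tensors, latent_dim = 4, epochs = 3, seed = 5)
  m2 <- train_rnn_dae(tensors, latent_dim = 4, epochs = 3, seed = 5)
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$encoder$W_z, m2$encoder$W_z)
  m3 <- train_rnn_dae(tensors, latent_dim = 4, epochs = 3, seed = 6)
  expect_false(identical(m1$training_log, m3$training_log))
})

test_that("deep features concatenate demographics with the latent vector", {
  fx <- trained_fixture()
  p <- fx$cohort$patients[[1]]
  sch <- fx$cohort$schema
  f <- deep_feature(p, fx$model, sch)
  expect_length(f, fx$model$latent_dim + 2)
  expect_equal(f[1], normalize_age(p$age, sch))
  expect_equal(f[2], p$gender)
  X <- encode_patient(p, sch)
  expect_equal(f[-(1:2)], encode_sequence(X, fx$model$encoder)$c)

  other <- build_schema("A")
  expect_error(deep_feature(p, fx$model, other), "schema")
})

test_that("batched encoding agrees with the sequential encoder", {
  fx <- trained_fixture()
  idx <- 1:25
  tensors <- fx$samples$tensors[idx]
  batched <- encode_tensors(tensors, fx$model)
  for (i in c(1, 7, 25)) {
    expect_equal(batched[i, ],
                 encode_sequence(tensors[[i]], fx$model$encoder)$c,
                 tolerance = 1e-10)
  }
})

test_that("latent codes are robust to small input perturbations", {
  fx <- trained_fixture()
  multi <- Filter(function(p) length(p$records) >= 2, fx$cohort$patients)[1:40]
  cos <- vapply(multi, function(p) {
    X <- encode_patient(p, fx$cohort$schema)
    c1 <- encode_sequence(X, fx$model$encoder)$c
    c2 <- encode_sequence(corrupt(X, noise_spec(0, 0.01, seed = 4)),
                          fx$model$encoder)$c
    sum(c1 * c2) / sqrt(sum(c1^2) * sum(c2^2))
  }, 0)
  expect_gt(median(cos), 0.9)
})

test_that("models survive a save/load round trip", {
  fx <- trained_fixture()
  f <- tempfile(fileext = ".json")
  save_model(fx$model, f)
  back <- load_model(f)
  x <- fx$samples$tensors[[2]]
  expect_equal(encode_sequence(x, back$encoder)$c,
               encode_sequence(x, fx$model$encoder)$c, tolerance = 1e-12)
  expect_equal(back$training_log, fx$model$training_log, tolerance = 1e-12)
  expect_identical(back$schema_fingerprint, fx$model$schema_fingerprint)
})
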