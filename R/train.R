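# Batched forward/backward passes for the denoising GRU sequence
# autoencoder. Sequences in a mini-batch are padded to the batch max length
# with zero rows; a mask both freezes encoder state updates past each true
# length (so the latent c is the last VALID hidden state) and silences the
# loss on padded steps. The decoder needs no state mask: padded steps
# receive zero loss gradient, so nothing flows back through them.

# Stack a list of n_i x d tensors into per-timestep B x d matrices.
pad_batch <- function(tensors) {
  lens <- vapply(tensors, nrow, 0L)
  L <- max(lens)
  B <- length(tensors)
  d <- ncol(tensors[[1]])
  X <- lapply(seq_len(L), function(t) {
    m <- matrix(0, B, d)
    rows <- which(lens >= t)
    m[rows, ] <- do.call(rbind, lapply(tensors[rows], function(x) x[t, ]))
    m
  })
  list(X = X, lens = lens, L = L, B = B, d = d)
}

# Encoder forward over padded input; returns final states and (optionally)
# the caches backprop needs.
encoder_forward <- function(Xt, lens, enc, keep_cache = TRUE) {
  L <- length(Xt)
  B <- nrow(Xt[[1]])
  H <- enc$hidden
  h <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", L)
  for (t in seq_len(L)) {
    m <- as.numeric(lens >= t)
    C <- cbind(h, Xt[[t]])
    Z <- sigmoid(C %*% t(enc$W_z) + rep(enc$b_z %||% 0, each = B))
    R <- sigmoid(C %*% t(enc$W_r) + rep(enc$b_r %||% 0, each = B))
    C2 <- cbind(R * h, Xt[[t]])
    G <- tanh(C2 %*% t(enc$W) + rep(enc$b %||% 0, each = B))
    hnew <- (1 - Z) * h + Z * G
    hmasked <- m * hnew + (1 - m) * h
    if (keep_cache) cache[[t]] <- list(hprev = h, Z = Z, R = R, G = G, m = m)
    h <- hmasked
  }
  list(c = h, cache = cache)
}

# Decoder forward: constant input c at every step, logistic output head.
decoder_forward <- function(cmat, L, dec, proj, keep_cache = TRUE) {
  B <- nrow(cmat)
  H <- dec$hidden
  s <- matrix(0, B, H)
  Y <- vector("list", L)
  cache <- if (keep_cache) vector("list", L)
  for (t in seq_len(L)) {
    C <- cbind(s, cmat)
    Z <- sigmoid(C %*% t(dec$W_z) + rep(dec$b_z %||% 0, each = B))
    R <- sigmoid(C %*% t(dec$W_r) + rep(dec$b_r %||% 0, each = B))
    C2 <- cbind(R * s, cmat)
    G <- tanh(C2 %*% t(dec$W) + rep(dec$b %||% 0, each = B))
    snew <- (1 - Z) * s + Z * G
    Y[[t]] <- sigmoid(snew %*% t(proj$V) + rep(proj$b, each = B))
    if (keep_cache) cache[[t]] <- list(sprev = s, Z = Z, R = R, G = G, S = snew)
    s <- snew
  }
  list(Y = Y, cache = cache)
}

zeros_like <- function(p) {
  g <- list(W_z = p$W_z * 0, W_r = p$W_r * 0, W = p$W * 0)
  if (!is.null(p$b_z)) { g$b_z <- p$b_z * 0; g$b_r <- p$b_r * 0; g$b <- p$b * 0 }
  g
}

# Full backward pass; returns gradients of the mean per-sequence summed
# cross-entropy w.r.t. every parameter. Xclean is the loss target; Xcor is
# what the encoder actually read (they coincide when noise is off).
dae_backward <- function(Xclean, Xcor, lens, enc_out, dec_out, enc, dec,
                         proj) {
  L <- length(Xclean); B <- nrow(Xclean[[1]])
  H <- enc$hidden
  ge <- zeros_like(enc); gd <- zeros_like(dec)
  gV <- proj$V * 0; gb <- proj$b * 0
  has_bias <- !is.null(enc$b_z)

  # output head + decoder BPTT
  dC_total <- matrix(0, B, H)
  dS <- matrix(0, B, H)
  for (t in rev(seq_len(L))) {
    cc <- dec_out$cache[[t]]
    mask <- as.numeric(lens >= t)
    dA <- mask * (dec_out$Y[[t]] - Xclean[[t]]) / B   # sigmoid + CE shortcut
    gV <- gV + t(dA) %*% cc$S
    gb <- gb + colSums(dA)
    dSt <- dS + dA %*% proj$V
    dZ <- dSt * (cc$G - cc$sprev)
    dG <- dSt * cc$Z
    dGpre <- dG * (1 - cc$G^2)
    C2 <- cbind(cc$R * cc$sprev, enc_out$c)
    gd$W <- gd$W + t(dGpre) %*% C2
    dC2 <- dGpre %*% dec$W
    dRS <- dC2[, seq_len(H), drop = FALSE]
    dc1 <- dC2[, H + seq_len(H), drop = FALSE]
    dR <- dRS * cc$sprev
    dSprev_a <- dRS * cc$R
    dZpre <- dZ * cc$Z * (1 - cc$Z)
    dRpre <- dR * cc$R * (1 - cc$R)
    C1 <- cbind(cc$sprev, enc_out$c)
    gd$W_z <- gd$W_z + t(dZpre) %*% C1
    gd$W_r <- gd$W_r + t(dRpre) %*% C1
    if (has_bias) {
      gd$b_z <- gd$b_z + colSums(dZpre)
      gd$b_r <- gd$b_r + colSums(dRpre)
      gd$b <- gd$b + colSums(dGpre)
    }
    dC1 <- dZpre %*% dec$W_z + dRpre %*% dec$W_r
    dS <- dSt * (1 - cc$Z) + dSprev_a + dC1[, seq_len(H), drop = FALSE]
    dC_total <- dC_total + dc1 + dC1[, H + seq_len(H), drop = FALSE]
  }

  # encoder BPTT from dL/dc
  dH <- dC_total
  for (t in rev(seq_len(L))) {
    cc <- enc_out$cache[[t]]
    m <- cc$m
    dHnew <- m * dH
    dHcarry <- (1 - m) * dH
    dZ <- dHnew * (cc$G - cc$hprev)
    dG <- dHnew * cc$Z
    dGpre <- dG * (1 - cc$G^2)
    C2 <- cbind(cc$R * cc$hprev, Xcor[[t]])
    ge$W <- ge$W + t(dGpre) %*% C2
    dC2 <- dGpre %*% enc$W
    dRH <- dC2[, seq_len(H), drop = FALSE]
    dR <- dRH * cc$hprev
    dHprev_a <- dRH * cc$R
    dZpre <- dZ * cc$Z * (1 - cc$Z)
    dRpre <- dR * cc$R * (1 - cc$R)
    C1 <- cbind(cc$hprev, Xcor[[t]])
    ge$W_z <- ge$W_z + t(dZpre) %*% C1
    ge$W_r <- ge$W_r + t(dRpre) %*% C1
    if (has_bias) {
      ge$b_z <- ge$b_z + colSums(dZpre)
      ge$b_r <- ge$b_r + colSums(dRpre)
      ge$b <- ge$b + colSums(dGpre)
    }
    dC1 <- dZpre %*% enc$W_z + dRpre %*% enc$W_r
    dH <- dHcarry + dHnew * (1 - cc$Z) + dHprev_a +
      dC1[, seq_len(H), drop = FALSE]
  }
  list(enc = ge, dec = gd, V = gV, b = gb)
}

# Adam step over a flat named list of gradient arrays.
adam_step <- function(state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    state$theta[[k]] <- state$theta[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

# Lightweight structural fingerprint so a model refuses tensors from a
# different schema.
schema_fingerprint <- function(schema) {
  paste(schema_dim(schema), length(schema$diagnosis_codes),
        length(schema$medication_groups), nrow(schema$lab_tests),
        schema$diagnosis_codes[1],
        schema$diagnosis_codes[length(schema$diagnosis_codes)], sep = "|")
}

#' Train the denoising GRU sequence autoencoder
#'
#' Minimizes the summed cross-entropy between each clean tensor and the
#' decoder's reconstruction of its Gaussian-corrupted version, by Adam over
#' mini-batches. Corruption applies to the encoder input only and is
#' resampled at every presentation; the clean tensor is always the target.
#' With `noise_var = 0` this is the plain (non-denoising) sequence
#' autoencoder ablation.
#'
#' @param tensors list of `n_i x d` binary matrices (patient/prefix
#'   tensors), e.g. `encode_samples(...)$tensors`.
#' @param latent_dim hidden/latent dimension (300 in the full-size reference
#'   configuration; smaller for desk-scale runs).
#' @param noise_var Gaussian corruption variance (default 0.1, mean 0).
#' @param batch_size mini-batch size (default 100).
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param use_bias add bias vectors to the GRU cells.
#' @param seed RNG seed covering initialization, shuffling and corruption.
#' @param schema optional `ehr_schema` to fingerprint the model against.
#' @param verbose print per-epoch losses.
#' @return object of class `rnn_dae`: encoder/decoder `gru_params`, output
#'   projection, noise spec, and the per-epoch training log.
#' @export
train_rnn_dae <- function(tensors, latent_dim = 32, noise_var = 0.1,
                          batch_size = 100, epochs = 30, lr = 1e-3,
                          use_bias = FALSE, seed = 1L, schema = NULL,
                          verbose = FALSE) {
  stopifnot(length(tensors) >= 1, latent_dim >= 1)
  d <- ncol(tensors[[1]])
  N <- length(tensors)
  sdv <- sqrt(noise_var)
  with_seed(seed, {
    enc <- init_gru_params(latent_dim, d, use_bias)
    dec <- init_gru_params(latent_dim, latent_dim, use_bias)
    proj <- init_output_projection(d, latent_dim)
    theta <- c(stats::setNames(enc[c("W_z", "W_r", "W")],
                               c("e.W_z", "e.W_r", "e.W")),
               stats::setNames(dec[c("W_z", "W_r", "W")],
                               c("d.W_z", "d.W_r", "d.W")),
               list(V = proj$V, b = proj$b))
    if (use_bias) {
      theta <- c(theta,
                 stats::setNames(enc[c("b_z", "b_r", "b")],
                                 c("e.b_z", "e.b_r", "e.b")),
                 stats::setNames(dec[c("b_z", "b_r", "b")],
                                 c("d.b_z", "d.b_r", "d.b")))
    }
    adam <- list(t = 0, theta = theta,
                 m = lapply(theta, function(x) x * 0),
                 v = lapply(theta, function(x) x * 0))
    unpack <- function(th) {
      e <- gru_params(th$e.W_z, th$e.W_r, th$e.W,
                      th$e.b_z, th$e.b_r, th$e.b)
      dd <- gru_params(th$d.W_z, th$d.W_r, th$d.W,
                       th$d.b_z, th$d.b_r, th$d.b)
      list(enc = e, dec = dd, proj = output_projection(th$V, th$b))
    }
    log <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      total <- 0
      for (start in seq(1, N, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, N)]
        batch <- pad_batch(tensors[idx])
        pars <- unpack(adam$theta)
        Xcor <- if (sdv > 0) {
          lapply(seq_len(batch$L), function(t) {
            # padded rows get noise too, but the mask freezes their updates
            batch$X[[t]] + matrix(stats::rnorm(batch$B * batch$d, 0, sdv),
                                  batch$B, batch$d)
          })
        } else batch$X
        eo <- encoder_forward(Xcor, batch$lens, pars$enc)
        dout <- decoder_forward(eo$c, batch$L, pars$dec, pars$proj)
        # masked loss against the CLEAN input
        for (t in seq_len(batch$L)) {
          mask <- batch$lens >= t
          if (any(mask)) {
            total <- total + reconstruction_loss(
              batch$X[[t]][mask, , drop = FALSE],
              dout$Y[[t]][mask, , drop = FALSE])
          }
        }
        if (!is.finite(total)) stop("training diverged (non-finite loss)")
        gr <- dae_backward(batch$X, Xcor, batch$lens, eo, dout,
                           pars$enc, pars$dec, pars$proj)
        grads <- c(stats::setNames(gr$enc[c("W_z", "W_r", "W")],
                                   c("e.W_z", "e.W_r", "e.W")),
                   stats::setNames(gr$dec[c("W_z", "W_r", "W")],
                                   c("d.W_z", "d.W_r", "d.W")),
                   list(V = gr$V, b = gr$b))
        if (use_bias) {
          grads <- c(grads,
                     stats::setNames(gr$enc[c("b_z", "b_r", "b")],
                                     c("e.b_z", "e.b_r", "e.b")),
                     stats::setNames(gr$dec[c("b_z", "b_r", "b")],
                                     c("d.b_z", "d.b_r", "d.b")))
        }
        adam <- adam_step(adam, grads, lr)
      }
      log[ep] <- total / N
      if (verbose) message("epoch ", ep, " mean loss ", round(log[ep], 4))
    }
    pars <- unpack(adam$theta)
    structure(list(
      encoder = pars$enc, decoder = pars$dec, projection = pars$proj,
      noise = noise_spec(0, noise_var), latent_dim = latent_dim,
      input_dim = d, training_log = log, seed = seed,
      schema_fingerprint = if (!is.null(schema)) schema_fingerprint(schema),
      config = list(batch_size = batch_size, epochs = epochs, lr = lr,
                    use_bias = use_bias)
    ), class = "rnn_dae")
  })
}

#' @export
print.rnn_dae <- function(x, ...) {
  cat("<rnn_dae> latent", x$latent_dim, "| input", x$input_dim,
      "| noise var", x$noise$variance,
      "| final epoch loss", round(utils::tail(x$training_log, 1), 3), "\n")
  invisible(x)
}

#' Encode a list of tensors to latent vectors
#'
#' Clean (uncorrupted) batched encoding; row `i` is the latent vector of
#' `tensors[[i]]`.
#'
#' @param tensors list of `n_i x d` matrices.
#' @param model a trained `rnn_dae`.
#' @param batch_size internal batching for speed.
#' @return `length(tensors) x latent_dim` matrix.
#' @export
encode_tensors <- function(tensors, model, batch_size = 512) {
  stopifnot(inherits(model, "rnn_dae"))
  out <- matrix(0, length(tensors), model$latent_dim)
  for (start in seq(1, length(tensors), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(tensors))
    b <- pad_batch(tensors[idx])
    out[idx, ] <- encoder_forward(b$X, b$lens, model$encoder,
                                  keep_cache = FALSE)$c
  }
  out
}

#' Deep Feature of one patient
#'
#' Encodes the patient's clean tensor (no corruption at inference) and
#' prepends the two demographic dimensions: `[normalized age, gender, c]`.
#' With the full-size 300-dim latent this is the 302-dim patient vector.
#'
#' @param patient an `ehr_patient`.
#' @param model trained `rnn_dae`.
#' @param schema the `ehr_schema` the model was trained against.
#' @return numeric vector of length `latent_dim + 2`.
#' @export
deep_feature <- function(patient, model, schema) {
  stopifnot(inherits(model, "rnn_dae"))
  if (!is.null(model$schema_fingerprint) &&
      !identical(model$schema_fingerprint, schema_fingerprint(schema))) {
    stop("schema does not match the one the model was trained on")
  }
  X <- encode_patient(patient, schema)
  c(normalize_age(patient$age, schema), patient$gender,
    encode_sequence(X, model$encoder)$c)
}

#' Deep Features for a cohort of prefix samples
#'
#' @param patients list of `ehr_patient`.
#' @param model trained `rnn_dae`.
#' @param schema matching `ehr_schema`.
#' @param split build one feature row per prefix sample (default) or per
#'   patient.
#' @return list with `features` (matrix, `latent_dim + 2` columns) and
#'   `labels` (as [encode_samples()]).
#' @export
deep_features <- function(patients, model, schema, split = TRUE) {
  if (!is.null(model$schema_fingerprint) &&
      !identical(model$schema_fingerprint, schema_fingerprint(schema))) {
    stop("schema does not match the one the model was trained on")
  }
  es <- encode_samples(patients, schema, split = split)
  cmat <- encode_tensors(es$tensors, model)
  feats <- cbind(normalize_age(es$labels$age, schema), es$labels$gender, cmat)
  colnames(feats) <- c("age", "gender", paste0("c", seq_len(model$latent_dim)))
  list(features = feats, labels = es$labels, comorbidities = es$comorbidities)
}

#' Save / load a trained model as JSON
#' @param model an `rnn_dae`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  o <- list(
    encoder = model$encoder[c("W_z", "W_r", "W", "b_z", "b_r", "b")],
    decoder = model$decoder[c("W_z", "W_r", "W", "b_z", "b_r", "b")],
    projection = model$projection[c("V", "b")],
    noise_variance = model$noise$variance,
    latent_dim = model$latent_dim, input_dim = model$input_dim,
    training_log = model$training_log, seed = model$seed,
    schema_fingerprint = model$schema_fingerprint, config = model$config
  )
  writeLines(jsonlite::toJSON(o, digits = NA, auto_unbox = TRUE,
                              matrix = "rowmajor", null = "null"), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  o <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  as_mat <- function(x) if (is.null(x)) NULL else as.matrix(x)
  enc <- gru_params(as_mat(o$encoder$W_z), as_mat(o$encoder$W_r),
                    as_mat(o$encoder$W), o$encoder$b_z, o$encoder$b_r,
                    o$encoder$b)
  dec <- gru_params(as_mat(o$decoder$W_z), as_mat(o$decoder$W_r),
                    as_mat(o$decoder$W), o$decoder$b_z, o$decoder$b_r,
                    o$decoder$b)
  structure(list(
    encoder = enc, decoder = dec,
    projection = output_projection(as_mat(o$projection$V),
                                   as.numeric(o$projection$b)),
    noise = noise_spec(0, o$noise_variance),
    latent_dim = o$latent_dim, input_dim = o$input_dim,
    training_log = o$training_log, seed = o$seed,
    schema_fingerprint = o$schema_fingerprint,
    config = o$config
  ), class = "rnn_dae")
}
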