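#' GRU parameter set
#'
#' Three weight matrices acting on the concatenation `[state, input]`:
#' update gate `W_z`, reset gate `W_r`, and candidate `W`, each of shape
#' `hidden x (hidden + input)`. The printed cell has no bias terms; set
#' `use_bias = TRUE` in [init_gru_params()] to add them.
#'
#' @param W_z,W_r,W numeric matrices, all `hidden x (hidden + input)`.
#' @param b_z,b_r,b optional bias vectors of length `hidden`.
#' @return list of class `gru_params`.
#' @export
gru_params <- function(W_z, W_r, W, b_z = NULL, b_r = NULL, b = NULL) {
  dims <- vapply(list(W_z, W_r, W), dim, integer(2))
  if (any(dims != dims[, 1])) stop("W_z, W_r, W must share one shape")
  if (!all(is.finite(W_z)) || !all(is.finite(W_r)) || !all(is.finite(W))) {
    stop("GRU weights must be finite")
  }
  hidden <- nrow(W_z)
  input <- ncol(W_z) - hidden
  if (input < 1) stop("columns must exceed rows: shape hidden x (hidden + input)")
  structure(list(W_z = W_z, W_r = W_r, W = W,
                 b_z = b_z, b_r = b_r, b = b,
                 hidden = hidden, input = input),
            class = "gru_params")
}

#' Randomly initialize GRU parameters
#'
#' Uniform initialization with the scaled (Glorot) limit
#' `sqrt(6 / (fan_in + fan_out))`.
#'
#' @param hidden hidden-state dimension.
#' @param input input dimension.
#' @param use_bias include bias vectors (zero-initialized).
#' @return a `gru_params`.
#' @export
init_gru_params <- function(hidden, input, use_bias = FALSE) {
  lim <- sqrt(6 / (hidden + input + hidden))
  mk <- function() matrix(stats::runif(hidden * (hidden + input), -lim, lim),
                          hidden, hidden + input)
  z <- if (use_bias) numeric(hidden) else NULL
  gru_params(mk(), mk(), mk(), b_z = z, b_r = z, b = z)
}

#' One GRU step
#'
#' Computes the update gate `z = sigmoid(W_z [prev, x])`, reset gate
#' `r = sigmoid(W_r [prev, x])`, candidate `tanh(W [r * prev, x])` and the
#' new state `(1 - z) * prev + z * candidate`. The same cell serves encoder
#' (input = record vector) and decoder (input = latent vector `c`).
#'
#' @param x input vector of length `params$input`.
#' @param prev previous hidden state, length `params$hidden`.
#' @param params a `gru_params`.
#' @return list with `h` (new state) and the gate values `z`, `r`,
#'   `h_tilde` (exposed for testing).
#' @export
gru_cell <- function(x, prev, params) {
  stopifnot(inherits(params, "gru_params"))
  if (length(x) != params$input) {
    stop("input length ", length(x), " != expected ", params$input)
  }
  if (length(prev) != params$hidden) {
    stop("state length ", length(prev), " != expected ", params$hidden)
  }
  cx <- c(prev, x)
  z <- sigmoid(drop(params$W_z %*% cx) + (params$b_z %||% 0))
  r <- sigmoid(drop(params$W_r %*% cx) + (params$b_r %||% 0))
  h_tilde <- tanh(drop(params$W %*% c(r * prev, x)) + (params$b %||% 0))
  list(h = (1 - z) * prev + z * h_tilde, z = z, r = r, h_tilde = h_tilde)
}

#' Gaussian corruption specification
#'
#' @param mean noise mean (0 in the reference configuration).
#' @param variance noise variance (0.1 in the reference configuration; 0 gives
#'   the plain, non-denoising autoencoder variant).
#' @param seed optional seed for a reproducible draw.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(mean = 0, variance = 0.1, seed = NULL) {
  if (variance < 0) stop("variance must be >= 0")
  structure(list(mean = mean, variance = variance, seed = seed),
            class = "noise_spec")
}

#' Corrupt a tensor with i.i.d. Gaussian noise
#'
#' The stochastic mapping of the denoising autoencoder: every entry gets an
#' independent Gaussian perturbation. A fresh draw is made per call unless
#' the spec carries a seed.
#'
#' @param X numeric matrix (a patient tensor).
#' @param noise a [noise_spec()].
#' @return real-valued matrix of the same shape.
#' @export
corrupt <- function(X, noise = noise_spec()) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$variance == 0 && noise$mean == 0) return(X)
  draw <- function() X + matrix(stats::rnorm(length(X), noise$mean,
                                             sqrt(noise$variance)),
                                nrow(X), ncol(X))
  if (!is.null(noise$seed)) with_seed(noise$seed, draw()) else draw()
}

#' Encode a record sequence into its latent vector
#'
#' Iterates the GRU over the rows of `X` chronologically from a zero initial
#' state; the latent patient vector `c` is the final hidden state.
#'
#' @param X numeric matrix, rows = records (possibly corrupted).
#' @param params encoder `gru_params`.
#' @return list with `c` (final hidden state) and `states`
#'   (`n x hidden` matrix of all hidden states).
#' @export
encode_sequence <- function(X, params) {
  X <- rbind(X)
  if (nrow(X) < 1) stop("cannot encode an empty sequence")
  h <- numeric(params$hidden)
  states <- matrix(0, nrow(X), params$hidden)
  for (t in seq_len(nrow(X))) {
    h <- gru_cell(X[t, ], h, params)$h
    states[t, ] <- h
  }
  list(c = h, states = states)
}

#' Output projection of the decoder
#'
#' Affine map from the decoder state (dimension `hidden`) to the record
#' dimension `d`, followed by a logistic squash so every reconstructed entry
#' lies strictly in (0, 1) as the cross-entropy loss requires.
#'
#' @param V numeric `d x hidden` matrix.
#' @param b numeric length-`d` offset.
#' @return list of class `output_projection`.
#' @export
output_projection <- function(V, b = numeric(nrow(V))) {
  structure(list(V = V, b = b), class = "output_projection")
}

#' @rdname output_projection
#' @param d,hidden output and input dimensions for random initialization.
#' @export
init_output_projection <- function(d, hidden) {
  lim <- sqrt(6 / (hidden + d))
  output_projection(matrix(stats::runif(d * hidden, -lim, lim), d, hidden),
                    numeric(d))
}

#' Decode a latent vector into a reconstructed sequence
#'
#' Runs the decoder GRU for `n` steps from a zero initial state with the
#' latent vector `c` as a constant input at every step (no autoregressive
#' feedback), and projects each state through the output head.
#'
#' @param c latent vector.
#' @param n number of steps (records) to emit.
#' @param params decoder `gru_params` (input dimension = `length(c)`).
#' @param projection an [output_projection()].
#' @return `n x d` matrix with entries in (0, 1).
#' @export
decode_sequence <- function(c, n, params, projection) {
  if (n < 1) stop("n must be >= 1")
  s <- numeric(params$hidden)
  Y <- matrix(0, n, length(projection$b))
  for (t in seq_len(n)) {
    s <- gru_cell(c, s, params)$h
    Y[t, ] <- sigmoid(drop(projection$V %*% s) + projection$b)
  }
  Y
}

#' Cross-entropy reconstruction loss
#'
#' `L = -sum_ij [ x_ij log y_ij + (1 - x_ij) log(1 - y_ij) ]` over the whole
#' sequence. Reconstructed entries are clamped to `[eps, 1 - eps]` before
#' the logs.
#'
#' @param X clean binary tensor.
#' @param Y reconstruction, same shape, entries in (0, 1).
#' @param eps numerical clamp.
#' @return non-negative scalar.
#' @export
reconstruction_loss <- function(X, Y, eps = 1e-7) {
  if (!all(dim(rbind(X)) == dim(rbind(Y)))) stop("X and Y shapes differ")
  Yc <- pmin(pmax(Y, eps), 1 - eps)
  -sum(X * log(Yc) + (1 - X) * log(1 - Yc))
}
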