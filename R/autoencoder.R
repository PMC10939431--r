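#' Single-layer autoencoder
#'
#' Compresses each row of a similarity matrix into a d-dimensional
#' embedding: `z = g(x W_enc + b_enc)`, `x_hat = g(z W_dec + b_dec)`,
#' trained by full-batch Adam on the mean per-row squared reconstruction
#' error `(1/n) sum_i ||x_i - x_hat_i||^2`.
#'
#' @name autoencoder
NULL

.activation <- function(name) {
  switch(name,
         relu = list(f = function(x) pmax(x, 0),
                     df = function(pre) (pre > 0) * 1),
         tanh = list(f = tanh,
                     df = function(pre) 1 - tanh(pre)^2),
         stop("unknown activation: ", name))
}

#' Create autoencoder parameters
#'
#' Glorot-style uniform initialisation scaled by fan-in/fan-out. Biases
#' start at a small positive value (0.1) so that, with nonnegative
#' similarity inputs, no ReLU unit is dead from the first step. Seeded by
#' the caller.
#'
#' @param n Input dimensionality (similarity matrix size).
#' @param d Latent dimensionality (`d < n`).
#' @param activation `"relu"` or `"tanh"`.
#' @return A list of class `"autoencoder_params"`.
#' @export
init_autoencoder <- function(n, d, activation = "relu") {
  if (d >= n) stop("latent dimension d must be smaller than input size n")
  lim1 <- sqrt(6 / (n + d))
  params <- list(
    W_enc = matrix(stats::runif(n * d, -lim1, lim1), n, d),
    b_enc = rep(0.1, d),
    W_dec = matrix(stats::runif(d * n, -lim1, lim1), d, n),
    b_dec = rep(0.1, n),
    activation = activation
  )
  class(params) <- "autoencoder_params"
  params
}

#' Encode a row vector
#'
#' @param x Numeric vector of length n (a similarity-matrix row), or an
#'   n-column matrix of such rows.
#' @param params An `autoencoder_params` object.
#' @return The latent representation `g(x W_enc + b_enc)`.
#' @export
ae_encode <- function(x, params) {
  act <- .activation(params$activation)
  x <- rbind(x)
  if (ncol(x) != nrow(params$W_enc)) stop("input length mismatch")
  pre <- sweep(x %*% params$W_enc, 2, params$b_enc, "+")
  out <- act$f(pre)
  if (nrow(out) == 1L) drop(out) else out
}

#' Decode a latent vector
#'
#' @param z Numeric vector of length d, or a d-column matrix.
#' @inheritParams ae_encode
#' @return The reconstruction `g(z W_dec + b_dec)`.
#' @export
ae_decode <- function(z, params) {
  act <- .activation(params$activation)
  z <- rbind(z)
  if (ncol(z) != nrow(params$W_dec)) stop("latent length mismatch")
  pre <- sweep(z %*% params$W_dec, 2, params$b_dec, "+")
  out <- act$f(pre)
  if (nrow(out) == 1L) drop(out) else out
}

#' Squared-error reconstruction loss
#'
#' Per-row loss is the squared L2 distance; over a matrix the training
#' objective is the mean of the per-row losses.
#'
#' @param x,x_hat Equal-length numeric vectors (or equal-shape matrices).
#' @return Nonnegative scalar.
#' @export
reconstruction_loss <- function(x, x_hat) {
  if (length(x) != length(x_hat)) stop("length mismatch")
  x <- rbind(x)
  x_hat <- rbind(x_hat)
  mean(rowSums((x - x_hat)^2))
}

# one Adam step; state holds first/second moments and the step counter
.adam_step <- function(value, grad, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  t <- state$t + 1
  m_hat <- state$m / (1 - beta1^t)
  v_hat <- state$v / (1 - beta2^t)
  state$t <- t
  list(value = value - lr * m_hat / (sqrt(v_hat) + eps), state = state)
}

.adam_init <- function(value) list(m = value * 0, v = value * 0, t = 0)

#' Train the autoencoder on a similarity matrix
#'
#' Rows of `S` are the training samples. Training is full-batch Adam,
#' seeded and therefore exactly reproducible; divergence (non-finite loss)
#' is reported as an error.
#'
#' @param S Square similarity matrix with ids as dimnames.
#' @param d Latent dimensionality, `d < nrow(S)`.
#' @param config An [hda_config()]; uses `ae_learning_rate`, `ae_epochs`
#'   and `seed`.
#' @param activation `"relu"` or `"tanh"`.
#' @return A list with `embeddings` (n x d matrix of encoded rows, row
#'   ids preserved), `params`, and `loss_trace` (initial loss followed by
#'   the loss after each epoch).
#' @export
train_autoencoder <- function(S, d, config = hda_config(),
                              activation = "relu") {
  validate_similarity_matrix(S)
  n <- nrow(S)
  d <- as.integer(d)
  if (d >= n) stop("latent dimension d must be smaller than input size n")
  set.seed(config$seed)
  params <- init_autoencoder(n, d, activation)
  act <- .activation(activation)
  lr <- config$ae_learning_rate
  st <- lapply(params[c("W_enc", "b_enc", "W_dec", "b_dec")], .adam_init)

  forward <- function(p) {
    pre1 <- sweep(S %*% p$W_enc, 2, p$b_enc, "+")
    Z <- act$f(pre1)
    pre2 <- sweep(Z %*% p$W_dec, 2, p$b_dec, "+")
    Xhat <- act$f(pre2)
    list(pre1 = pre1, Z = Z, pre2 = pre2, Xhat = Xhat,
         loss = mean(rowSums((S - Xhat)^2)))
  }

  fw <- forward(params)
  trace <- fw$loss
  for (epoch in seq_len(config$ae_epochs)) {
    dXhat <- (2 / n) * (fw$Xhat - S) * act$df(fw$pre2)
    gW_dec <- t(fw$Z) %*% dXhat
    gb_dec <- colSums(dXhat)
    dZ <- (dXhat %*% t(params$W_dec)) * act$df(fw$pre1)
    gW_enc <- t(S) %*% dZ
    gb_enc <- colSums(dZ)

    for (nm in c("W_enc", "b_enc", "W_dec", "b_dec")) {
      g <- switch(nm, W_enc = gW_enc, b_enc = gb_enc,
                  W_dec = gW_dec, b_dec = gb_dec)
      upd <- .adam_step(params[[nm]], g, st[[nm]], lr)
      params[[nm]] <- upd$value
      st[[nm]] <- upd$state
    }
    fw <- forward(params)
    if (!is.finite(fw$loss)) {
      stop("autoencoder training diverged (non-finite loss); ",
           "try a smaller ae_learning_rate")
    }
    trace <- c(trace, fw$loss)
  }

  emb <- act$f(sweep(S %*% params$W_enc, 2, params$b_enc, "+"))
  rownames(emb) <- rownames(S)
  list(embeddings = emb, params = params, loss_trace = trace)
}
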