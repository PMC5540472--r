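#' Logistic sigmoid
#'
#' The activation function used throughout the network,
#' `f(a) = 1 / (1 + exp(-a))`. Saturates to 0/1 for large `|a|`, never NaN.
#'
#' @param a Numeric scalar, vector or matrix.
#' @return Same shape as `a`, values in (0, 1).
#' @export
sigmoid <- function(a) 1 / (1 + exp(-a))

#' Sparsity hyperparameters
#'
#' @param alpha Weight of the KL sparsity penalty in the autoencoder cost
#'   (`alpha >= 0`). The default 0.3 keeps hidden activity near `rho`
#'   without collapsing the representation: with 80 hidden units a much
#'   larger weight lets the penalty dominate the reconstruction term and
#'   the optimum degenerates to constant activations.
#' @param rho Target mean hidden activation in (0, 1); hidden units are
#'   pushed to be active on about a fraction `rho` of the inputs.
#' @return A `sparsity_config` object.
#' @export
sparsity_config <- function(alpha = 0.3, rho = 0.05) {
  stopifnot(alpha >= 0, rho > 0, rho < 1)
  structure(list(alpha = alpha, rho = rho), class = "sparsity_config")
}

#' Training hyperparameters
#'
#' Full-batch gradient descent with a halve-on-increase step-size backoff:
#' a step that would increase the cost is retried with half the learning
#' rate, so the accepted cost trace is non-increasing.
#'
#' @param learning_rate Initial step size, > 0.
#' @param max_iters Number of accepted gradient steps (pretraining stage).
#' @param refine_iters Function-evaluation budget of the supervised
#'   fine-tuning stage.
#' @param seed Integer seed for weight initialisation.
#' @return A `train_control` object.
#' @export
train_control <- function(learning_rate = 0.5, max_iters = 400,
                          refine_iters = 400, seed = 1L) {
  stopifnot(learning_rate > 0, max_iters >= 0, refine_iters >= 0)
  structure(list(learning_rate = learning_rate,
                 max_iters = as.integer(max_iters),
                 refine_iters = as.integer(refine_iters),
                 seed = as.integer(seed)),
            class = "train_control")
}

#' Construct / initialise an autoencoder layer
#'
#' Weights are drawn uniformly from
#' `+/- sqrt(6 / (fan_in + fan_out))`; offsets start at zero.
#'
#' @param n_visible,n_hidden Layer dimensions.
#' @param seed Integer seed.
#' @return An `autoencoder_layer`: encoder weights `W_e` (hidden x visible),
#'   decoder weights `W_d` (visible x hidden), offsets `b_e`, `b_d`.
#' @export
init_autoencoder <- function(n_visible, n_hidden, seed = 1L) {
  stopifnot(n_visible >= 1, n_hidden >= 1)
  set.seed(seed)
  r <- sqrt(6 / (n_visible + n_hidden))
  structure(list(
    W_e = matrix(stats::runif(n_hidden * n_visible, -r, r), n_hidden),
    W_d = matrix(stats::runif(n_visible * n_hidden, -r, r), n_visible),
    b_e = numeric(n_hidden),
    b_d = numeric(n_visible)), class = "autoencoder_layer")
}

#' Forward pass through one autoencoder layer
#'
#' Encode then decode: `z = f(W_e n + b_e)`, `y = f(W_d z + b_d)` with `f`
#' the sigmoid.
#'
#' @param layer An `autoencoder_layer`.
#' @param n Input: numeric vector, or matrix with one input per row.
#' @return List with `z` (hidden activation) and `y` (reconstruction), each
#'   a vector or row-matrix matching the input shape; entries in (0, 1).
#' @export
ae_forward <- function(layer, n) {
  vec <- is.null(dim(n))
  X <- if (vec) matrix(n, 1) else as.matrix(n)
  if (ncol(X) != ncol(layer$W_e))
    stop("input dimension ", ncol(X), " does not match layer visible size ",
         ncol(layer$W_e))
  Z <- sigmoid(tcrossprod(X, layer$W_e) +
                 matrix(layer$b_e, nrow(X), length(layer$b_e), byrow = TRUE))
  Y <- sigmoid(tcrossprod(Z, layer$W_d) +
                 matrix(layer$b_d, nrow(X), length(layer$b_d), byrow = TRUE))
  if (vec) list(z = drop(Z), y = drop(Y)) else list(z = Z, y = Y)
}

#' Encode a batch through one layer
#' @inheritParams ae_forward
#' @return Hidden activations, one row per input.
#' @export
ae_encode <- function(layer, n) {
  ae_forward(layer, n)$z
}

#' KL-divergence sparsity penalty
#'
#' The Bernoulli Kullback-Leibler divergence
#' `KL(rho || rho_hat) = rho * ln(rho / rho_hat) +
#'  (1 - rho) * ln((1 - rho) / (1 - rho_hat))`
#' (natural logarithm) between the target activation `rho` and a hidden
#' unit's observed mean activation `rho_hat`. Nonnegative, zero iff
#' `rho_hat == rho`, convex in `rho_hat`. `rho_hat` is clamped to
#' `[1e-6, 1 - 1e-6]` so the logarithms stay finite.
#'
#' @param rho Target activation in (0, 1).
#' @param rho_hat Observed mean activation(s); vectorised.
#' @return Nonnegative numeric of the same length as `rho_hat`.
#' @export
kl_penalty <- function(rho, rho_hat) {
  eps <- 1e-6
  rho_hat <- pmin(pmax(rho_hat, eps), 1 - eps)
  rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat))
}

#' Sparse autoencoder cost
#'
#' `cost = 1/(2q) * sum_i ||n_i - y_i||^2 +
#'   alpha * sum_j KL(rho || rho_hat_j)`
#' over a batch of `q` inputs, where `rho_hat_j` is hidden unit `j`'s mean
#' activation over the batch.
#'
#' @param layer An `autoencoder_layer`.
#' @param X Batch matrix, one input per row, entries in \[0,1\].
#' @param sparsity A [sparsity_config()].
#' @return List with `total`, `reconstruction` and `sparsity` cost terms.
#' @export
ae_cost <- function(layer, X, sparsity = sparsity_config()) {
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("empty batch")
  fwd <- ae_forward(layer, X)
  q <- nrow(X)
  recon <- sum((X - fwd$y)^2) / (2 * q)
  rho_hat <- colMeans(fwd$z)
  sp <- sparsity$alpha * sum(kl_penalty(sparsity$rho, rho_hat))
  list(total = recon + sp, reconstruction = recon, sparsity = sp)
}

#' Analytic gradients of the sparse autoencoder cost
#'
#' Exact backpropagated gradients of [ae_cost()] with respect to `W_e`,
#' `W_d`, `b_e`, `b_d`, including the sparsity term's dependence on the
#' hidden activations through `rho_hat`.
#'
#' @inheritParams ae_cost
#' @return List of gradients with the same shapes as the layer fields.
#' @export
ae_gradients <- function(layer, X, sparsity = sparsity_config()) {
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("empty batch")
  q <- nrow(X)
  fwd <- ae_forward(layer, X)
  Z <- fwd$z
  Y <- fwd$y
  # output stage: dC/dY = (Y - X)/q, through the sigmoid
  delta_y <- ((Y - X) / q) * Y * (1 - Y)            # q x n_visible
  gW_d <- crossprod(delta_y, Z)                     # n_visible x h
  gb_d <- colSums(delta_y)
  # hidden stage: reconstruction path + sparsity path (through rho_hat)
  eps <- 1e-6
  rho_hat <- pmin(pmax(colMeans(Z), eps), 1 - eps)
  dkl <- -sparsity$rho / rho_hat + (1 - sparsity$rho) / (1 - rho_hat)
  dZ <- delta_y %*% layer$W_d +
    matrix(sparsity$alpha * dkl / q, q, ncol(Z), byrow = TRUE)
  delta_z <- dZ * Z * (1 - Z)                       # q x h
  list(W_e = crossprod(delta_z, X), W_d = gW_d,
       b_e = colSums(delta_z), b_d = gb_d)
}

#' Train one sparse autoencoder
#'
#' Full-batch gradient descent on [ae_cost()] with halve-on-increase
#' step-size backoff; the accepted cost trace is non-increasing and the run
#' is deterministic given `cfg$seed`. With `max_iters = 0` the seeded
#' initialisation is returned untouched.
#'
#' @param X Batch matrix (rows are inputs in \[0,1\]).
#' @param n_hidden Hidden layer width.
#' @param sparsity A [sparsity_config()].
#' @param cfg A [train_control()].
#' @return A trained `autoencoder_layer` with attribute `trace` (accepted
#'   cost values, starting at the initial cost).
#' @export
train_autoencoder <- function(X, n_hidden, sparsity = sparsity_config(),
                              cfg = train_control()) {
  X <- as.matrix(X)
  layer <- init_autoencoder(ncol(X), n_hidden, seed = cfg$seed)
  cost <- ae_cost(layer, X, sparsity)$total
  if (!is.finite(cost)) stop("training diverged at iteration 0 (cost not finite)")
  trace <- cost
  lr <- cfg$learning_rate
  fields <- c("W_e", "W_d", "b_e", "b_d")
  for (it in seq_len(cfg$max_iters)) {
    g <- ae_gradients(layer, X, sparsity)
    repeat {
      cand <- layer
      for (f in fields) cand[[f]] <- layer[[f]] - lr * g[[f]]
      cand_cost <- ae_cost(cand, X, sparsity)$total
      if (is.nan(cand_cost))
        stop("training diverged at iteration ", it)
      if (cand_cost <= cost) {
        layer <- cand
        cost <- cand_cost
        lr <- min(lr * 2, cfg$learning_rate)   # recover after backoff
        break
      }
      lr <- lr / 2
      if (lr < 1e-12) break          # cost is at a numerical floor
    }
    trace <- c(trace, cost)
    if (lr < 1e-12) break
  }
  attr(layer, "trace") <- trace
  layer
}

#' Greedy layer-wise pretraining of a stacked autoencoder
#'
#' Trains the first layer on the batch, then each subsequent layer on the
#' previous layer's hidden activations of the batch.
#'
#' @param X Batch matrix (rows are inputs in \[0,1\]).
#' @param layer_sizes Integer vector of hidden widths, one per stacked
#'   layer (default three layers of 80).
#' @inheritParams train_autoencoder
#' @return Ordered list of trained `autoencoder_layer`s.
#' @export
pretrain_stack <- function(X, layer_sizes = c(80, 80, 80),
                           sparsity = sparsity_config(),
                           cfg = train_control()) {
  stopifnot(length(layer_sizes) >= 1)
  layers <- vector("list", length(layer_sizes))
  cur <- as.matrix(X)
  for (i in seq_along(layer_sizes)) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer((cfg$seed + i - 1L) %% .Machine$integer.max)
    layers[[i]] <- train_autoencoder(cur, layer_sizes[i], sparsity, cfg_i)
    cur <- ae_encode(layers[[i]], cur)
  }
  layers
}

#' Encode a batch through a stack of layers
#'
#' @param layers List of `autoencoder_layer`s.
#' @param X Batch matrix.
#' @return Top-layer hidden activations, one row per input.
#' @export
stack_encode <- function(layers, X) {
  for (l in layers) X <- ae_encode(l, X)
  X
}
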