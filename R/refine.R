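# Supervised fine-tuning: backpropagation of the softmax cross-entropy
# through all encoder layers (branches + joint) and the head. Decoder
# weights are untouched. Optimised with L-BFGS on the flattened parameters.

flatten_params <- function(model) {
  p <- c()
  for (br in model$branches)
    for (l in br$layers) p <- c(p, as.vector(l$W_e), l$b_e)
  for (l in model$joint) p <- c(p, as.vector(l$W_e), l$b_e)
  c(p, as.vector(model$head))
}

unflatten_params <- function(par, model) {
  pos <- 1L
  take <- function(n) {
    out <- par[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  for (i in seq_along(model$branches))
    for (j in seq_along(model$branches[[i]]$layers)) {
      l <- model$branches[[i]]$layers[[j]]
      model$branches[[i]]$layers[[j]]$W_e <-
        matrix(take(length(l$W_e)), nrow(l$W_e))
      model$branches[[i]]$layers[[j]]$b_e <- take(length(l$b_e))
    }
  for (j in seq_along(model$joint)) {
    l <- model$joint[[j]]
    model$joint[[j]]$W_e <- matrix(take(length(l$W_e)), nrow(l$W_e))
    model$joint[[j]]$b_e <- take(length(l$b_e))
  }
  model$head <- matrix(take(length(model$head)), nrow(model$head))
  stopifnot(pos == length(par) + 1L)
  model
}

# Encode a chain of layers keeping every layer's input; returns list of
# per-layer inputs plus the final output.
chain_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1]] <- X
  for (j in seq_along(layers))
    acts[[j + 1]] <- ae_encode(layers[[j]], acts[[j]])
  acts
}

# Backpropagate dC/d(output) through a chain; returns encoder gradients per
# layer and dC/d(input).
chain_backward <- function(layers, acts, delta) {
  grads <- vector("list", length(layers))
  for (j in rev(seq_along(layers))) {
    out <- acts[[j + 1]]
    dpre <- delta * out * (1 - out)
    grads[[j]] <- list(W_e = crossprod(dpre, acts[[j]]),
                       b_e = colSums(dpre))
    delta <- dpre %*% layers[[j]]$W_e
  }
  list(grads = grads, delta_in = delta)
}

refine_cost_grad <- function(par, model, Xm, Xe, L, lambda = 1e-4) {
  model <- unflatten_params(par, model)
  q <- length(L)
  k <- nrow(model$head)
  br_acts <- lapply(model$branches, function(br)
    chain_forward(br$layers, branch_input(br, Xm, Xe)))
  tops <- lapply(br_acts, function(a) a[[length(a)]])
  widths <- vapply(tops, ncol, integer(1))
  top <- do.call(cbind, tops)
  joint_acts <- chain_forward(model$joint, top)
  rep_top <- joint_acts[[length(joint_acts)]]

  P <- softmax_probabilities(model$head, rep_top)
  if (is.null(dim(P))) P <- matrix(P, 1)
  W0 <- model$head
  W0[, 1] <- 0
  cost <- -mean(log(pmax(P[cbind(seq_len(q), L)], 1e-300))) +
    lambda / 2 * sum(W0^2)

  Yh <- matrix(0, q, k)
  Yh[cbind(seq_len(q), L)] <- 1
  G <- (P - Yh) / q
  g_head <- crossprod(G, cbind(1, rep_top)) + lambda * W0
  delta <- G %*% model$head[, -1, drop = FALSE]

  jb <- chain_backward(model$joint, joint_acts, delta)
  delta <- jb$delta_in
  grad <- c()
  off <- 0L
  for (i in seq_along(model$branches)) {
    d_i <- delta[, off + seq_len(widths[i]), drop = FALSE]
    off <- off + widths[i]
    bb <- chain_backward(model$branches[[i]]$layers, br_acts[[i]], d_i)
    for (g in bb$grads) grad <- c(grad, as.vector(g$W_e), g$b_e)
  }
  for (g in jb$grads) grad <- c(grad, as.vector(g$W_e), g$b_e)
  grad <- c(grad, as.vector(g_head))
  list(cost = cost, grad = grad)
}

refine_model <- function(model, Xm, Xe, L, maxit = 400, lambda = 1e-4) {
  par0 <- flatten_params(model)
  cache <- new.env(parent = emptyenv())
  eval_at <- function(p) {
    if (is.null(cache$par) || length(cache$par) != length(p) ||
        any(cache$par != p)) {
      cache$par <- p
      cache$val <- refine_cost_grad(p, model, Xm, Xe, L, lambda)
    }
    cache$val
  }
  opt <- stats::optim(par0, fn = function(p) eval_at(p)$cost,
                      gr = function(p) eval_at(p)$grad,
                      method = "L-BFGS-B", control = list(maxit = maxit))
  if (!is.finite(opt$value)) stop("fine-tuning diverged (non-finite loss)")
  # keep whichever parameters are better; L-BFGS never returns worse than
  # the start in practice, but guard the non-increasing contract
  c0 <- refine_cost_grad(par0, model, Xm, Xe, L, lambda)$cost
  if (opt$value <= c0) model <- unflatten_params(opt$par, model)
  model
}
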