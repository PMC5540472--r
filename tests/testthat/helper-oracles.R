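# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Central finite differences of a scalar function of a numeric vector.
numeric_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

max_rel_err <- function(analytic, numeric, floor = 1e-6) {
  max(abs(analytic - numeric) / pmax(abs(numeric), floor))
}

# Exhaustive minimum over all monotone warping paths (steps right, down,
# diagonal) of the summed local costs; plain recursion, no dynamic-program
# table shared with the implementation.
bruteforce_dtw <- function(a, b) {
  a <- if (is.null(dim(a))) matrix(a, ncol = 1) else as.matrix(a)
  b <- if (is.null(dim(b))) matrix(b, ncol = 1) else as.matrix(b)
  cost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  rec <- function(i, j) {
    c0 <- cost(i, j)
    if (i == 1 && j == 1) return(c0)
    opts <- c()
    if (i > 1) opts <- c(opts, rec(i - 1, j))
    if (j > 1) opts <- c(opts, rec(i, j - 1))
    if (i > 1 && j > 1) opts <- c(opts, rec(i - 1, j - 1))
    c0 + min(opts)
  }
  rec(nrow(a), nrow(b))
}

# Scalar-loop re-implementation of the sparse autoencoder cost.
loop_ae_cost <- function(layer, X, alpha, rho) {
  q <- nrow(X)
  h <- length(layer$b_e)
  nv <- length(layer$b_d)
  Z <- matrix(0, q, h)
  recon <- 0
  for (i in seq_len(q)) {
    z <- numeric(h)
    for (j in seq_len(h))
      z[j] <- 1 / (1 + exp(-(sum(layer$W_e[j, ] * X[i, ]) + layer$b_e[j])))
    Z[i, ] <- z
    for (v in seq_len(nv)) {
      y <- 1 / (1 + exp(-(sum(layer$W_d[v, ] * z) + layer$b_d[v])))
      recon <- recon + (X[i, v] - y)^2
    }
  }
  pen <- 0
  for (j in seq_len(h)) {
    rh <- mean(Z[, j])
    rh <- min(max(rh, 1e-6), 1 - 1e-6)
    pen <- pen + rho * log(rho / rh) + (1 - rho) * log((1 - rho) / (1 - rh))
  }
  recon / (2 * q) + alpha * pen
}

# Small deterministic fixtures ------------------------------------------------

tiny_config <- function(n_per_class = 3, seed = 7, noise_sd = "moderate") {
  counts <- rep(n_per_class, 9)
  names(counts) <- names(caresig::default_class_counts())
  caresig::generator_config(class_counts = counts, noise_sd = noise_sd,
                            seed = seed)
}

fast_control <- function(seed = 1L) {
  caresig::train_control(max_iters = 30, refine_iters = 60, seed = seed)
}

# FFT band power of a single channel between lo and hi Hz.
fft_band_power <- function(x, rate, lo, hi) {
  n <- length(x)
  sp <- abs(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * rate / n
  keep <- freqs >= lo & freqs <= hi & freqs <= rate / 2
  sum(sp[keep])
}
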