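test_that("sigmoid matches its closed form and symmetry", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(2), 0.880797077977882, tolerance = 1e-12)
  set.seed(1)
  a <- stats::rnorm(20, sd = 3)
  expect_equal(sigmoid(a) + sigmoid(-a), rep(1, 20), tolerance = 1e-12)
  expect_true(all(sigmoid(c(-1e4, 1e4)) >= 0 & sigmoid(c(-1e4, 1e4)) <= 1))
})

test_that("forward pass matches a hand computation and the zero-weight case", {
  l0 <- init_autoencoder(3, 2, seed = 1)
  l0$W_e[] <- 0; l0$W_d[] <- 0; l0$b_e[] <- 0; l0$b_d[] <- 0
  f <- ae_forward(l0, c(0.2, 0.9, 0.4))
  expect_equal(f$z, c(0.5, 0.5))
  expect_equal(f$y, c(0.5, 0.5, 0.5))
  # 2x2 hand-picked weights, two affine+sigmoid stages
  l <- l0
  l$W_e <- matrix(c(1, -1, 0.5, 2), 2, byrow = TRUE)
  l$b_e <- c(0.1, -0.2)
  l$W_d <- matrix(c(0.3, 0.7, -1, 0.2), 2, byrow = TRUE)
  l$b_d <- c(0, 0.5)
  n <- c(0.6, 0.8)
  z_hand <- 1 / (1 + exp(-(l$W_e %*% n + l$b_e)))
  y_hand <- 1 / (1 + exp(-(l$W_d %*% z_hand + l$b_d)))
  f2 <- ae_forward(l[1:4], n)
  expect_equal(f2$z, as.vector(z_hand))
  expect_equal(f2$y, as.vector(y_hand))
  expect_error(ae_forward(l, c(1, 2, 3)), "dimension")
})

test_that("KL penalty is zero at the target, matches Eq-style closed form, convex", {
  expect_equal(kl_penalty(0.05, 0.05), 0)
  expect_equal(kl_penalty(0.5, 0.25), 0.143841036225891, tolerance = 1e-9)
  grid <- seq(0.01, 0.99, by = 0.01)
  v <- kl_penalty(0.3, grid)
  expect_true(all(v >= 0))
  expect_equal(grid[which.min(v)], 0.3)        # unique interior minimum
  d2 <- diff(diff(v))
  expect_true(all(d2 > -1e-9))                 # discrete convexity
})

test_that("batched cost matches an independent scalar-loop oracle", {
  set.seed(4)
  for (rep in 1:5) {
    l <- init_autoencoder(4, 3, seed = rep)
    X <- matrix(stats::runif(3 * 4), 3)
    sp <- sparsity_config(alpha = stats::runif(1, 0, 2),
                          rho = stats::runif(1, 0.02, 0.5))
    got <- ae_cost(l, X, sp)
    want <- loop_ae_cost(l, X, sp$alpha, sp$rho)
    expect_equal(got$total, want, tolerance = 1e-12)
    expect_equal(got$total, got$reconstruction + got$sparsity)
  }
  # alpha = 0, single input, worked example ||n - y||^2 / 2
  l0 <- init_autoencoder(2, 1, seed = 1)
  l0$W_e[] <- 0; l0$W_d[] <- 0
  l0$b_e[] <- 0; l0$b_d <- c(-50, -50)       # y ~ (0, 0)
  got <- ae_cost(l0, matrix(c(1, 0), 1), sparsity_config(alpha = 0))
  expect_equal(got$reconstruction, 0.5, tolerance = 1e-6)
})

test_that("analytic gradients match central finite differences", {
  set.seed(5)
  for (rep in 1:6) {
    nv <- sample(2:6, 1)
    nh <- sample(2:4, 1)
    q <- sample(1:5, 1)
    l <- init_autoencoder(nv, nh, seed = 100 + rep)
    X <- matrix(stats::runif(q * nv), q)
    sp <- sparsity_config(alpha = stats::runif(1, 0, 3),
                          rho = stats::runif(1, 0.05, 0.4))
    ga <- ae_gradients(l, X, sp)
    ga <- c(ga$W_e, ga$W_d, ga$b_e, ga$b_d)
    pack <- c(l$W_e, l$W_d, l$b_e, l$b_d)
    unpack <- function(p) {
      l2 <- l
      i <- 0
      l2$W_e <- matrix(p[i + seq_along(l$W_e)], nh); i <- i + length(l$W_e)
      l2$W_d <- matrix(p[i + seq_along(l$W_d)], nv); i <- i + length(l$W_d)
      l2$b_e <- p[i + seq_len(nh)]; i <- i + nh
      l2$b_d <- p[i + seq_len(nv)]
      l2
    }
    gn <- numeric_gradient(function(p) ae_cost(unpack(p), X, sp)$total, pack)
    expect_lt(max_rel_err(ga, gn), 1e-6)
  }
})

test_that("alpha = 0 reduces gradients to the plain autoencoder", {
  l <- init_autoencoder(4, 2, seed = 9)
  X <- matrix(stats::runif(8), 2)
  g0 <- ae_gradients(l, X, sparsity_config(alpha = 0))
  g1 <- ae_gradients(l, X, sparsity_config(alpha = 2))
  # the decoder-side gradients carry no sparsity dependence
  expect_equal(g0$W_d, g1$W_d)
  expect_equal(g0$b_d, g1$b_d)
  expect_false(isTRUE(all.equal(g0$W_e, g1$W_e)))
})

test_that("training decreases cost monotonically and respects max_iters = 0", {
  set.seed(6)
  # 4-d inputs on a 2-d linear manifold
  B <- matrix(stats::runif(8), 4, 2)
  Z <- matrix(stats::runif(2 * 40), 40, 2)
  X <- Z %*% t(B)
  X <- (X - min(X)) / (max(X) - min(X))
  cfg0 <- train_control(max_iters = 0, seed = 3)
  l_init <- train_autoencoder(X, 2, sparsity_config(alpha = 0), cfg0)
  expect_equal(l_init[1:4],
               init_autoencoder(4, 2, seed = 3)[1:4])
  l <- train_autoencoder(X, 2, sparsity_config(alpha = 0),
                         train_control(learning_rate = 2, max_iters = 400,
                                       seed = 3))
  tr <- attr(l, "trace")
  expect_true(all(diff(tr) <= 1e-12))
  expect_lt(tr[length(tr)], 0.25 * tr[1])
})

test_that("training is deterministic for a fixed seed", {
  X <- matrix(stats::runif(60, 0, 1), 10)
  a <- train_autoencoder(X, 3, cfg = train_control(max_iters = 25, seed = 42))
  b <- train_autoencoder(X, 3, cfg = train_control(max_iters = 25, seed = 42))
  expect_identical(a[1:4], b[1:4])
})

test_that("a strong sparsity penalty drives mean hidden activity toward rho", {
  set.seed(7)
  X <- matrix(stats::runif(30 * 8), 30)
  l <- train_autoencoder(X, 5, sparsity_config(alpha = 10, rho = 0.05),
                         train_control(max_iters = 200, seed = 2))
  rho_hat <- mean(ae_encode(l, X))
  expect_gte(rho_hat, 0.01)
  expect_lte(rho_hat, 0.15)
})

test_that("greedy pretraining chains layers on the previous hidden output", {
  set.seed(8)
  X <- matrix(stats::runif(12 * 10), 12)
  cfg <- train_control(max_iters = 10, seed = 5)
  # base case: one layer equals train_autoencoder with the derived seed
  single <- pretrain_stack(X, 4, cfg = cfg)
  expect_length(single, 1)
  direct <- train_autoencoder(X, 4, sparsity_config(), cfg)
  expect_equal(single[[1]][1:4], direct[1:4])
  # stacked shapes and pipeline consistency
  stack <- pretrain_stack(X, c(4, 3, 2), cfg = cfg)
  expect_equal(dim(stack[[1]]$W_e), c(4, 10))
  expect_equal(dim(stack[[2]]$W_e), c(3, 4))
  expect_equal(dim(stack[[3]]$W_e), c(2, 3))
  h1 <- ae_encode(stack[[1]], X)
  expect_equal(stack_encode(stack[1:2], X), ae_encode(stack[[2]], h1))
})
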