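test_that("softmax probabilities: uniform at zero weights, shift-invariant, normalised", {
  th0 <- matrix(0, 9, 6)
  p <- softmax_probabilities(th0, stats::runif(5))
  expect_equal(p, rep(1 / 9, 9))
  set.seed(11)
  th <- matrix(stats::rnorm(3 * 5), 3)
  z <- stats::runif(4)
  p1 <- softmax_probabilities(th, z)
  p2 <- softmax_probabilities(th + matrix(stats::rnorm(5), 3, 5, byrow = TRUE),
                              z)
  expect_equal(p1, p2, tolerance = 1e-12)
  for (r in 1:20) {
    th <- matrix(stats::rnorm(4 * 7, sd = 5), 4)
    p <- softmax_probabilities(th, stats::rnorm(6, sd = 5))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("two-class probabilities equal the sigmoid of the score gap", {
  # scores 1 and 0 on the two classes
  th <- rbind(c(1, 0), c(0, 0))
  p <- softmax_probabilities(th, 0.5)   # biases 1 and 0, zero weight
  expect_equal(unname(p), c(0.731058578630005, 0.268941421369995),
               tolerance = 1e-12)
})

test_that("softmax cost is ln(k) at zero weights and has exact gradients", {
  set.seed(12)
  Z <- matrix(stats::runif(8 * 4), 8)
  L <- sample(1:3, 8, replace = TRUE)
  expect_equal(softmax_cost(matrix(0, 3, 5), Z, L, lambda = 0)$cost, log(3))
  for (rep in 1:5) {
    th <- matrix(stats::rnorm(3 * 5), 3)
    ga <- as.vector(softmax_cost(th, Z, L)$grad)
    gn <- numeric_gradient(function(p)
      softmax_cost(matrix(p, 3), Z, L)$cost, as.vector(th))
    expect_lt(max_rel_err(ga, gn), 1e-6)
  }
  expect_error(softmax_cost(matrix(0, 3, 5), Z, c(L[-1], 9)), "1..3")
})

test_that("architecture shapes follow the published layer sizes", {
  m_early <- build_model("early_fusion")
  expect_equal(dim(m_early$branches[[1]]$layers[[1]]$W_e), c(80, 280))
  m_eeg <- build_model("eeg")
  expect_equal(dim(m_eeg$branches[[1]]$layers[[1]]$W_e), c(80, 80))
  expect_length(m_eeg$branches[[1]]$layers, 3)
  m_late <- build_model("late_fusion")
  expect_length(m_late$branches, 2)
  expect_length(m_late$branches[[1]]$layers, 2)
  expect_equal(dim(m_late$joint[[1]]$W_e), c(160, 160))
  m_skel <- build_model("skeleton")
  expect_equal(dim(m_skel$branches[[1]]$layers[[1]]$W_e), c(80, 200))
  expect_equal(nrow(m_skel$head), 9)
})

test_that("prediction takes the argmax with ties to the lowest class index", {
  m <- build_model("skeleton", k = 3)
  m$classes <- c("a", "b", "c")
  m$scalers <- list(motion = fit_feature_scaler(matrix(stats::runif(400), 2)),
                    mental = fit_feature_scaler(matrix(stats::runif(160), 2)))
  m$trained <- TRUE
  # zero head: all probabilities tie at 1/3 -> first class
  mot <- stats::runif(200)
  men <- stats::runif(80)
  expect_equal(predict(m, mot, men), "a")
  p <- predict(m, mot, men, type = "prob")
  expect_equal(as.vector(p), rep(1 / 3, 3))
  # a clear winner is picked
  m$head[2, 1] <- 5
  expect_equal(predict(m, mot, men), "b")
})

test_that("linearly separable two-class features reach 100% after refinement", {
  set.seed(13)
  n <- 30
  motion <- matrix(stats::runif(2 * n * 200), 2 * n)
  motion[1:n, 1] <- motion[1:n, 1] * 0.3          # class gap on feature 1
  motion[(n + 1):(2 * n), 1] <- 0.7 + motion[(n + 1):(2 * n), 1] * 0.3
  mental <- matrix(stats::runif(2 * n * 80), 2 * n)
  labels <- rep(c("walking", "sleeping"), each = n)
  fit <- caresig(motion, mental, labels, "skeleton",
                 control = train_control(max_iters = 20, refine_iters = 80))
  expect_equal(mean(predict(fit, motion, mental) == labels), 1)
})

test_that("zero-iteration refinement equals the head-only model", {
  set.seed(14)
  ds <- generate_dataset(tiny_config(3, seed = 15))
  M <- motion_feature_matrix(ds)
  E <- mental_feature_matrix(ds)
  lab <- dataset_labels(ds)
  f0 <- caresig(M, E, lab, "eeg",
                control = train_control(max_iters = 10, refine_iters = 0))
  expect_equal(f0$loss$refine_initial, f0$loss$refine_final)
  # manual head-only model on the pretrained features predicts identically
  Xe <- apply_feature_scaler(E, f0$scalers$mental)
  top <- stack_encode(f0$branches[[1]]$layers, Xe)
  P <- softmax_probabilities(f0$head, top)
  manual <- f0$classes[max.col(P, ties.method = "first")]
  expect_identical(predict(f0, M, E), manual)
})

test_that("refinement reduces the supervised loss relative to pretrain-only", {
  drops <- c()
  for (s in 1:3) {
    ds <- generate_dataset(tiny_config(3, seed = 30 + s))
    fit <- caresig(motion_feature_matrix(ds), mental_feature_matrix(ds),
                   dataset_labels(ds), "late_fusion", control = fast_control())
    drops <- c(drops, fit$loss$refine_initial - fit$loss$refine_final)
    expect_lte(fit$loss$refine_final, fit$loss$refine_initial)
  }
  expect_gt(mean(drops), 0)
})

test_that("batch prediction equals record-by-record prediction", {
  ds <- generate_dataset(tiny_config(2, seed = 16))
  M <- motion_feature_matrix(ds)
  E <- mental_feature_matrix(ds)
  fit <- caresig(M, E, dataset_labels(ds), "late_fusion",
                 control = fast_control())
  batch <- predict(fit, M, E)
  single <- vapply(seq_len(nrow(M)), function(i)
    predict(fit, M[i, ], E[i, ]), character(1))
  expect_identical(batch, single)
})

test_that("refinement backpropagation gradients match finite differences", {
  set.seed(17)
  model <- build_model("late_fusion", n_motion = 6, n_mental = 4, k = 3,
                       seed = 2)
  # shrink the architecture for the check
  model$branches[[1]]$layers <- list(init_autoencoder(6, 3, 21))
  model$branches[[2]]$layers <- list(init_autoencoder(4, 3, 22))
  model$joint <- list(init_autoencoder(6, 4, 23))
  model$head <- matrix(stats::rnorm(3 * 5, sd = 0.2), 3)
  Xm <- matrix(stats::runif(5 * 6), 5)
  Xe <- matrix(stats::runif(5 * 4), 5)
  L <- c(1, 2, 3, 1, 2)
  par <- caresig:::flatten_params(model)
  got <- caresig:::refine_cost_grad(par, model, Xm, Xe, L)
  gn <- numeric_gradient(function(p)
    caresig:::refine_cost_grad(p, model, Xm, Xe, L)$cost, par)
  expect_lt(max_rel_err(got$grad, gn, floor = 1e-4), 1e-6)
})

test_that("a fitted model survives a JSON save/load round trip", {
  ds <- generate_dataset(tiny_config(2, seed = 18))
  M <- motion_feature_matrix(ds)
  E <- mental_feature_matrix(ds)
  fit <- caresig(M, E, dataset_labels(ds), "late_fusion",
                 control = fast_control())
  path <- tempfile(fileext = ".json")
  write_caresig(fit, path)
  back <- read_caresig(path)
  expect_identical(predict(back, M, E), predict(fit, M, E))
  expect_equal(predict(back, M, E, type = "prob"),
               predict(fit, M, E, type = "prob"), tolerance = 1e-12)
})
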