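session_fixture <- function(labels = c("drinking", "walking"), gap = 1,
                            seed = 31, noise = 0) {
  counts <- table(labels)
  cc <- stats::setNames(as.integer(counts), names(counts))
  generate_continuous_session(
    generator_config(class_counts = cc, noise_sd = noise, seed = seed),
    gap = gap)
}

test_that("framing enumerates window starts at the configured hop", {
  sess <- session_fixture()
  sess$duration <- 9                      # framing arithmetic only
  sess$records[[length(sess$records)]]$end <- 9
  frames <- frame_session(sess, frame_length = 3, shift_fraction = 0.5)
  expect_equal(attr(frames, "starts"), c(0, 1.5, 3, 4.5, 6))
  expect_length(frames, 5)
})

test_that("window starts match an independent enumeration for random durations", {
  set.seed(32)
  for (rep in 1:50) {
    dur <- stats::runif(1, 3, 40)
    L <- stats::runif(1, 1, 4)
    s <- stats::runif(1, 0.2, 1)
    step <- L * s
    want <- seq(0, dur - L + 1e-9, by = step)
    n_win <- floor((dur - L) / step + 1e-9) + 1
    expect_equal(n_win, length(want))
  }
  # a session exactly one frame long yields exactly one frame
  sess <- session_fixture(labels = "drinking", gap = 0)
  one <- frame_session(sess, frame_length = sess$duration)
  expect_length(one, 1)
  expect_error(frame_session(sess, frame_length = sess$duration + 1),
               "shorter")
})

test_that("frames carry the label of the majority activity", {
  sess <- session_fixture(labels = "drinking", gap = 3, seed = 33)
  # layout: 3 s nothing gap, then one drinking activity of 2-3 s
  frames <- frame_session(sess, frame_length = 3, shift_fraction = 0.5)
  starts <- attr(frames, "starts")
  labs <- dataset_labels(frames)
  expect_equal(labs[1], "nothing")        # fully inside the gap
  act <- sess$records[[2]]
  inside <- which(starts >= act$start - 1e-9 &
                    starts + 3 <= act$end + 1e-9)
  expect_true(all(labs[inside] == "drinking"))
  # majority rule: window covering > 50% activity is labelled with it
  cover <- pmax(0, pmin(starts + 3, act$end) - pmax(starts, act$start))
  expect_identical(labs == "drinking", cover > 1.5 + 1e-9)
})

test_that("framed records feed the feature extractors", {
  sess <- session_fixture(labels = c("drinking", "walking"), seed = 34,
                          noise = 0.02)
  frames <- frame_session(sess)
  M <- motion_feature_matrix(frames)
  E <- mental_feature_matrix(frames)
  expect_equal(ncol(M), 200)
  expect_equal(ncol(E), 80)
  expect_equal(nrow(M), length(frames))
})

test_that("metric report reproduces hand-computed P, macro-R and F1", {
  # perfect predictions
  perfect <- compute_metrics(c("a", "b", "a"), c("a", "b", "a"),
                             classes = c("a", "b"))
  expect_equal(perfect$P, 100)
  expect_equal(perfect$R, 100)
  expect_equal(perfect$F1, 100)
  # confusion [[8,2],[1,9]]
  truth <- c(rep("a", 10), rep("b", 10))
  pred <- c(rep("a", 8), rep("b", 2), "a", rep("b", 9))
  rep2 <- compute_metrics(pred, truth, classes = c("a", "b"))
  expect_equal(unclass(unname(rep2$confusion)),
               matrix(c(8, 1, 2, 9), 2), ignore_attr = TRUE)
  expect_equal(rep2$A_g, 17)
  expect_equal(rep2$A_n, 3)
  expect_equal(rep2$P, 85)
  expect_equal(rep2$R, 85)
  expect_equal(rep2$F1, 85)
  # all-one-class predictions on balanced 9-class truth
  classes <- names(default_class_counts())
  truth9 <- rep(classes, each = 4)
  pred9 <- rep(classes[1], length(truth9))
  rep3 <- compute_metrics(pred9, truth9, classes = classes)
  expect_equal(rep3$R, 100 / 9)
  expect_equal(rep3$P, 100 / 9)
  # N_g counts idle records recognised as activity
  rep4 <- compute_metrics(c("walking", "nothing"), c("nothing", "nothing"))
  expect_equal(rep4$N_g, 1)
  expect_error(compute_metrics("a", c("a", "b")), "equal length")
})

test_that("metrics from the confusion matrix equal metrics from raw pairs", {
  set.seed(35)
  classes <- letters[1:4]
  truth <- sample(classes, 200, replace = TRUE)
  pred <- ifelse(stats::runif(200) < 0.7, truth,
                 sample(classes, 200, replace = TRUE))
  r <- compute_metrics(pred, truth, classes = classes)
  expect_equal(r$P, 100 * mean(pred == truth))
  expect_equal(r$A_g + r$A_n, 200)
  expect_equal(r$F1, 2 * r$P * r$R / (r$P + r$R))
})

test_that("stratified folds partition the data with balanced class counts", {
  set.seed(36)
  labels <- rep(names(default_class_counts()), times = 12)
  cv_builder <- function(train_idx) {
    function(test_idx) rep(labels[train_idx][1], length(test_idx))
  }
  res <- cross_validate(labels, cv_builder, k_folds = 10, seed = 3)
  fold <- res$assignments
  expect_setequal(unique(fold), 1:10)
  # disjoint + exhaustive by construction of assignments; stratification +/-1
  for (cl in unique(labels)) {
    per_fold <- table(factor(fold[labels == cl], levels = 1:10))
    expect_lte(diff(range(per_fold)), 1)
  }
  expect_error(cross_validate(c("a", "a", "b"), cv_builder, k_folds = 2),
               "at least k_folds")
})

test_that("a constant-class predictor scores the class prevalence", {
  labels <- rep(c("walking", "sleeping", "nothing"), times = c(20, 30, 50))
  builder <- function(train_idx) function(test_idx)
    rep("nothing", length(test_idx))
  res <- cross_validate(labels, builder, k_folds = 10, seed = 4)
  expect_equal(res$pooled$P, 50)
  expect_equal(sum(res$pooled$confusion), 100)
})

test_that("held-out labels and features cannot influence training (no leakage)", {
  set.seed(37)
  ds <- generate_dataset(tiny_config(3, seed = 38))
  M <- motion_feature_matrix(ds)
  E <- mental_feature_matrix(ds)
  lab <- dataset_labels(ds)
  n <- length(lab)
  test_idx <- seq(1, n, by = 3)
  train_idx <- setdiff(seq_len(n), test_idx)
  fit1 <- caresig(M[train_idx, ], E[train_idx, ], lab[train_idx], "eeg",
                  control = fast_control())
  # corrupt the held-out records' labels and features: training untouched
  lab2 <- lab
  lab2[test_idx] <- "nothing"
  M2 <- M
  M2[test_idx, ] <- 0
  fit2 <- caresig(M2[train_idx, ], E[train_idx, ], lab2[train_idx], "eeg",
                  control = fast_control())
  expect_identical(fit1$head, fit2$head)
  expect_identical(fit1$branches, fit2$branches)
  expect_identical(fit1$scalers, fit2$scalers)
})

test_that("a model evaluates end-to-end on a continuous session", {
  ds <- generate_dataset(tiny_config(3, seed = 39))
  fit <- caresig(motion_feature_matrix(ds), mental_feature_matrix(ds),
                 dataset_labels(ds), "late_fusion", control = fast_control())
  sess <- session_fixture(labels = c("drinking", "walking"), seed = 40,
                          noise = 0.02)
  rep <- evaluate_session(fit, sess)
  expect_s3_class(rep, "eval_report")
  expect_true(rep$P >= 0 && rep$P <= 100)
  expect_equal(sum(rep$confusion), length(frame_session(sess)))
})
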