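#' Softmax class probabilities
#'
#' Multinomial logistic probabilities
#' `p(l = j | z) = exp(theta_j' z) / sum_i exp(theta_i' z)`, computed with
#' max-subtraction so large scores cannot overflow.
#'
#' @param theta Weight matrix, one row per class; first column is the bias.
#' @param z Feature vector, or matrix with one vector per row.
#' @return Probability vector (or row-matrix), each summing to 1.
#' @export
softmax_probabilities <- function(theta, z) {
  vec <- is.null(dim(z))
  Z <- if (vec) matrix(z, 1) else as.matrix(z)
  if (ncol(Z) + 1L != ncol(theta))
    stop("feature dimension does not match the head")
  S <- tcrossprod(cbind(1, Z), theta)
  S <- S - apply(S, 1, max)
  E <- exp(S)
  P <- E / rowSums(E)
  if (vec) drop(P) else P
}

#' Softmax cross-entropy cost and gradient
#'
#' Mean negative log-likelihood of the true labels under
#' [softmax_probabilities()], plus a small L2 penalty `lambda/2 * ||W||^2`
#' on the non-bias weights for identifiability under separable data. The
#' gradient is analytic.
#'
#' @param theta Head weight matrix (classes x (features + 1)).
#' @param Z Representation matrix, one record per row.
#' @param L Integer labels in `1..k`.
#' @param lambda L2 penalty weight on the non-bias entries.
#' @return List with `cost` (scalar) and `grad` (same shape as `theta`).
#' @export
softmax_cost <- function(theta, Z, L, lambda = 1e-4) {
  Z <- as.matrix(Z)
  q <- nrow(Z)
  k <- nrow(theta)
  L <- as.integer(L)
  if (length(L) != q) stop("labels and representations differ in length")
  if (any(L < 1L | L > k)) stop("label outside 1..", k)
  P <- softmax_probabilities(theta, Z)
  if (q == 1) P <- matrix(P, 1)
  W0 <- theta
  W0[, 1] <- 0
  cost <- -mean(log(pmax(P[cbind(seq_len(q), L)], 1e-300))) +
    lambda / 2 * sum(W0^2)
  Yh <- matrix(0, q, k)
  Yh[cbind(seq_len(q), L)] <- 1
  G <- crossprod(P - Yh, cbind(1, Z)) / q + lambda * W0
  list(cost = cost, grad = G)
}

# Head-only training: L-BFGS from a zero start (deterministic).
train_softmax_head <- function(Z, L, k, lambda = 1e-4, maxit = 200) {
  d <- ncol(Z)
  fn <- function(p) softmax_cost(matrix(p, k), Z, L, lambda)$cost
  gr <- function(p) as.vector(softmax_cost(matrix(p, k), Z, L, lambda)$grad)
  opt <- stats::optim(numeric(k * (d + 1)), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  matrix(opt$par, k)
}

#' Architecture specification
#'
#' The four model layouts:
#' \describe{
#'   \item{skeleton}{single-modal: motion input (200) -> three hidden layers
#'     of 80 -> softmax.}
#'   \item{eeg}{single-modal: mental input (80) -> three hidden layers of 80
#'     -> softmax.}
#'   \item{early_fusion}{the two inputs concatenated (280) before the first
#'     layer -> three hidden layers of 80 -> softmax ("skeleton-EEG").}
#'   \item{late_fusion}{each modality pretrained in its own two-layer branch
#'     (80, 80), the branch tops concatenated into a joint third hidden
#'     layer of 160 -> softmax ("integrated").}
#' }
#'
#' @param kind One of `"skeleton"`, `"eeg"`, `"early_fusion"`,
#'   `"late_fusion"`.
#' @return An `architecture_spec`: list of branch definitions (input stream
#'   and hidden sizes) plus joint-layer sizes.
#' @export
architecture_spec <- function(kind = c("late_fusion", "early_fusion",
                                       "skeleton", "eeg")) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    skeleton = list(branches = list(list(input = "motion",
                                         sizes = c(80, 80, 80))),
                    joint = integer(0)),
    eeg = list(branches = list(list(input = "mental",
                                    sizes = c(80, 80, 80))),
               joint = integer(0)),
    early_fusion = list(branches = list(list(input = "both",
                                             sizes = c(80, 80, 80))),
                        joint = integer(0)),
    late_fusion = list(branches = list(list(input = "motion",
                                            sizes = c(80, 80)),
                                       list(input = "mental",
                                            sizes = c(80, 80))),
                       joint = 160L))
  structure(c(list(kind = kind), spec), class = "architecture_spec")
}

branch_input <- function(branch, motion, mental) {
  switch(branch$input,
         motion = motion,
         mental = mental,
         both = cbind(motion, mental))
}

#' Build an untrained model
#'
#' Instantiates the layers of an architecture with seeded random weights and
#' a zero softmax head, without any training; mainly useful for inspecting
#' shapes and as the starting point of [caresig()].
#'
#' @param architecture An [architecture_spec()] or its `kind` string.
#' @param n_motion,n_mental Input dimensions (defaults 200 and 80).
#' @param k Number of classes.
#' @param seed Integer seed.
#' @return An untrained `caresig` model object.
#' @export
build_model <- function(architecture = "late_fusion", n_motion = 200,
                        n_mental = 80, k = 9, seed = 1L) {
  if (!inherits(architecture, "architecture_spec"))
    architecture <- architecture_spec(architecture)
  dims <- c(motion = n_motion, mental = n_mental,
            both = n_motion + n_mental)
  branches <- lapply(seq_along(architecture$branches), function(i) {
    br <- architecture$branches[[i]]
    n_in <- dims[[br$input]]
    layers <- vector("list", length(br$sizes))
    for (j in seq_along(br$sizes)) {
      layers[[j]] <- init_autoencoder(n_in, br$sizes[j],
                                      seed = seed + 10L * i + j)
      n_in <- br$sizes[j]
    }
    list(input = br$input, layers = layers)
  })
  top_w <- sum(vapply(architecture$branches,
                      function(br) br$sizes[length(br$sizes)], numeric(1)))
  joint <- list()
  n_in <- top_w
  for (j in seq_along(architecture$joint)) {
    joint[[j]] <- init_autoencoder(n_in, architecture$joint[j],
                                   seed = seed + 100L + j)
    n_in <- architecture$joint[j]
  }
  structure(list(architecture = architecture, branches = branches,
                 joint = joint, head = matrix(0, k, n_in + 1),
                 classes = NULL, scalers = NULL, trained = FALSE),
            class = "caresig")
}

# Encode scaled inputs to the top representation (branches + joint layers).
model_top <- function(model, motion, mental) {
  tops <- lapply(model$branches, function(br)
    stack_encode(br$layers, branch_input(br, motion, mental)))
  top <- do.call(cbind, tops)
  for (l in model$joint) top <- ae_encode(l, top)
  top
}

#' Fit a multimodal help-requirement classifier
#'
#' The package's central fitting function. Training has two stages:
#' \enumerate{
#'   \item unsupervised greedy layer-wise pretraining of every stacked
#'     sparse-autoencoder branch ([pretrain_stack()]) on the min-max-scaled
#'     features;
#'   \item supervised refinement: a softmax head is fitted on the top
#'     representation, then the cross-entropy loss is minimised by
#'     backpropagation through all encoder layers and the head (decoders are
#'     frozen after pretraining; they are unused at prediction time).
#' }
#' Feature scalers are fitted on the supplied (training) data only and
#' stored in the model, so held-out records are scaled without leakage.
#'
#' @param motion Numeric matrix of raw motion features, one 200-dimensional
#'   row per record (see [motion_feature_matrix()]).
#' @param mental Numeric matrix of raw mental features, one 80-dimensional
#'   row per record.
#' @param labels Character or factor record labels.
#' @param architecture Architecture kind, see [architecture_spec()].
#' @param sparsity A [sparsity_config()].
#' @param control A [train_control()].
#' @return A fitted object of class `caresig` with components
#'   `architecture`, `branches`, `joint`, `head`, `classes`, `scalers` and
#'   `loss` (pretraining traces and supervised losses before/after
#'   refinement).
#' @seealso [predict.caresig()], [cross_validate()]
#' @examples
#' cfg <- scaled_config(60, noise_sd = "moderate", seed = 7)
#' ds <- generate_dataset(cfg)
#' fit <- caresig(motion_feature_matrix(ds), mental_feature_matrix(ds),
#'                dataset_labels(ds), architecture = "late_fusion",
#'                control = train_control(max_iters = 30, refine_iters = 40))
#' table(predict(fit, motion_feature_matrix(ds), mental_feature_matrix(ds)),
#'       dataset_labels(ds))
#' @export
caresig <- function(motion, mental, labels,
                    architecture = c("late_fusion", "early_fusion",
                                     "skeleton", "eeg"),
                    sparsity = sparsity_config(),
                    control = train_control()) {
  arch <- architecture_spec(match.arg(architecture))
  if (is.factor(labels)) {
    classes <- levels(labels)
  } else {
    known <- names(activity_classes())
    u <- unique(labels)
    classes <- if (all(u %in% known)) known[known %in% u] else sort(u)
  }
  L <- match(as.character(labels), classes)
  stopifnot(!anyNA(L))
  k <- length(classes)
  motion <- as.matrix(motion)
  mental <- as.matrix(mental)
  stopifnot(nrow(motion) == length(L), nrow(mental) == length(L))

  scalers <- list(motion = fit_feature_scaler(motion),
                  mental = fit_feature_scaler(mental))
  Xm <- apply_feature_scaler(motion, scalers$motion)
  Xe <- apply_feature_scaler(mental, scalers$mental)

  # stage 1: greedy unsupervised pretraining, per branch then joint
  branches <- vector("list", length(arch$branches))
  traces <- list()
  for (i in seq_along(arch$branches)) {
    br <- arch$branches[[i]]
    cfg_i <- control
    cfg_i$seed <- as.integer((control$seed + 1000L * i) %% .Machine$integer.max)
    layers <- pretrain_stack(branch_input(br, Xm, Xe), br$sizes, sparsity,
                             cfg_i)
    traces[[paste0("branch", i)]] <-
      lapply(layers, function(l) attr(l, "trace"))
    branches[[i]] <- list(input = br$input, layers = layers)
  }
  tops <- lapply(branches, function(br)
    stack_encode(br$layers, branch_input(br, Xm, Xe)))
  top <- do.call(cbind, tops)
  joint <- list()
  if (length(arch$joint)) {
    cfg_j <- control
    cfg_j$seed <- as.integer((control$seed + 9000L) %% .Machine$integer.max)
    joint <- pretrain_stack(top, arch$joint, sparsity, cfg_j)
    traces$joint <- lapply(joint, function(l) attr(l, "trace"))
    top <- stack_encode(joint, top)
  }

  # stage 2: softmax head, then backpropagation through encoders + head
  head <- train_softmax_head(top, L, k)
  model <- structure(list(architecture = arch, branches = branches,
                          joint = joint, head = head, classes = classes,
                          scalers = scalers, sparsity = sparsity,
                          control = control, trained = TRUE),
                     class = "caresig")
  loss_before <- softmax_cost(head, top, L)$cost
  loss_after <- loss_before
  if (control$refine_iters > 0) {
    model <- refine_model(model, Xm, Xe, L, maxit = control$refine_iters)
    loss_after <- softmax_cost(model$head, model_top(model, Xm, Xe), L)$cost
  }
  model$loss <- list(pretrain = traces, refine_initial = loss_before,
                     refine_final = loss_after)
  model$call <- match.call()
  model
}

#' Predict help-requirement classes
#'
#' Scales the raw feature rows with the model's stored training scalers,
#' encodes them through the model and applies the softmax head. The
#' predicted label is the class with the highest probability; exact ties go
#' to the lowest class index.
#'
#' @param object A fitted `caresig` model.
#' @param motion,mental Raw feature matrices (rows are records) or single
#'   vectors.
#' @param type `"class"` for labels, `"prob"` for the probability matrix.
#' @param ... Unused.
#' @return Character vector of labels, or a records x classes probability
#'   matrix.
#' @export
predict.caresig <- function(object, motion, mental, type = c("class", "prob"),
                            ...) {
  type <- match.arg(type)
  if (!isTRUE(object$trained)) stop("model has not been fitted")
  if (is.null(dim(motion))) motion <- rbind(motion)
  if (is.null(dim(mental))) mental <- rbind(mental)
  Xm <- apply_feature_scaler(motion, object$scalers$motion)
  Xe <- apply_feature_scaler(mental, object$scalers$mental)
  P <- softmax_probabilities(object$head, model_top(object, Xm, Xe))
  if (is.null(dim(P))) P <- matrix(P, 1)
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  object$classes[max.col(P, ties.method = "first")]
}

#' @export
print.caresig <- function(x, ...) {
  cat("Multimodal SAE help-requirement classifier\n")
  cat("  architecture:", x$architecture$kind, "\n")
  for (br in x$branches)
    cat(sprintf("  branch [%s]: %s\n", br$input,
                paste(vapply(br$layers, function(l) nrow(l$W_e), numeric(1)),
                      collapse = " -> ")))
  if (length(x$joint))
    cat("  joint layer:",
        paste(vapply(x$joint, function(l) nrow(l$W_e), numeric(1)),
              collapse = " -> "), "\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  if (isTRUE(x$trained) && !is.null(x$loss))
    cat(sprintf("  supervised loss: %.4f (head) -> %.4f (refined)\n",
                x$loss$refine_initial, x$loss$refine_final))
  invisible(x)
}

#' @export
summary.caresig <- function(object, ...) {
  np <- sum(vapply(object$branches, function(br)
    sum(vapply(br$layers, function(l) length(l$W_e) + length(l$b_e),
               numeric(1))), numeric(1))) +
    sum(vapply(object$joint, function(l) length(l$W_e) + length(l$b_e),
               numeric(1))) + length(object$head)
  structure(list(model = object, n_encoder_params = np), class = "summary.caresig")
}

#' @export
print.summary.caresig <- function(x, ...) {
  print(x$model)
  cat("  trainable parameters (encoders + head):", x$n_encoder_params, "\n")
  if (!is.null(x$model$loss$pretrain)) {
    cat("  pretraining reconstruction+sparsity cost per layer (start -> end):\n")
    for (nm in names(x$model$loss$pretrain)) {
      tr <- x$model$loss$pretrain[[nm]]
      for (i in seq_along(tr))
        cat(sprintf("    %s layer %d: %.4f -> %.4f\n", nm, i,
                    tr[[i]][1], tr[[i]][length(tr[[i]])]))
    }
  }
  invisible(x)
}

#' @export
coef.caresig <- function(object, ...) {
  list(branches = lapply(object$branches, function(br)
         lapply(br$layers, function(l) l[c("W_e", "b_e")])),
       joint = lapply(object$joint, function(l) l[c("W_e", "b_e")]),
       head = object$head)
}

#' Plot pretraining cost traces
#'
#' One line per stacked layer: the accepted (non-increasing) autoencoder
#' cost over pretraining iterations.
#'
#' @param x A fitted `caresig` model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.caresig <- function(x, ...) {
  if (is.null(x$loss$pretrain)) stop("no training traces stored")
  tr <- unlist(x$loss$pretrain, recursive = FALSE)
  len <- max(vapply(tr, length, numeric(1)))
  M <- sapply(tr, function(v) c(v, rep(NA, len - length(v))))
  graphics::matplot(M, type = "l", lty = 1, xlab = "iteration",
                    ylab = "autoencoder cost",
                    main = paste("Pretraining,", x$architecture$kind), ...)
  invisible(x)
}
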