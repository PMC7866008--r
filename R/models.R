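#' Declarative description of a 1D-CNN
#'
#' Every architecture is a stack of same-padded stride-1 convolution blocks —
#' each one convolution, rectifier activation, optional batch normalization,
#' then length-2 max pooling with floor division — followed by flattening,
#' fully connected hidden layers with rectifier activations, and a 2-class
#' softmax output. Dropout sits after the last convolution block and after
#' the first fully connected layer.
#'
#' @param name Identifier.
#' @param input_length Length of the normalized pulse the network consumes.
#' @param conv_blocks List of `c(out_channels, kernel_length)` pairs; kernel
#'   lengths must be odd so that same padding is symmetric.
#' @param fc_widths Hidden fully connected widths.
#' @param n_classes Number of output classes (2).
#' @param batch_norm Logical: batch normalization after each conv activation.
#' @param dropout_conv,dropout_fc Dropout probabilities at the two placements.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(name, input_length, conv_blocks, fc_widths,
                              n_classes = 2L, batch_norm = FALSE,
                              dropout_conv = 0.5, dropout_fc = 0.5) {
  stopifnot(n_classes == 2L, input_length >= 2, length(conv_blocks) >= 1)
  len <- as.integer(input_length)
  for (blk in conv_blocks) {
    stopifnot(length(blk) == 2, blk[1] >= 1, blk[2] >= 1)
    if (blk[2] %% 2 != 1) stop("kernel lengths must be odd")
    len <- len %/% 2L
    if (len < 1) stop("pooled length fell below 1")
  }
  structure(list(name = name, input_length = as.integer(input_length),
                 conv_blocks = lapply(conv_blocks, as.integer),
                 fc_widths = as.integer(fc_widths),
                 n_classes = as.integer(n_classes),
                 batch_norm = isTRUE(batch_norm),
                 dropout_conv = dropout_conv, dropout_fc = dropout_fc),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  convs <- vapply(x$conv_blocks, function(b)
    sprintf("%dxk%d", b[1], b[2]), character(1))
  cat(sprintf("<architecture_spec> %s: input %d | conv %s | fc %s | %d classes%s\n",
              x$name, x$input_length, paste(convs, collapse = " -> "),
              paste(x$fc_widths, collapse = ", "), x$n_classes,
              if (x$batch_norm) " | batch-norm" else ""))
  invisible(x)
}

# pooled length after all conv blocks, and the flatten width
flatten_length <- function(spec) {
  len <- spec$input_length
  for (blk in spec$conv_blocks) len <- len %/% 2L
  len * spec$conv_blocks[[length(spec$conv_blocks)]][1]
}

#' Build a named 1D-CNN architecture
#'
#' Fixed architectures used throughout the package:
#' \describe{
#'   \item{lenet5_1d}{input 70; convs (32,k5), (64,k5); FC 128, 64; the
#'     LeNet5 adaptation (flatten 64 x 17 = 1088). Batch norm off by default
#'     so its parameter count is 158,274.}
#'   \item{cpcnn4}{input 72; convs (32,k7), (64,k5), (128,k3); FC 128, 64;
#'     flatten 128 x 9 = 1152; 191,234 parameters without batch norm.}
#'   \item{cpcnn5}{input 72; convs (32,k11), (64,k7), (128,k5), (196,k3);
#'     FC 128, 64; flatten 196 x 4 = 784.}
#'   \item{alexnet_1d}{input 72; convs (32,k11), (64,k5), (128,k3), (256,k3);
#'     FC 1024, 128.}
#' }
#'
#' @param name One of `"lenet5_1d"`, `"cpcnn4"`, `"cpcnn5"`, `"alexnet_1d"`.
#' @param batch_norm Override the default batch-norm flag (`NULL` keeps the
#'   default: off for lenet5_1d, on for the others).
#' @return An [architecture_spec()].
#' @export
build_architecture <- function(name, batch_norm = NULL) {
  defs <- list(
    lenet5_1d = list(input = 70L, conv = list(c(32, 5), c(64, 5)),
                     fc = c(128L, 64L), bn = FALSE, dc = 0),
    cpcnn4 = list(input = 72L, conv = list(c(32, 7), c(64, 5), c(128, 3)),
                  fc = c(128L, 64L), bn = TRUE, dc = 0.5),
    cpcnn5 = list(input = 72L,
                  conv = list(c(32, 11), c(64, 7), c(128, 5), c(196, 3)),
                  fc = c(128L, 64L), bn = TRUE, dc = 0.5),
    alexnet_1d = list(input = 72L,
                      conv = list(c(32, 11), c(64, 5), c(128, 3), c(256, 3)),
                      fc = c(1024L, 128L), bn = TRUE, dc = 0.5))
  if (!name %in% names(defs))
    stop(sprintf("unknown architecture '%s'; choose one of %s", name,
                 paste(names(defs), collapse = ", ")))
  d <- defs[[name]]
  architecture_spec(name, d$input, d$conv, d$fc,
                    batch_norm = if (is.null(batch_norm)) d$bn else batch_norm,
                    dropout_conv = d$dc, dropout_fc = 0.5)
}

#' Closed-form trainable parameter count
#'
#' Each convolution contributes `out_ch * (in_ch * kernel + 1)` weights and
#' biases, each fully connected layer `out * (in + 1)`, and batch
#' normalization `2 * channels` per flagged block. Equals the number of
#' trainable scalars in a materialized model.
#'
#' @param spec An [architecture_spec()].
#' @param include_batch_norm Count batch-norm scales/shifts; defaults to the
#'   spec's own flag.
#' @return Integer count.
#' @export
count_parameters <- function(spec, include_batch_norm = NULL) {
  stopifnot(inherits(spec, "architecture_spec"))
  if (is.null(include_batch_norm)) include_batch_norm <- spec$batch_norm
  total <- 0
  in_ch <- 1L
  for (blk in spec$conv_blocks) {
    total <- total + blk[1] * (in_ch * blk[2] + 1)
    if (include_batch_norm) total <- total + 2 * blk[1]
    in_ch <- blk[1]
  }
  widths <- c(flatten_length(spec), spec$fc_widths, spec$n_classes)
  for (j in seq_len(length(widths) - 1))
    total <- total + widths[j + 1] * (widths[j] + 1)
  as.integer(total)
}

#' Materialize a model from an architecture spec
#'
#' He-initialized weights, zero biases, unit batch-norm scales. Consumes the
#' R random number stream (seed it for reproducibility).
#'
#' @param spec An [architecture_spec()].
#' @return An object of class `ccdnet_model` with flat named parameter and
#'   running-statistics lists.
#' @export
init_model <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  params <- list()
  running <- list()
  in_ch <- 1L
  for (i in seq_along(spec$conv_blocks)) {
    blk <- spec$conv_blocks[[i]]
    fan_in <- in_ch * blk[2]
    params[[sprintf("conv%d.W", i)]] <-
      matrix(rnorm(fan_in * blk[1], 0, sqrt(2 / fan_in)), fan_in, blk[1])
    params[[sprintf("conv%d.b", i)]] <- numeric(blk[1])
    if (spec$batch_norm) {
      params[[sprintf("conv%d.gamma", i)]] <- rep(1, blk[1])
      params[[sprintf("conv%d.beta", i)]] <- numeric(blk[1])
      running[[sprintf("conv%d", i)]] <- list(mean = numeric(blk[1]),
                                              var = rep(1, blk[1]))
    }
    in_ch <- blk[1]
  }
  widths <- c(flatten_length(spec), spec$fc_widths, spec$n_classes)
  for (j in seq_len(length(widths) - 1)) {
    fan_in <- widths[j]
    params[[sprintf("fc%d.W", j)]] <-
      matrix(rnorm(fan_in * widths[j + 1], 0, sqrt(2 / fan_in)),
             fan_in, widths[j + 1])
    params[[sprintf("fc%d.b", j)]] <- numeric(widths[j + 1])
  }
  structure(list(spec = spec, params = params, running = running,
                 history = NULL),
            class = "ccdnet_model")
}

#' @export
print.ccdnet_model <- function(x, ...) {
  cat(sprintf("<ccdnet_model> %s, %d trainable parameters%s\n", x$spec$name,
              n_trainable(x),
              if (is.null(x$history)) " (untrained)" else " (trained)"))
  invisible(x)
}

#' Number of trainable scalars in a materialized model
#' @param model A `ccdnet_model`.
#' @return Integer count.
#' @export
n_trainable <- function(model) {
  as.integer(sum(vapply(model$params, length, numeric(1))))
}

# full forward pass; returns probabilities plus caches for backprop and
# the post-pool feature maps of every conv block
nn_forward <- function(model, X, training = FALSE, keep_cache = FALSE) {
  spec <- model$spec
  if (ncol(X) != spec$input_length)
    stop(sprintf("batch width %d does not match input_length %d",
                 ncol(X), spec$input_length))
  A <- array(X, c(nrow(X), ncol(X), 1L))
  caches <- list()
  features <- list()
  nb <- length(spec$conv_blocks)
  for (i in seq_len(nb)) {
    blk <- spec$conv_blocks[[i]]
    cv <- conv_forward(A, model$params[[sprintf("conv%d.W", i)]],
                       model$params[[sprintf("conv%d.b", i)]], blk[2])
    rl <- relu_forward(cv$out)
    A <- rl$out
    bn <- NULL
    if (spec$batch_norm) {
      bn <- bn_forward(A, model$params[[sprintf("conv%d.gamma", i)]],
                       model$params[[sprintf("conv%d.beta", i)]],
                       model$running[[sprintf("conv%d", i)]], training)
      A <- bn$out
      model$running[[sprintf("conv%d", i)]] <- bn$running
    }
    pl <- pool_forward(A)
    A <- pl$out
    dp <- NULL
    if (i == nb) {
      dp <- dropout_forward(A, spec$dropout_conv, training)
      A <- dp$out
    }
    features[[i]] <- A
    if (keep_cache)
      caches[[i]] <- list(conv = cv, relu = rl, bn = bn, pool = pl,
                          dropout = dp)
  }
  Xf <- matrix(A, dim(A)[1], dim(A)[2] * dim(A)[3])
  conv_out_dims <- dim(A)
  fc_caches <- list()
  nf <- length(spec$fc_widths) + 1L
  H <- Xf
  for (j in seq_len(nf)) {
    fc <- fc_forward(H, model$params[[sprintf("fc%d.W", j)]],
                     model$params[[sprintf("fc%d.b", j)]])
    if (j < nf) {
      rl <- relu_forward(fc$out)
      H <- rl$out
      dp <- NULL
      if (j == 1L) {
        dp <- dropout_forward(H, spec$dropout_fc, training)
        H <- dp$out
      }
      if (keep_cache) fc_caches[[j]] <- list(fc = fc, relu = rl, dropout = dp)
    } else {
      H <- fc$out
      if (keep_cache) fc_caches[[j]] <- list(fc = fc)
    }
  }
  probs <- softmax_rows(H)
  list(probs = probs, logits = H, features = features, model = model,
       caches = if (keep_cache) list(conv = caches, fc = fc_caches,
                                     conv_out_dims = conv_out_dims))
}

# gradient of mean cross-entropy w.r.t. every parameter
nn_backward <- function(model, fwd, labels) {
  spec <- model$spec
  n <- nrow(fwd$probs)
  Y <- matrix(0, n, 2)
  Y[cbind(seq_len(n), labels + 1L)] <- 1
  dZ <- (fwd$probs - Y) / n
  grads <- list()
  nf <- length(spec$fc_widths) + 1L
  for (j in rev(seq_len(nf))) {
    cc <- fwd$caches$fc[[j]]
    bk <- fc_backward(dZ, cc$fc, model$params[[sprintf("fc%d.W", j)]])
    grads[[sprintf("fc%d.W", j)]] <- bk$dW
    grads[[sprintf("fc%d.b", j)]] <- bk$db
    dZ <- bk$dX
    if (j > 1L) {
      cp <- fwd$caches$fc[[j - 1L]]
      if (!is.null(cp$dropout)) dZ <- dropout_backward(dZ, cp$dropout)
      dZ <- relu_backward(dZ, cp$relu)
    }
  }
  dA <- array(dZ, fwd$caches$conv_out_dims)
  nb <- length(spec$conv_blocks)
  for (i in rev(seq_len(nb))) {
    cc <- fwd$caches$conv[[i]]
    if (!is.null(cc$dropout)) dA <- dropout_backward(dA, cc$dropout)
    dA <- pool_backward(dA, cc$pool)
    if (spec$batch_norm) {
      bb <- bn_backward(dA, cc$bn$cache)
      grads[[sprintf("conv%d.gamma", i)]] <- bb$dgamma
      grads[[sprintf("conv%d.beta", i)]] <- bb$dbeta
      dA <- bb$dA
    }
    dA <- relu_backward(dA, cc$relu)
    bk <- conv_backward(dA, cc$conv, model$params[[sprintf("conv%d.W", i)]],
                        spec$conv_blocks[[i]][2])
    grads[[sprintf("conv%d.W", i)]] <- bk$dW
    grads[[sprintf("conv%d.b", i)]] <- bk$db
    dA <- bk$dA
  }
  grads
}

#' Forward pass: per-class probabilities
#'
#' @param model A `ccdnet_model`.
#' @param batch Numeric matrix, one normalized pulse per row, or a
#'   [pulse_set()].
#' @return N x 2 matrix of class probabilities (columns: class 0, class 1);
#'   rows sum to 1.
#' @export
model_forward <- function(model, batch) {
  if (inherits(batch, "pulse_set")) batch <- batch$values
  if (is.null(dim(batch))) batch <- matrix(batch, 1)
  nn_forward(model, batch, training = FALSE)$probs
}

#' Binary cross-entropy loss
#'
#' Mean over the batch of `-[y log p + (1 - y) log(1 - p)]`, where `p` is the
#' probability assigned to class 1. Probabilities are clamped away from 0 and
#' 1 by a small epsilon.
#'
#' @param probabilities N x 2 probability matrix (class-1 probabilities in
#'   column 2) or a vector of class-1 probabilities.
#' @param labels Integer 0/1 labels.
#' @return Scalar loss.
#' @export
cross_entropy <- function(probabilities, labels) {
  p1 <- if (is.matrix(probabilities)) probabilities[, 2] else probabilities
  stopifnot(length(p1) == length(labels), all(labels %in% c(0, 1)))
  eps <- 1e-12
  clamped <- p1 <= 0 | p1 >= 1
  if (any(clamped & (labels == (p1 <= 0))))
    warning("saturated probabilities clamped by epsilon")
  p1 <- pmin(pmax(p1, eps), 1 - eps)
  -mean(labels * log(p1) + (1 - labels) * log(1 - p1))
}

#' Training configuration
#'
#' @param batch_size Mini-batch size (default 40).
#' @param iterations Number of mini-batch updates.
#' @param learning_rate Step size of the adaptive-moment optimizer.
#' @param seed Integer seed covering initialization, batch order and dropout.
#' @param optimizer Only `"adam"` is provided.
#' @param eval_every Record validation accuracy every this many iterations.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 40, iterations = 300,
                         learning_rate = 1e-3, seed = 1L,
                         optimizer = "adam", eval_every = 25) {
  stopifnot(batch_size >= 1, iterations >= 1, learning_rate > 0)
  optimizer <- match.arg(optimizer)
  structure(list(batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 optimizer = optimizer, eval_every = as.integer(eval_every)),
            class = "train_config")
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train a 1D-CNN on labelled pulses
#'
#' Minimizes the cross-entropy by mini-batch gradient descent with the
#' adaptive-moment optimizer. Fully reproducible given `config$seed`.
#'
#' @param spec An [architecture_spec()] (or an architecture name).
#' @param train_set,val_set [pulse_set()]s with labels (`val_set` optional).
#' @param config A [train_config()].
#' @return A trained `ccdnet_model`; `$history` holds the per-iteration loss
#'   and periodic validation accuracy.
#' @export
train_model <- function(spec, train_set, val_set = NULL,
                        config = train_config()) {
  if (is.character(spec)) spec <- build_architecture(spec)
  stopifnot(inherits(spec, "architecture_spec"),
            inherits(train_set, "pulse_set"), !is.null(train_set$label))
  if (length(unique(train_set$label)) < 2)
    stop("training set must contain both classes")
  X <- train_set$values
  y <- train_set$label
  set.seed(config$seed)
  model <- init_model(spec)
  state <- list(m = lapply(model$params, function(p) p * 0),
                v = lapply(model$params, function(p) p * 0))
  n <- nrow(X)
  hist_iter <- integer(0); hist_loss <- numeric(0)
  hist_val_iter <- integer(0); hist_val_acc <- numeric(0)
  order <- integer(0)
  for (t in seq_len(config$iterations)) {
    if (length(order) < config$batch_size) order <- sample.int(n)
    take <- head(order, config$batch_size)
    order <- tail(order, -config$batch_size)
    fwd <- nn_forward(model, X[take, , drop = FALSE], training = TRUE,
                      keep_cache = TRUE)
    model$running <- fwd$model$running
    loss <- cross_entropy(fwd$probs, y[take])
    if (!is.finite(loss))
      stop(sprintf("training diverged at iteration %d (loss %g)", t, loss))
    grads <- nn_backward(model, fwd, y[take])
    upd <- adam_step(model$params, grads, state, config$learning_rate, t)
    model$params <- upd$params
    state <- upd$state
    hist_iter <- c(hist_iter, t); hist_loss <- c(hist_loss, loss)
    if (!is.null(val_set) &&
        (t %% config$eval_every == 0 || t == config$iterations)) {
      acc <- mean(classify_pulses(model, val_set) == val_set$label)
      hist_val_iter <- c(hist_val_iter, t)
      hist_val_acc <- c(hist_val_acc, acc)
    }
  }
  model$history <- list(
    loss = data.frame(iteration = hist_iter, loss = hist_loss),
    validation = if (length(hist_val_iter))
      data.frame(iteration = hist_val_iter, accuracy = hist_val_acc))
  model
}

#' Hard 0/1 predictions for a set of pulses
#'
#' @param model A trained `ccdnet_model`.
#' @param pulses A [pulse_set()] or matrix of normalized pulses.
#' @return Integer vector of predicted labels (1 = correct depth).
#' @export
classify_pulses <- function(model, pulses) {
  as.integer(model_forward(model, pulses)[, 2] >= 0.5)
}
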