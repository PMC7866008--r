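# Low-level 1D-CNN layers on batches. Feature maps are 3D arrays
# [batch, length, channels]; convolutions are realized as BLAS matrix
# products via im2col. All layers provide matching backward passes.

# valid 1D convolution of a single vector with a single kernel (used for
# small hand-checkable cases and as the reference form of the conv sum)
#' Valid 1D convolution (correlation form)
#'
#' Computes `y[j] = sum_k w[k] x[j + k - 1] + b` over all valid positions —
#' the elementary operation each convolutional channel applies at stride 1.
#'
#' @param x Numeric input vector.
#' @param w Numeric kernel.
#' @param b Scalar bias (default 0).
#' @return Numeric vector of length `length(x) - length(w) + 1`.
#' @export
conv1d <- function(x, w, b = 0) {
  n <- length(x) - length(w) + 1L
  if (n < 1) stop("kernel longer than input")
  vapply(seq_len(n), function(j)
    sum(w * x[j:(j + length(w) - 1L)]) + b, numeric(1))
}

im2col <- function(A, k) {
  d <- dim(A); N <- d[1]; len <- d[2]; cin <- d[3]
  p <- (k - 1L) %/% 2L
  P <- array(0, c(N, len + 2L * p, cin))
  P[, (p + 1L):(p + len), ] <- A
  X <- matrix(0, N * len, k * cin)
  for (o in seq_len(k))
    X[, ((o - 1L) * cin + 1L):(o * cin)] <-
      matrix(P[, o:(o + len - 1L), , drop = FALSE], N * len, cin)
  X
}

col2im <- function(dX, k, N, len, cin) {
  p <- (k - 1L) %/% 2L
  dP <- array(0, c(N, len + 2L * p, cin))
  for (o in seq_len(k)) {
    slice <- array(dX[, ((o - 1L) * cin + 1L):(o * cin)], c(N, len, cin))
    dP[, o:(o + len - 1L), ] <-
      dP[, o:(o + len - 1L), , drop = FALSE] + slice
  }
  dP[, (p + 1L):(p + len), , drop = FALSE]
}

# same-padded conv: A [N,len,cin], W (k*cin)x(cout) offset-major rows
conv_forward <- function(A, W, b, k) {
  d <- dim(A)
  Xcol <- im2col(A, k)
  Z <- Xcol %*% W
  Z <- Z + rep(b, each = nrow(Z))
  list(out = array(Z, c(d[1], d[2], ncol(W))), Xcol = Xcol, dims = d)
}

conv_backward <- function(dOut, cache, W, k) {
  d <- cache$dims
  dZ <- matrix(dOut, d[1] * d[2], dim(dOut)[3])
  dW <- crossprod(cache$Xcol, dZ)
  db <- colSums(dZ)
  dXcol <- dZ %*% t(W)
  dA <- col2im(dXcol, k, d[1], d[2], d[3])
  list(dA = dA, dW = dW, db = db)
}

relu_forward <- function(A) list(out = pmax(A, 0), mask = A > 0)
relu_backward <- function(dOut, cache) dOut * cache$mask

# batch norm over channels; M-form helpers flatten [N,len,ch] to (N*len)xch
bn_forward <- function(A, gamma, beta, running, training, eps = 1e-5,
                       momentum = 0.1) {
  d <- dim(A)
  M <- matrix(A, d[1] * d[2], d[3])
  if (training) {
    mu <- colMeans(M)
    v <- colMeans(M^2) - mu^2
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv_sd <- 1 / sqrt(v + eps)
  scale <- gamma * inv_sd
  shift <- beta - mu * scale
  out <- M * rep(scale, each = nrow(M)) + rep(shift, each = nrow(M))
  list(out = array(out, d), running = running,
       cache = list(M = M, mu = mu, inv_sd = inv_sd, gamma = gamma, dims = d))
}

bn_backward <- function(dOut, cache) {
  d <- cache$dims
  m <- d[1] * d[2]
  dY <- matrix(dOut, m, d[3])
  Mc <- cache$M - rep(cache$mu, each = m)
  xhat <- Mc * rep(cache$inv_sd, each = m)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(cache$gamma, each = m)
  dvar <- colSums(dxhat * Mc) * (-0.5) * cache$inv_sd^3
  dmu <- colSums(dxhat) * (-cache$inv_sd)
  dM <- dxhat * rep(cache$inv_sd, each = m) +
    Mc * rep(2 * dvar / m, each = m) + rep(dmu / m, each = m)
  list(dA = array(dM, d), dgamma = dgamma, dbeta = dbeta)
}

# length-2 max pooling with floor division; ties keep the first sample
pool_forward <- function(A) {
  d <- dim(A)
  len2 <- d[2] %/% 2L
  i1 <- seq(1L, 2L * len2, 2L)
  A1 <- A[, i1, , drop = FALSE]
  A2 <- A[, i1 + 1L, , drop = FALSE]
  mask <- A1 >= A2
  list(out = pmax(A1, A2), mask = mask, in_dims = d)
}

pool_backward <- function(dOut, cache) {
  d <- cache$in_dims
  len2 <- d[2] %/% 2L
  dA <- array(0, d)
  i1 <- seq(1L, 2L * len2, 2L)
  dA[, i1, ] <- dOut * cache$mask
  dA[, i1 + 1L, ] <- dOut * !cache$mask
  dA
}

# inverted dropout; draws one uniform per activation in training mode
dropout_forward <- function(A, p, training) {
  if (!training || p <= 0) return(list(out = A, mask = NULL))
  mask <- (runif(length(A)) >= p) / (1 - p)
  if (is.array(A)) mask <- array(mask, dim(A)) else mask <- matrix(mask, nrow(A), ncol(A))
  list(out = A * mask, mask = mask)
}

dropout_backward <- function(dOut, cache) {
  if (is.null(cache$mask)) dOut else dOut * cache$mask
}

fc_forward <- function(X, W, b) {
  Z <- X %*% W
  list(out = Z + rep(b, each = nrow(Z)), X = X)
}

fc_backward <- function(dZ, cache, W) {
  list(dX = dZ %*% t(W), dW = crossprod(cache$X, dZ), db = colSums(dZ))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}
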