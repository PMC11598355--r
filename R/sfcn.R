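#' Build an SFCN-style architecture specification
#'
#' The classifier is a seven-block fully convolutional network: blocks 1-5
#' are 3x3x3 convolution (padding 1) + batch normalization + 2x2x2 max
#' pooling (stride 2) + ReLU; block 6 is a 1x1x1 convolution + batch
#' normalization + ReLU; block 7 is average pooling over the remaining
#' spatial extent, dropout (training only) and a final 1x1x1 convolution to
#' a single pre-sigmoid score.  Male is the positive class.
#'
#' The average-pooling kernel is derived from the input shape: it equals the
#' spatial extent left after five stride-2 floor-halvings, e.g. 6x7x6 for a
#' 193x229x193 input and 1x1x1 for 48x48x48.
#'
#' @param input_shape Integer length-3 input grid; every axis must be >= 32
#'   so that five halvings leave at least one voxel.
#' @param channels Six channel widths for blocks 1-6.
#' @param dropout_p Dropout probability in block 7 (training only).
#' @return An `sfcn_spec` with the per-block spatial trace and derived
#'   average-pool kernel.
#' @export
build_sfcn <- function(input_shape, channels = c(8, 16, 16, 32, 32, 16),
                       dropout_p = 0.5) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3L, length(channels) == 6L,
            all(channels >= 1), dropout_p >= 0, dropout_p < 1)
  small <- which(input_shape < 32L)
  if (length(small))
    stop(sprintf("input axis %s is %d voxels; five max-pool halvings need >= 32",
                 paste(small, collapse = ","),
                 input_shape[small[1]]))
  trace <- list(input_shape)
  d <- input_shape
  for (i in 1:5) { d <- d %/% 2L; trace[[i + 1L]] <- d }
  structure(list(input_shape = input_shape,
                 channels = as.integer(channels),
                 dropout_p = dropout_p,
                 n_out = 1L,
                 dims_trace = trace,
                 avgpool_kernel = d),
            class = "sfcn_spec")
}

#' @export
print.sfcn_spec <- function(x, ...) {
  cat(sprintf("<sfcn_spec input %s, channels %s, avgpool %s, dropout %.2f>\n",
              paste(x$input_shape, collapse = "x"),
              paste(x$channels, collapse = ","),
              paste(x$avgpool_kernel, collapse = "x"), x$dropout_p))
  invisible(x)
}

#' Initialize SFCN weights
#'
#' He-normal initialization for convolution kernels, unit-gamma/zero-beta
#' batch-norm parameters, zero biases.
#'
#' @param spec An `sfcn_spec`.
#' @param seed Integer seed.
#' @return An `sfcn_model`: list with `spec` and `params`.
#' @export
sfcn_init <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sfcn_spec"))
  set.seed(derive_seed(seed, "init"))
  ch <- c(1L, spec$channels)
  blocks <- vector("list", 6L)
  for (i in 1:6) {
    kin <- if (i <= 5) 27L * ch[i] else ch[i]
    W <- matrix(rnorm(kin * ch[i + 1], 0, sqrt(2 / kin)), kin, ch[i + 1])
    blocks[[i]] <- list(W = W, b = rep(0, ch[i + 1]),
                        gamma = rep(1, ch[i + 1]), beta = rep(0, ch[i + 1]),
                        rm = rep(0, ch[i + 1]), rv = rep(1, ch[i + 1]))
  }
  # zero-initialized head: the initial logit is 0 (probability 0.5) for any
  # input, so no epochs are spent unlearning a random initial class bias
  out <- list(W = matrix(0, ch[7], 1), b = 0)
  structure(list(spec = spec, params = list(blocks = blocks, out = out)),
            class = "sfcn_model")
}

#' Count of trainable parameters
#' @param model An `sfcn_model`.
#' @return Integer parameter count (convolutions, batch-norm affine, output).
#' @export
sfcn_n_params <- function(model) {
  p <- model$params
  n <- length(p$out$W) + 1L
  for (bl in p$blocks)
    n <- n + length(bl$W) + length(bl$b) + length(bl$gamma) + length(bl$beta)
  as.integer(n)
}

bn_eps <- 1e-5
bn_momentum <- 0.1

col_affine <- function(X, mu, a, b) cpp_col_affine(X, mu, a, b)

bn_forward <- function(Z, bl, training) {
  if (training) {
    st <- cpp_col_stats(Z)
    mu <- as.numeric(st$mu)
    va <- as.numeric(st$va)
  } else {
    mu <- bl$rm
    va <- bl$rv
  }
  isd <- 1 / sqrt(va + bn_eps)
  list(out = col_affine(Z, mu, bl$gamma * isd, bl$beta), mu = mu, va = va)
}

bn_backward <- function(dOut, Z, mu, va, gamma, training) {
  out <- cpp_bn_backward(dOut, Z, mu, va, gamma, bn_eps, training)
  list(dZ = out$dZ, dgamma = as.numeric(out$dgamma),
       dbeta = as.numeric(out$dbeta))
}

# Stack a list of volumes/arrays into the (S*B) x 1 batch matrix.
batch_matrix <- function(vols) {
  matrix(unlist(lapply(unname(vols), function(v) as.numeric(bare_array(v))),
                use.names = FALSE), ncol = 1)
}

# Forward pass over a batch matrix X ((S*B) x 1).  Returns logits and,
# optionally, the cache needed for back-propagation.  In training mode the
# batch-norm running statistics are updated and returned in `params`.
sfcn_forward <- function(model, X, B, training = FALSE, keep_cache = FALSE) {
  spec <- model$spec
  params <- model$params
  d <- spec$input_shape
  A <- X
  cache <- list(blocks = vector("list", 6L))
  for (i in 1:5) {
    bl <- params$blocks[[i]]
    Z <- cpp_conv3d_fw(A, d, B, bl$W, bl$b)
    bn <- bn_forward(Z, bl, training)
    if (training) {
      params$blocks[[i]]$rm <- (1 - bn_momentum) * bl$rm + bn_momentum * bn$mu
      params$blocks[[i]]$rv <- (1 - bn_momentum) * bl$rv + bn_momentum * bn$va
    }
    pl <- cpp_maxpool3d_fw(bn$out, d, B)
    H <- pmax(pl$Y, 0)
    if (keep_cache)
      cache$blocks[[i]] <- list(A = A, d = d, Z = Z, mu = bn$mu, va = bn$va,
                                idx = pl$idx, pooled = pl$Y)
    A <- H
    d <- d %/% 2L
  }
  bl <- params$blocks[[6]]
  Z6 <- col_affine(A %*% bl$W, numeric(length(bl$b)), rep(1, length(bl$b)),
                   bl$b)
  bn6 <- bn_forward(Z6, bl, training)
  if (training) {
    params$blocks[[6]]$rm <- (1 - bn_momentum) * bl$rm + bn_momentum * bn6$mu
    params$blocks[[6]]$rv <- (1 - bn_momentum) * bl$rv + bn_momentum * bn6$va
  }
  H6 <- pmax(bn6$out, 0)
  S7 <- prod(d)
  grp <- rep(seq_len(B), each = S7)
  M <- rowsum(H6, grp) / S7
  if (training && spec$dropout_p > 0) {
    keep <- matrix(rbinom(length(M), 1, 1 - spec$dropout_p), nrow(M)) /
      (1 - spec$dropout_p)
    Md <- M * keep
  } else {
    keep <- NULL
    Md <- M
  }
  logits <- as.numeric(Md %*% params$out$W + params$out$b)
  if (keep_cache) {
    cache$blocks[[6]] <- list(A = A, Z = Z6, mu = bn6$mu, va = bn6$va,
                              relu = bn6$out > 0)
    cache$out <- list(S7 = S7, B = B, M = M, Md = Md, keep = keep,
                      relu5 = NULL)
  }
  list(logits = logits, cache = if (keep_cache) cache else NULL,
       params = params)
}

# Back-propagation from d(loss)/d(logit).  Returns parameter gradients in
# the same structure as `params`, plus -- when `input_grad` -- the gradient
# with respect to the input batch (used for class-saliency maps).
sfcn_backward <- function(model, cache, dlogit, training = TRUE,
                          input_grad = !training) {
  params <- model$params
  co <- cache$out
  B <- co$B
  dlogit <- matrix(dlogit, ncol = 1)
  grads <- list(blocks = vector("list", 6L),
                out = list(W = t(co$Md) %*% dlogit, b = sum(dlogit)))
  dM <- dlogit %*% t(params$out$W)
  if (!is.null(co$keep)) dM <- dM * co$keep
  dH6 <- dM[rep(seq_len(B), each = co$S7), , drop = FALSE] / co$S7
  b6 <- cache$blocks[[6]]
  dZbn <- dH6 * b6$relu
  bb <- bn_backward(dZbn, b6$Z, b6$mu, b6$va, params$blocks[[6]]$gamma,
                    training)
  grads$blocks[[6]] <- list(W = t(b6$A) %*% bb$dZ, b = colSums(bb$dZ),
                            gamma = bb$dgamma, beta = bb$dbeta)
  dA <- bb$dZ %*% t(params$blocks[[6]]$W)
  for (i in 5:1) {
    bl <- cache$blocks[[i]]
    dPooled <- dA * (bl$pooled > 0)
    dBNout <- cpp_maxpool3d_bw(dPooled, bl$idx, prod(bl$d), B)
    bb <- bn_backward(dBNout, bl$Z, bl$mu, bl$va, params$blocks[[i]]$gamma,
                      training)
    need_dx <- i > 1L || input_grad
    cv <- cpp_conv3d_bw(bl$A, bl$d, B, params$blocks[[i]]$W, bb$dZ, need_dx)
    grads$blocks[[i]] <- list(W = cv$dW, b = as.numeric(cv$db),
                              gamma = bb$dgamma, beta = bb$dbeta)
    dA <- if (need_dx) cv$dX else NULL
  }
  list(grads = grads, dX = dA)
}

#' Predicted male probabilities for a set of volumes
#'
#' Runs the network in evaluation mode (dropout off, batch norm using running
#' statistics).  Outputs are sigmoid probabilities of the Male class.
#'
#' @param model A trained `sfcn_model`.
#' @param volumes List of `volume3d`/arrays matching the model input shape.
#' @param batch_size Evaluation batch size.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
sfcn_predict <- function(model, volumes, batch_size = 16L) {
  n <- length(volumes)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    X <- batch_matrix(volumes[i:j])
    fw <- sfcn_forward(model, X, j - i + 1L, training = FALSE)
    out[i:j] <- stats::plogis(fw$logits)
    i <- j + 1L
  }
  out
}

# numerically stable binary cross-entropy with logits; y in {0,1}
bce_with_logits <- function(logits, y) {
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}
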