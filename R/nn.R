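# Minimal dense/convolutional network primitives with explicit
# backpropagation.  The architecture (branch encoder/decoder + trunk net)
# is the package's core contribution, so forward and backward passes are
# written out by hand and verified against finite differences in the test
# suite.  All hidden activations are tanh; outputs are linear.

# ---- dense multilayer perceptron -------------------------------------------

# sizes: integer vector, e.g. c(2, 64, 64, 64, 64) = input, hidden..., output
nn_mlp_init <- function(sizes) {
  n <- length(sizes) - 1L
  W <- vector("list", n); b <- vector("list", n)
  for (l in seq_len(n)) {
    # Xavier scaling for tanh hidden layers
    sc <- sqrt(2 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0, sc),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

# X: (N, d_in).  Returns list(out, cache) with per-layer activations.
nn_mlp_forward <- function(net, X) {
  n <- length(net$W)
  hs <- vector("list", n + 1L)
  hs[[1L]] <- X
  for (l in seq_len(n)) {
    Z <- hs[[l]] %*% net$W[[l]]
    Z <- Z + rep(net$b[[l]], each = nrow(Z))
    hs[[l + 1L]] <- if (l < n) tanh(Z) else Z
  }
  list(out = hs[[n + 1L]], hs = hs)
}

# dY: gradient wrt output (N, d_out).  Returns grads and input gradient.
nn_mlp_backward <- function(net, cache, dY) {
  n <- length(net$W)
  gW <- vector("list", n); gb <- vector("list", n)
  delta <- dY
  for (l in rev(seq_len(n))) {
    if (l < n) delta <- delta * (1 - cache$hs[[l + 1L]]^2)  # tanh'
    gW[[l]] <- crossprod(cache$hs[[l]], delta)
    gb[[l]] <- colSums(delta)
    delta <- delta %*% t(net$W[[l]])
  }
  list(W = gW, b = gb, dX = delta)
}

# ---- convolutional branch encoder ------------------------------------------

# Feature maps are stored transposed, as matrices (H*W*C, N) with channel
# fastest: feature index = (pos - 1) * C + ch, position column-major over
# (H, W).  Each conv layer is a row-gather (im2col) + one dense matmul; in
# this layout every intermediate reshape is a zero-copy `dim<-`, and the
# backward scatter is a single grouped rowsum().

.conv_geometry <- function(H, W, C, k, stride, pad) {
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  KC <- k * k * C
  P <- Ho * Wo
  nfeat <- H * W * C
  idx <- integer(P * KC)  # nfeat + 1 = zero (padding) slot
  j <- 0L
  for (co in seq_len(Wo)) for (ro in seq_len(Ho)) {       # pos column-major
    for (dc in seq_len(k)) for (dr in seq_len(k)) for (ch in seq_len(C)) {
      ri <- (ro - 1L) * stride - pad + dr
      ci <- (co - 1L) * stride - pad + dc
      j <- j + 1L
      idx[j] <- if (ri >= 1L && ri <= H && ci >= 1L && ci <= W)
        ((ci - 1L) * H + (ri - 1L)) * C + ch else nfeat + 1L
    }
  }
  # backward scatter bookkeeping: rowsum() groups the gathered rows by
  # source feature; precompute the sorted group ids and their targets
  ugrp <- sort(unique(idx))
  list(Ho = Ho, Wo = Wo, P = P, KC = KC, nfeat = nfeat, idx = idx,
       ugrp = ugrp, ulive = ugrp <= nfeat)
}

# channels: output channels per conv block; d_out: latent dimension
nn_encoder_init <- function(m, in_ch = 2L, channels = c(8L, 16L, 32L),
                            k = 3L, stride = 2L, pad = 1L, d_out = 4L) {
  geoms <- list(); kerns <- list(); biases <- list()
  H <- m; W <- m; C <- in_ch
  for (l in seq_along(channels)) {
    g <- .conv_geometry(H, W, C, k, stride, pad)
    Co <- channels[l]
    sc <- sqrt(2 / (g$KC + Co))
    geoms[[l]] <- g
    kerns[[l]] <- matrix(stats::rnorm(g$KC * Co, 0, sc), g$KC, Co)
    biases[[l]] <- numeric(Co)
    H <- g$Ho; W <- g$Wo; C <- Co
  }
  nflat <- H * W * C
  sc <- sqrt(2 / (nflat + d_out))
  list(m = m, in_ch = in_ch, k = k, stride = stride, pad = pad,
       channels = channels, geoms = geoms,
       params = list(K = kerns, kb = biases,
                     Wd = matrix(stats::rnorm(nflat * d_out, 0, sc),
                                 nflat, d_out),
                     bd = numeric(d_out)))
}

# X: (N, m*m*in_ch) encoder inputs (row per sample; transposed internally).
# Returns list(out (N, d_out), cache).
nn_encoder_forward <- function(enc, X) {
  p <- enc$params
  N <- nrow(X)
  caches <- vector("list", length(enc$geoms))
  M <- t(X)                                          # (nfeat, N)
  for (l in seq_along(enc$geoms)) {
    g <- enc$geoms[[l]]
    Mp <- rbind(M, 0)
    Xc <- Mp[g$idx, , drop = FALSE]                  # (P*KC, N), KC fastest
    dim(Xc) <- c(g$KC, g$P * N)                      # zero-copy reshape
    Z <- crossprod(p$K[[l]], Xc) + p$kb[[l]]         # (Co, P*N), bias recycles
    A <- tanh(Z)
    caches[[l]] <- list(Xc = Xc, A = A)
    Co <- nrow(A)
    dim(A) <- c(Co * g$P, N)                         # next layer's features
    M <- A
  }
  out <- t(crossprod(M, p$Wd))                       # (d_out, N)
  out <- t(out + p$bd)                               # (N, d_out)
  list(out = out, cache = list(layers = caches, flat = M, N = N))
}

# dY: (N, d_out).  Returns list(grads, dX) with grads matching enc$params;
# dX is (N, nfeat) in the caller's row-per-sample layout.
nn_encoder_backward <- function(enc, cache, dY) {
  p <- enc$params
  N <- cache$N
  gWd <- cache$flat %*% dY                           # (nflat, d_out)
  gbd <- colSums(dY)
  dM <- p$Wd %*% t(dY)                               # (nflat, N)
  gK <- vector("list", length(enc$geoms))
  gkb <- vector("list", length(enc$geoms))
  for (l in rev(seq_along(enc$geoms))) {
    g <- enc$geoms[[l]]
    Co <- ncol(p$K[[l]])
    A <- cache$layers[[l]]$A                         # (Co, P*N)
    dim(dM) <- c(Co, g$P * N)
    dZ <- dM * (1 - A * A)
    gK[[l]] <- tcrossprod(cache$layers[[l]]$Xc, dZ)  # (KC, Co)
    gkb[[l]] <- rowSums(dZ)
    dXc <- p$K[[l]] %*% dZ                           # (KC, P*N)
    dim(dXc) <- c(g$KC * g$P, N)
    rs <- rowsum(dXc, g$idx)                         # scatter-add by feature
    dM <- matrix(0, g$nfeat, N)
    dM[g$ugrp[g$ulive], ] <- rs[g$ulive, , drop = FALSE]
  }
  list(grads = list(K = gK, kb = gkb, Wd = gWd, bd = gbd), dX = t(dM))
}

# ---- parameter vector packing and Adam -------------------------------------

# The trainable state is a nested list of numeric arrays; pack/unpack give a
# flat vector view for the optimizer, numeric gradient checks and hashing.
nn_pack <- function(params) unlist(params, use.names = FALSE)

nn_unpack <- function(vec, skeleton) {
  out <- skeleton
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    v <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    attributes(v) <- attributes(x)
    v
  }
  out <- walk(skeleton)
  stopifnot(pos == length(vec))
  out
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# cosine decay from lr to frac_min*lr over frac_T of the run, then constant
lr_schedule <- function(epoch, epochs, lr, frac_min = 0.1, frac_T = 0.8) {
  Tc <- max(1, floor(frac_T * epochs))
  f <- min(epoch / Tc, 1)
  lr * (frac_min + (1 - frac_min) * (1 + cos(pi * f)) / 2)
}
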