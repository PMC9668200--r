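# Core architecture: branch encoder (conv net over the stress grid image),
# branch decoder (MLP from [class feature; sample feature] to two
# p-dimensional coefficient vectors) and trunk net (MLP from a stretch state
# to two p-dimensional basis vectors).  The stress prediction is the inner
# product of decoder and trunk outputs plus a per-component trainable bias.

#' Model configuration
#'
#' Collects the architecture hyperparameters.  The sub-network depths and
#' widths are package defaults, exposed here because they are tunable and
#' not canonical.
#'
#' @param m stress-grid size per side (default 31).
#' @param p branch/trunk output width (default 32).
#' @param d_eta sample-feature dimension, between 2 and 6 (default 4).
#' @param d_zeta number of genotype classes (default 4).
#' @param enc_channels conv-block output channels of the branch encoder.
#' @param hidden width of decoder/trunk hidden layers.
#' @param depth number of decoder/trunk hidden layers.
#' @param domain stretch domain.
#' @param sigma0 stress normalisation constant (kPa).
#' @return object of class `g2phi_config`.
#' @export
g2phi_config <- function(m = 31, p = 32, d_eta = 4, d_zeta = 4,
                         enc_channels = c(8, 16, 32), hidden = 64, depth = 3,
                         domain = .default_domain, sigma0 = 1) {
  stopifnot(m >= 2, p >= 1, d_zeta >= 2, hidden >= 1, depth >= 1)
  if (d_eta < 2 || d_eta > 6)
    stop("d_eta must lie in 2..6")
  structure(list(m = as.integer(m), p = as.integer(p),
                 d_eta = as.integer(d_eta), d_zeta = as.integer(d_zeta),
                 enc_channels = as.integer(enc_channels),
                 hidden = as.integer(hidden), depth = as.integer(depth),
                 domain = domain, sigma0 = sigma0),
            class = "g2phi_config")
}

#' Initialise model parameters
#'
#' Draws fresh sub-network weights (Xavier-scaled Gaussians) for the branch
#' encoder, branch decoder and trunk net.  Deterministic given `seed`.
#'
#' @param config a [g2phi_config()].
#' @param seed integer seed.
#' @return object of class `g2phi_params`.
#' @export
g2phi_init <- function(config, seed = 1L) {
  stopifnot(inherits(config, "g2phi_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  enc <- nn_encoder_init(config$m, in_ch = 2L,
                         channels = config$enc_channels,
                         d_out = config$d_eta)
  dec <- nn_mlp_init(c(config$d_zeta + config$d_eta,
                       rep(config$hidden, config$depth), 2L * config$p))
  trk <- nn_mlp_init(c(2L, rep(config$hidden, config$depth), 2L * config$p))
  structure(list(config = config, encoder = enc, decoder = dec, trunk = trk,
                 b0 = c(theta = 0, z = 0),
                 input_center = 0, input_scale = 1,
                 init_seed = as.integer(seed)),
            class = "g2phi_params")
}

#' @export
print.g2phi_params <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<g2phi_params m=%d p=%d d_eta=%d d_zeta=%d ",
                     "(%d trainable values)>\n"),
              cfg$m, cfg$p, cfg$d_eta, cfg$d_zeta,
              length(nn_pack(.trainable(x)))))
  invisible(x)
}

# nested list of every trainable array (order matters for pack/unpack)
.trainable <- function(params) {
  list(encoder = params$encoder$params, decoder = params$decoder,
       trunk = params$trunk, b0 = params$b0)
}

.set_trainable <- function(params, tr) {
  params$encoder$params <- tr$encoder
  params$decoder <- tr$decoder
  params$trunk <- tr$trunk
  params$b0 <- tr$b0
  params
}

# flatten a normalised stress grid (m, m, 2) into the encoder input layout
# (channel fastest, position column-major with lambda_z as the row index)
grid_to_input <- function(grid) {
  v <- if (inherits(grid, "stress_grid")) grid$values else grid
  as.vector(aperm(v, c(3L, 1L, 2L)))
}

# stack a list of grids into an (N, m*m*2) input matrix
grids_to_inputs <- function(grids) {
  do.call(rbind, lapply(grids, grid_to_input))
}

# scale stretch states to [-1, 1] for the trunk input
.scale_stretch <- function(stretches, domain) {
  2 * (stretches - domain[1]) / (domain[2] - domain[1]) - 1
}

#' Branch encoder: compress a stress grid to a sample feature
#'
#' @param params a [g2phi_init()] model.
#' @param grids a single [stress_grid()] (or `(m, m, 2)` array), or a list
#'   of them.
#' @return sample-feature matrix `(N, d_eta)`; a single row for one grid.
#' @export
branch_encode <- function(params, grids) {
  stopifnot(inherits(params, "g2phi_params"))
  single <- inherits(grids, "stress_grid") ||
    (is.array(grids) && length(dim(grids)) == 3L)
  if (single) grids <- list(grids)
  X <- grids_to_inputs(grids)
  if (ncol(X) != params$config$m^2 * 2L)
    stop("branch_encode(): grid size does not match the model (m = ",
         params$config$m, ")")
  X <- (X - params$input_center) / params$input_scale
  nn_encoder_forward(params$encoder, X)$out
}

#' Branch decoder: map class + sample feature to coefficient vectors
#'
#' @param params a [g2phi_init()] model.
#' @param zeta class-feature vector (length `d_zeta`) or matrix `(N, d_zeta)`.
#' @param eta sample-feature vector (length `d_eta`) or matrix `(N, d_eta)`.
#' @return list with matrices `b_theta` and `b_z`, each `(N, p)`.
#' @export
branch_decode <- function(params, zeta, eta) {
  stopifnot(inherits(params, "g2phi_params"))
  cfg <- params$config
  if (is.null(dim(zeta))) zeta <- matrix(zeta, nrow = 1L)
  if (is.null(dim(eta))) eta <- matrix(eta, nrow = 1L)
  if (ncol(zeta) != cfg$d_zeta || ncol(eta) != cfg$d_eta ||
      nrow(zeta) != nrow(eta))
    stop("branch_decode(): feature dimensions do not match the model")
  out <- nn_mlp_forward(params$decoder, cbind(zeta, eta))$out
  list(b_theta = out[, seq_len(cfg$p), drop = FALSE],
       b_z = out[, cfg$p + seq_len(cfg$p), drop = FALSE])
}

#' Trunk net: map stretch states to basis vectors
#'
#' @param params a [g2phi_init()] model.
#' @param stretches matrix `(n, 2)` with columns `(lambda_theta, lambda_z)`,
#'   or a length-2 vector.
#' @return list with matrices `t_theta` and `t_z`, each `(n, p)`.
#' @export
trunk_eval <- function(params, stretches) {
  stopifnot(inherits(params, "g2phi_params"))
  cfg <- params$config
  if (is.null(dim(stretches))) stretches <- matrix(stretches, nrow = 1L)
  out <- nn_mlp_forward(params$trunk,
                        .scale_stretch(stretches, cfg$domain))$out
  list(t_theta = out[, seq_len(cfg$p), drop = FALSE],
       t_z = out[, cfg$p + seq_len(cfg$p), drop = FALSE])
}

#' Predict normalised stresses for one (class, sample) feature pair
#'
#' The prediction is the inner product of branch-decoder and trunk outputs
#' plus a per-component trainable bias:
#' \eqn{\hat\sigma_c = b_c \cdot t_c + b_{0c}}.
#'
#' @param params a [g2phi_init()] model.
#' @param zeta class-feature vector (length `d_zeta`).
#' @param eta sample-feature vector (length `d_eta`).
#' @param stretches matrix `(n, 2)` of stretch states or a length-2 vector.
#' @return matrix `(n, 2)` of normalised stresses, columns
#'   `(sigma_theta, sigma_z)`.
#' @export
predict_stress <- function(params, zeta, eta, stretches) {
  b <- branch_decode(params, zeta, eta)
  t <- trunk_eval(params, stretches)
  cbind(sigma_theta = as.vector(t$t_theta %*% t(b$b_theta)) +
          params$b0[["theta"]],
        sigma_z = as.vector(t$t_z %*% t(b$b_z)) + params$b0[["z"]])
}

#' Reconstruction loss on normalised stress grids
#'
#' Relative-quadratic mismatch
#' \deqn{L_{rec} = \frac{1}{m^2 N}\sum_k v_k \sum_{i,j}
#'   \left[\frac{(\hat\sigma_\theta-\sigma_\theta)^2}{|\sigma_\theta+\epsilon|}
#'   + \frac{(\hat\sigma_z-\sigma_z)^2}{|\sigma_z+\epsilon|}\right],}
#' where the stabiliser `eps` guards the zero-stress corner and `v` weights
#' each sample (real vs mixup-synthesised).
#'
#' @param pred,truth arrays `(m, m, 2, N)`, lists of `(m, m, 2)` arrays /
#'   [stress_grid()]s, or single grids; normalised stresses.
#' @param v per-sample weights, recycled to N.
#' @param eps stabiliser (default 0.01, normalised units).
#' @return scalar loss, >= 0 and 0 iff `pred == truth`.
#' @export
reconstruction_loss <- function(pred, truth, v = 1, eps = 0.01) {
  P <- .as_grid_batch(pred); Tm <- .as_grid_batch(truth)
  if (!identical(dim(P), dim(Tm)))
    stop("reconstruction_loss(): shape mismatch between pred and truth")
  N <- dim(P)[4L]; m2 <- dim(P)[1L] * dim(P)[2L]
  if (N < 1) stop("reconstruction_loss(): empty batch")
  v <- rep_len(v, N)
  contrib <- (P - Tm)^2 / abs(Tm + eps)
  per_sample <- apply(contrib, 4L, sum)
  sum(v * per_sample) / (m2 * N)
}

# coerce grids to an (m, m, 2, N) array
.as_grid_batch <- function(x) {
  if (inherits(x, "stress_grid")) x <- x$values
  if (is.list(x)) {
    x <- lapply(x, function(g) if (inherits(g, "stress_grid")) g$values else g)
    return(array(unlist(x), dim = c(dim(x[[1L]]), length(x))))
  }
  if (is.array(x) && length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

#' Latent-space regulariser of the sample features
#'
#' Penalises deviation of the batch of sample features from a standard
#' normal population:
#' \deqn{L_{reg} = \tfrac12\left[\mu^\top\mu + \mathrm{tr}\,\Sigma - d_\eta
#'  - \log|\Sigma|\right],}
#' with \eqn{\mu} the sample mean and \eqn{\Sigma} the sample covariance of
#' the batch.  Nonnegative, and zero iff \eqn{\mu = 0, \Sigma = I}.
#' Batches smaller than `d_eta + 1` fall back to a diagonal-only covariance;
#' a near-singular covariance receives a `1e-6` diagonal jitter before the
#' log-determinant (never a silent `-Inf`).
#'
#' @param etas matrix `(N, d_eta)` of sample features, `N >= 2`.
#' @return scalar penalty.
#' @export
latent_regularization <- function(etas) {
  stopifnot(is.matrix(etas), nrow(etas) >= 2L)
  d <- ncol(etas)
  mu <- colMeans(etas)
  if (nrow(etas) <= d) {
    vars <- apply(etas, 2L, stats::var)
    vars <- pmax(vars, 1e-6)
    return(0.5 * (sum(mu^2) + sum(vars) - d - sum(log(vars))))
  }
  S <- stats::cov(etas)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    S <- S + diag(1e-6, d)
    ev <- ev + 1e-6
  }
  0.5 * (sum(mu^2) + sum(diag(S)) - d - sum(log(ev)))
}

# gradient of latent_regularization wrt the eta matrix (same jitter rules)
.latent_reg_grad <- function(etas) {
  N <- nrow(etas); d <- ncol(etas)
  mu <- colMeans(etas)
  g_mu <- matrix(mu, N, d, byrow = TRUE) / N
  if (N <= d) {
    vars <- apply(etas, 2L, stats::var)
    active <- vars > 1e-6
    vars <- pmax(vars, 1e-6)
    dvar <- 0.5 * (1 - 1 / vars) * active
    C <- sweep(etas, 2L, mu)
    return(g_mu + sweep(C, 2L, dvar, "*") * 2 / (N - 1))
  }
  S <- stats::cov(etas)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) S <- S + diag(1e-6, d)
  dS <- 0.5 * (diag(d) - solve(S))
  C <- sweep(etas, 2L, mu)
  g_mu + C %*% (dS + t(dS)) / (N - 1)
}

#' Total learning-stage loss
#'
#' @param recon reconstruction loss value.
#' @param latent_reg latent regularisation value.
#' @param w_rec,w_reg nonnegative weights.
#' @return `w_rec * recon + w_reg * latent_reg`.
#' @export
learning_loss <- function(recon, latent_reg, w_rec = 1, w_reg = 0.1) {
  stopifnot(w_rec >= 0, w_reg >= 0, is.finite(recon), is.finite(latent_reg))
  w_rec * recon + w_reg * latent_reg
}

#' Save / load a model container
#'
#' The container stores a schema version, the architecture dimensions, the
#' normalisation constant and every trainable array; reloading restores
#' bit-identical predictions.
#'
#' @param params a `g2phi_params`, `g2phi_fit` or `g2phi_ensemble` object.
#' @param path file path.
#' @return `load_g2phi()` returns the restored object.
#' @export
save_g2phi <- function(params, path) {
  stopifnot(inherits(params, c("g2phi_params", "g2phi_fit",
                               "g2phi_ensemble")))
  saveRDS(list(schema = "g2phinet-container-1",
               package_version = as.character(utils::packageVersion("g2phinet")),
               object = params), path)
  invisible(path)
}

#' @rdname save_g2phi
#' @export
load_g2phi <- function(path) {
  x <- readRDS(path)
  if (!identical(x$schema, "g2phinet-container-1"))
    stop("unrecognised model container schema: ", x$schema)
  x$object
}
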