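# Inference stage: fit the frozen ensemble to a new specimen's scattered
# normalised stresses by optimising the shared class feature zeta (on the
# probability simplex, via softmax over logits) and one sample feature
# eta per ensemble member, then reconstruct the full stress surface and
# classify the genotype by the largest component of zeta.

#' Construct an observation set
#'
#' @param stretches matrix `(m', 2)`, columns `(lambda_theta, lambda_z)`.
#' @param stresses_norm matrix `(m', 2)` of normalised stresses, columns
#'   `(sigma_theta, sigma_z)`.
#' @param setup tag: `"structured_3x3"` or `"unstructured"`.
#' @return object of class `observation_set`.
#' @export
observation_set <- function(stretches, stresses_norm,
                            setup = c("unstructured", "structured_3x3")) {
  setup <- match.arg(setup)
  stretches <- as.matrix(stretches); stresses_norm <- as.matrix(stresses_norm)
  stopifnot(nrow(stretches) >= 1L, ncol(stretches) == 2L,
            identical(dim(stretches), dim(stresses_norm)),
            all(is.finite(stretches)), all(is.finite(stresses_norm)))
  structure(list(stretches = stretches, stresses = stresses_norm,
                 m_prime = nrow(stretches), setup = setup),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("<observation_set m'=%d (%s)>\n", x$m_prime, x$setup))
  invisible(x)
}

# evaluate one frozen member at given scaled-trunk inputs; returns cached
# trunk outputs (t_theta, t_z), each (n, p)
.member_trunk <- function(member, stretches, config) {
  out <- nn_mlp_forward(member$trunk,
                        .scale_stretch(stretches, config$domain))$out
  p <- config$p
  list(t_theta = out[, seq_len(p), drop = FALSE],
       t_z = out[, p + seq_len(p), drop = FALSE])
}

#' Mega-model (ensemble) stress prediction
#'
#' The ensemble predicts the mean over its `K` frozen copies, each copy
#' using the shared class feature and its own sample feature:
#' \eqn{\hat\sigma = K^{-1}\sum_i \hat\sigma^{(i)}(\zeta, \eta^{(i)})}.
#'
#' @param ens a [harvest_ensemble()] object.
#' @param zeta class-feature vector (length `d_zeta`, on the simplex).
#' @param etas matrix `(K, d_eta)` (or a single vector recycled to all
#'   members) of per-member sample features.
#' @param stretches matrix `(n, 2)` of stretch states or a length-2 vector.
#' @return matrix `(n, 2)` of normalised stresses.
#' @export
ensemble_predict <- function(ens, zeta, etas, stretches) {
  stopifnot(inherits(ens, "g2phi_ensemble"))
  if (ens$K == 0L) stop("ensemble_predict(): empty ensemble")
  cfg <- ens$config
  if (is.null(dim(stretches))) stretches <- matrix(stretches, nrow = 1L)
  if (is.null(dim(etas)))
    etas <- matrix(etas, ens$K, cfg$d_eta, byrow = TRUE)
  stopifnot(nrow(etas) == ens$K, ncol(etas) == cfg$d_eta,
            length(zeta) == cfg$d_zeta)
  n <- nrow(stretches)
  acc <- matrix(0, n, 2L)
  for (i in seq_len(ens$K)) {
    mem <- ens$members[[i]]
    tk <- .member_trunk(mem, stretches, cfg)
    b <- nn_mlp_forward(mem$decoder,
                        matrix(c(zeta, etas[i, ]), nrow = 1L))$out
    bt <- b[1L, seq_len(cfg$p)]; bz <- b[1L, cfg$p + seq_len(cfg$p)]
    acc[, 1L] <- acc[, 1L] + tk$t_theta %*% bt + mem$b0[["theta"]]
    acc[, 2L] <- acc[, 2L] + tk$t_z %*% bz + mem$b0[["z"]]
  }
  acc <- acc / ens$K
  colnames(acc) <- c("sigma_theta", "sigma_z")
  acc
}

#' Inference fitting loss
#'
#' Relative-quadratic mismatch between ensemble predictions and the
#' observed normalised stresses:
#' \deqn{L_{fit} = \frac{1}{m'}\sum_i
#'   \left[\frac{(\hat\sigma_\theta-\sigma_\theta)^2}{|\sigma_\theta+\epsilon|}
#'   + \frac{(\hat\sigma_z-\sigma_z)^2}{|\sigma_z+\epsilon|}\right].}
#'
#' @param ens ensemble model.
#' @param zeta,etas features as in [ensemble_predict()].
#' @param obs an [observation_set()].
#' @param eps stabiliser (default 0.01).
#' @return scalar >= 0; 0 iff predictions equal observations.
#' @export
fitting_loss <- function(ens, zeta, etas, obs, eps = 0.01) {
  stopifnot(inherits(obs, "observation_set"))
  pred <- ensemble_predict(ens, zeta, etas, obs$stretches)
  d <- (pred - obs$stresses)^2 / abs(obs$stresses + eps)
  sum(d) / obs$m_prime
}

#' Sample-feature magnitude regulariser
#'
#' The fourth-power penalty on the sample-feature magnitude, aggregated as
#' a per-member mean over the ensemble.  The default reading of
#' \eqn{|\eta|^4} is \eqn{(\|\eta\|_2^2)^2}; `mode = "sum_quartic"` gives
#' \eqn{\sum_j \eta_j^4} instead.
#'
#' @param etas matrix `(K, d_eta)` or a single vector.
#' @param mode `"l2sq_sq"` (default) or `"sum_quartic"`.
#' @return scalar >= 0, zero at the origin.
#' @export
eta_regularizer <- function(etas, mode = c("l2sq_sq", "sum_quartic")) {
  mode <- match.arg(mode)
  if (is.null(dim(etas))) etas <- matrix(etas, nrow = 1L)
  per <- if (mode == "l2sq_sq") rowSums(etas^2)^2 else rowSums(etas^4)
  mean(per)
}

#' Classify a genotype from a class feature
#'
#' The predicted genotype is the largest component of `zeta`; exact ties
#' break to the lowest index.
#'
#' @param zeta simplex vector.
#' @return integer class index.
#' @export
classify <- function(zeta) {
  stopifnot(all(zeta >= -1e-9), abs(sum(zeta) - 1) < 1e-6)
  which.max(zeta)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Infer class and sample features for a new specimen
#'
#' Optimises the inference loss `w_fit * L_fit + w_reg2 * L_reg2` over the
#' shared class feature and the per-member sample features, with all member
#' weights frozen.  The class feature is parameterised as a softmax over
#' trainable logits initialised at zero, which reproduces the canonical
#' uniform initialisation `zeta = (1/d_zeta, ...)` exactly and keeps the
#' simplex constraint at machine precision throughout; sample features are
#' initialised at the origin.  Adam iterations with plateau early stopping
#' are followed by an optional BFGS polish.
#'
#' @param ens a [harvest_ensemble()] model.
#' @param obs an [observation_set()].
#' @param w_fit,w_reg2 loss weights (set `w_reg2 > 0` to activate the
#'   sample-feature regulariser; used for unstructured observations).
#' @param eps fitting-loss stabiliser.
#' @param iters maximum Adam iterations.
#' @param lr Adam learning rate.
#' @param polish run a BFGS polish after Adam (default TRUE).
#' @param plateau_tol,plateau_window early stop when the relative loss
#'   change over `plateau_window` iterations falls below `plateau_tol`.
#' @param eta_mode aggregation mode of [eta_regularizer()].
#' @param truth optional [stress_grid()] ground truth; when supplied the
#'   result carries per-component relative L2 errors.
#' @param reconstruct_m grid size of the returned reconstruction.
#' @return object of class `g2phi_inference`: fitted `zeta`, `etas`,
#'   `class_index`, `loss` (final), `loss_history`, `zeta_history`,
#'   `reconstruction` ([stress_grid()]) and optionally `errors`.
#' @export
infer_sample <- function(ens, obs, w_fit = 1, w_reg2 = 0, eps = 0.01,
                         iters = 1500, lr = 0.05, polish = TRUE,
                         plateau_tol = 1e-8, plateau_window = 100,
                         eta_mode = c("l2sq_sq", "sum_quartic"),
                         truth = NULL, reconstruct_m = NULL) {
  stopifnot(inherits(ens, "g2phi_ensemble"), inherits(obs, "observation_set"))
  eta_mode <- match.arg(eta_mode)
  if (obs$m_prime == 0L) stop("infer_sample(): empty observation set")
  cfg <- ens$config
  K <- ens$K; d_zeta <- cfg$d_zeta; d_eta <- cfg$d_eta; p <- cfg$p
  # frozen trunk outputs at the observed stretches, once per member
  trunks <- lapply(ens$members, .member_trunk, stretches = obs$stretches,
                   config = cfg)
  y <- obs$stresses
  den <- abs(y + eps)
  mp <- obs$m_prime

  objective <- function(theta, want_grad = TRUE) {
    z <- theta[seq_len(d_zeta)]
    zeta <- softmax(z)
    etas <- matrix(theta[-seq_len(d_zeta)], K, d_eta, byrow = TRUE)
    pred <- matrix(0, mp, 2L)
    caches <- vector("list", K)
    for (i in seq_len(K)) {
      mem <- ens$members[[i]]
      fw <- nn_mlp_forward(mem$decoder,
                           matrix(c(zeta, etas[i, ]), nrow = 1L))
      caches[[i]] <- fw
      bt <- fw$out[1L, seq_len(p)]; bz <- fw$out[1L, p + seq_len(p)]
      pred[, 1L] <- pred[, 1L] + trunks[[i]]$t_theta %*% bt +
        mem$b0[["theta"]]
      pred[, 2L] <- pred[, 2L] + trunks[[i]]$t_z %*% bz + mem$b0[["z"]]
    }
    pred <- pred / K
    resid <- pred - y
    l_fit <- sum(resid^2 / den) / mp
    l_reg <- if (w_reg2 > 0) eta_regularizer(etas, eta_mode) else 0
    val <- w_fit * l_fit + w_reg2 * l_reg
    if (!want_grad) return(list(value = val, l_fit = l_fit, zeta = zeta))
    dpred <- w_fit * 2 * resid / den / mp / K        # per-member share
    g_z <- numeric(d_zeta)
    g_eta <- matrix(0, K, d_eta)
    for (i in seq_len(K)) {
      dB <- c(crossprod(trunks[[i]]$t_theta, dpred[, 1L]),
              crossprod(trunks[[i]]$t_z, dpred[, 2L]))
      bw <- nn_mlp_backward(ens$members[[i]]$decoder, caches[[i]],
                            matrix(dB, nrow = 1L))
      din <- bw$dX[1L, ]
      g_z <- g_z + din[seq_len(d_zeta)]
      g_eta[i, ] <- din[d_zeta + seq_len(d_eta)]
    }
    if (w_reg2 > 0) {
      if (eta_mode == "l2sq_sq") {
        g_eta <- g_eta + w_reg2 * (4 * rowSums(etas^2) * etas) / K
      } else {
        g_eta <- g_eta + w_reg2 * 4 * etas^3 / K
      }
    }
    # softmax chain rule: dL/dz = J_softmax^T dL/dzeta
    dzeta <- g_z
    dz <- zeta * (dzeta - sum(zeta * dzeta))
    list(value = val, l_fit = l_fit, zeta = zeta,
         grad = c(dz, as.vector(t(g_eta))))
  }

  theta <- numeric(d_zeta + K * d_eta)   # uniform zeta, zero etas
  opt <- adam_init(length(theta))
  loss_hist <- numeric(0)
  zeta_hist <- list()
  last_window <- Inf
  for (it in seq_len(iters)) {
    ob <- objective(theta)
    stp <- adam_step(opt, theta, ob$grad, lr)
    theta <- stp$theta; opt <- stp$state
    if (!is.finite(ob$value)) {
      stop(structure(class = c("g2phi_divergence", "error", "condition"),
                     list(message = "inference diverged (non-finite loss)",
                          call = sys.call(-1), history = loss_hist)))
    }
    if (it %% 10L == 0L || it == 1L) {
      loss_hist <- c(loss_hist, ob$value)
      zeta_hist[[length(zeta_hist) + 1L]] <- ob$zeta
    }
    if (it %% plateau_window == 0L) {
      if (is.finite(last_window) &&
          abs(last_window - ob$value) <=
          plateau_tol * max(abs(last_window), 1e-12)) break
      last_window <- ob$value
    }
  }
  if (polish) {
    fit <- stats::optim(theta, fn = function(th) objective(th)$value,
                        gr = function(th) objective(th)$grad,
                        method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-14))
    if (is.finite(fit$value) &&
        fit$value <= objective(theta, want_grad = FALSE)$value)
      theta <- fit$par
  }
  final <- objective(theta, want_grad = FALSE)
  zeta <- final$zeta
  etas <- matrix(theta[-seq_len(d_zeta)], K, d_eta, byrow = TRUE)
  loss_hist <- c(loss_hist, final$value)
  zeta_hist[[length(zeta_hist) + 1L]] <- zeta

  m_rec <- if (is.null(reconstruct_m)) {
    if (!is.null(truth)) truth$m else cfg$m
  } else reconstruct_m
  rec_pts <- grid_stretches(m_rec, cfg$domain)
  rec <- ensemble_predict(ens, zeta, etas, rec_pts)
  recon <- stress_grid(array(as.vector(rec), dim = c(m_rec, m_rec, 2)),
                       domain = cfg$domain, normalized = TRUE,
                       sigma0 = cfg$sigma0)
  out <- list(zeta = zeta, etas = etas, class_index = classify(zeta),
              loss = final$value, fit_loss = final$l_fit,
              loss_history = loss_hist, zeta_history = zeta_hist,
              reconstruction = recon, setup = obs$setup)
  if (!is.null(truth)) out$errors <- l2_relative_error(recon, truth)
  structure(out, class = "g2phi_inference")
}

#' @export
print.g2phi_inference <- function(x, ...) {
  cat(sprintf("<g2phi_inference class=%d loss=%.3e zeta=(%s)>\n",
              x$class_index, x$loss,
              paste(sprintf("%.3f", x$zeta), collapse = ", ")))
  if (!is.null(x$errors))
    cat(sprintf("  rel. L2 error: theta %.3f%%, z %.3f%%\n",
                100 * x$errors[1L], 100 * x$errors[2L]))
  invisible(x)
}

#' Structured 3 x 3 boundary observations
#'
#' Nine observations on the uniform 3 x 3 lattice over the stretch domain
#' (corners, edge midpoints and centre), sparsely covering the domain
#' boundary so that reconstruction is mainly interpolation.  Values are
#' evaluated exactly from the specimen's analytic law (or fitted surface),
#' not interpolated from grid nodes.
#'
#' @param truth_obj a `sample_params`, [genotype_spec()] or fitted
#'   [energy_surface()].
#' @param domain stretch domain.
#' @param sigma0 normalisation constant (kPa).
#' @return an [observation_set()] with `m' = 9`, tagged `structured_3x3`.
#' @export
make_setup1_observations <- function(truth_obj, domain = .default_domain,
                                     sigma0 = 1) {
  g <- seq(domain[1], domain[2], length.out = 3)
  st <- cbind(lambda_theta = rep(g, each = 3), lambda_z = rep(g, times = 3))
  s <- if (inherits(truth_obj, "energy_surface")) {
    surface_stresses(truth_obj, st[, 1L], st[, 2L])
  } else {
    stress_from_energy(truth_obj, st[, 1L], st[, 2L])
  }
  observation_set(st, matrix(normalize_stress(as.vector(s), sigma0),
                             ncol = 2L), setup = "structured_3x3")
}

#' Unstructured protocol-path observations
#'
#' Thins a raw measurement record to `m'` points (stratified across the
#' seven protocols, seeded) and log-normalises the stresses.  The held-out
#' extrapolation region stays empty because the protocol paths never enter
#' it.
#'
#' @param record a `sample_record`.
#' @param m_prime number of observations (default 22).
#' @param seed integer seed for the subsampling.
#' @param sigma0 normalisation constant (kPa).
#' @return an [observation_set()] tagged `unstructured`.
#' @export
make_setup2_observations <- function(record, m_prime = 22, seed = 1L,
                                     sigma0 = 1) {
  sub <- subsample_record(record, m_prime = m_prime, seed = seed)
  st <- cbind(lambda_theta = sub$data$lambda_theta,
              lambda_z = sub$data$lambda_z)
  sn <- cbind(normalize_stress(sub$data$sigma_theta, sigma0),
              normalize_stress(sub$data$sigma_z, sigma0))
  observation_set(st, sn, setup = "unstructured")
}

#' Relative L2 error between stress grids
#'
#' Per normalised stress component:
#' \eqn{\|\mathrm{pred} - \mathrm{truth}\|_2 / \|\mathrm{truth}\|_2}.
#'
#' @param pred,truth [stress_grid()]s (or `(m, m, 2)` arrays) of matching
#'   shape.
#' @return named numeric vector `c(theta = ..., z = ...)`.
#' @export
l2_relative_error <- function(pred, truth) {
  P <- if (inherits(pred, "stress_grid")) pred$values else pred
  Tm <- if (inherits(truth, "stress_grid")) truth$values else truth
  if (!identical(dim(P), dim(Tm)))
    stop("l2_relative_error(): shape mismatch")
  out <- numeric(2L)
  for (c_ in 1:2) {
    nt <- sqrt(sum(Tm[, , c_]^2))
    if (nt == 0) stop("l2_relative_error(): zero-norm truth component")
    out[c_] <- sqrt(sum((P[, , c_] - Tm[, , c_])^2)) / nt
  }
  names(out) <- c("theta", "z")
  out
}
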