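# Learning-stage orchestration: mixup synthesis over genotype labels,
# seeded full-batch Adam training, late-stage checkpoint harvesting into
# ensembles, and stratified cross-validation folds.

#' Training configuration
#'
#' @param epochs training epochs (default 20000; scaled-down studies in the
#'   package use 2000).
#' @param lr Adam learning rate; decays on a cosine schedule to
#'   `lr_min_frac * lr` over the first `cosine_frac` of the run, then stays
#'   constant.
#' @param lr_min_frac,cosine_frac schedule shape parameters.
#' @param w_rec,w_reg learning-loss weights.
#' @param v_real,v_mix reconstruction-loss sample weights for real and
#'   mixup-synthesised samples.
#' @param eps reconstruction-loss stabiliser.
#' @param mixup_per_epoch mixup samples drawn per epoch; `NULL` means one
#'   per real training sample.
#' @param log_every history logging interval (epochs).
#' @param checkpoint_epochs epochs at which frozen decoder/trunk copies are
#'   stored for ensembling (late stage of the run).
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 20000, lr = 5e-3, lr_min_frac = 0.1,
                         cosine_frac = 0.8, w_rec = 1, w_reg = 0.02,
                         v_real = 1, v_mix = 0.5, eps = 0.01,
                         mixup_per_epoch = NULL, log_every = 100,
                         checkpoint_epochs = integer(0)) {
  stopifnot(epochs >= 1, lr > 0, w_rec >= 0, w_reg >= 0, eps > 0,
            v_real >= 0, v_mix >= 0, log_every >= 1)
  if (length(checkpoint_epochs))
    stopifnot(all(checkpoint_epochs >= 1), all(checkpoint_epochs <= epochs))
  structure(list(epochs = as.integer(epochs), lr = lr,
                 lr_min_frac = lr_min_frac, cosine_frac = cosine_frac,
                 w_rec = w_rec, w_reg = w_reg, v_real = v_real,
                 v_mix = v_mix, eps = eps,
                 mixup_per_epoch = mixup_per_epoch,
                 log_every = as.integer(log_every),
                 checkpoint_epochs = as.integer(sort(checkpoint_epochs))),
            class = "train_config")
}

#' Mixup-synthesise a training sample
#'
#' Convex combination of stress grids from distinct genotypes and of their
#' one-hot class features:
#' grid = sum_k alpha_k grid_k, zeta = sum_k alpha_k zeta_k.  The result's
#' class feature always lies on the probability simplex.  Grids are
#' combined on the normalised stress scale (the scale the branch encoder
#' consumes).
#'
#' @param grids list of `n0` normalised [stress_grid()]s (or arrays) from
#'   pairwise-distinct genotypes.
#' @param zetas matrix `(n0, d_zeta)` of class features (one-hot rows for
#'   real samples).
#' @param alpha `n0` nonnegative weights summing to 1.
#' @return list with elements `grid` (array) and `zeta` (simplex vector).
#' @export
mixup_generate <- function(grids, zetas, alpha) {
  n0 <- length(grids)
  stopifnot(n0 >= 2, is.matrix(zetas), nrow(zetas) == n0,
            length(alpha) == n0)
  if (any(alpha < 0) || abs(sum(alpha) - 1) > 1e-9)
    stop("mixup_generate(): alpha must be nonnegative and sum to 1")
  cls <- apply(zetas, 1L, which.max)
  if (anyDuplicated(cls))
    stop("mixup_generate(): samples must come from distinct genotypes")
  arrs <- lapply(grids, function(g)
    if (inherits(g, "stress_grid")) g$values else g)
  out <- arrs[[1L]] * alpha[1L]
  for (k in 2:n0) out <- out + arrs[[k]] * alpha[k]
  list(grid = out, zeta = as.vector(crossprod(zetas, alpha)))
}

#' Stratified cross-validation folds
#'
#' Partitions the samples into `k` test folds, stratified by genotype;
#' every sample appears in exactly one test fold.  Classes with fewer than
#' `k` samples are allowed (with a warning): their samples simply skip some
#' folds.
#'
#' @param labels genotype labels (vector, one per sample).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of `k` integer vectors of test indices.
#' @export
make_folds <- function(labels, k = 5, seed = 1L) {
  n <- length(labels)
  if (n == 0L) stop("make_folds(): empty dataset")
  stopifnot(k >= 2)
  tab <- table(labels)
  if (any(tab < k))
    warning("make_folds(): class(es) ",
            paste(names(tab)[tab < k], collapse = ", "),
            " have fewer samples than folds; stratification degrades")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  fold_of <- integer(n)
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold_of[idx] <- rep_len(sample(seq_len(k)), length(idx))
  }
  lapply(seq_len(k), function(f) which(fold_of == f))
}

#' Simulate a genotype-classed training cohort
#'
#' Draws specimen populations from each genotype spec, and attaches to each
#' specimen its ground-truth normalised stress grid and (optionally) its
#' raw seven-protocol measurement record.
#'
#' @param specs named list of [genotype_spec()]s (default the four-class
#'   preset battery).
#' @param n_per_class specimens per class, recycled over classes.
#' @param seed integer seed.
#' @param m grid size.
#' @param points_per_path protocol path resolution.
#' @param noise_cv measurement noise (relative std) for the records.
#' @param with_records generate raw protocol records too (default TRUE).
#' @param domain stretch domain.
#' @return list of specimen entries, each with `sample_id`, `genotype`,
#'   `genotype_index`, `params`, `grid` and optionally `record`.
#' @export
simulate_cohort <- function(specs = genotype_presets(), n_per_class = 8,
                            seed = 1L, m = 31, points_per_path = 25,
                            noise_cv = 0.02, with_records = TRUE,
                            domain = .default_domain) {
  n_per_class <- rep_len(n_per_class, length(specs))
  out <- list()
  for (ci in seq_along(specs)) {
    pops <- sample_population(specs[[ci]], n_per_class[ci],
                              seed = seed + 1000L * ci,
                              genotype_index = ci)
    for (si in seq_along(pops)) {
      p <- pops[[si]]
      entry <- list(sample_id = p$sample_id, genotype = p$genotype,
                    genotype_index = ci, params = p,
                    grid = generate_grid_truth(p, m = m, domain = domain))
      if (with_records) {
        protos <- canonical_protocols(points_per_path = points_per_path,
                                      noise_cv = noise_cv)
        entry$record <- generate_protocol_record(
          p, protos, seed = seed + 1000L * ci + si, domain = domain)
      }
      out[[length(out) + 1L]] <- entry
    }
  }
  out
}

# stack cohort grids into truth matrices (m^2, N) per stress component
.cohort_truth <- function(samples) {
  m <- samples[[1L]]$grid$m
  Gt <- vapply(samples, function(s) as.vector(s$grid$values[, , 1L]),
               numeric(m^2))
  Gz <- vapply(samples, function(s) as.vector(s$grid$values[, , 2L]),
               numeric(m^2))
  list(theta = Gt, z = Gz, m = m)
}

#' Train the learning stage
#'
#' Full-batch Adam minimisation of the learning loss (weighted
#' reconstruction + latent regularisation) over encoder, decoder and trunk
#' weights, on the real training grids plus freshly drawn mixup samples
#' each epoch (symmetric Dirichlet(1) weights over one sample per
#' genotype).  Deterministic given `seed`.
#'
#' @param samples training cohort entries (see [simulate_cohort()]); each
#'   needs `grid` and `genotype_index`.
#' @param config a [train_config()].
#' @param model_config a [g2phi_config()].
#' @param seed integer seed (weight init + mixup draws).
#' @return object of class `g2phi_fit`: trained `params`, `history` data
#'   frame (`epoch`, `l_rec`, `l_reg`, `l_total`), `checkpoints` (list of
#'   frozen decoder/trunk copies keyed by epoch) and provenance.
#' @export
train_learning_stage <- function(samples, config = train_config(),
                                 model_config = g2phi_config(), seed = 1L) {
  stopifnot(length(samples) >= 1L, inherits(config, "train_config"),
            inherits(model_config, "g2phi_config"))
  n_real <- length(samples)
  d_zeta <- model_config$d_zeta
  m <- model_config$m
  gidx <- vapply(samples, function(s) s$genotype_index, numeric(1))
  if (max(gidx) > d_zeta)
    stop("train_learning_stage(): genotype index exceeds d_zeta")
  by_class <- lapply(seq_len(d_zeta), function(ci) which(gidx == ci))
  n_classes_present <- sum(vapply(by_class, length, numeric(1)) > 0)
  truth <- .cohort_truth(samples)
  if (truth$m != m) stop("grid size does not match model_config$m")
  Z_real <- matrix(0, n_real, d_zeta)
  Z_real[cbind(seq_len(n_real), gidx)] <- 1
  X_real <- grids_to_inputs(lapply(samples, function(s) s$grid))
  # standardise the encoder input (normalised stresses span ~[0, 6], which
  # would saturate the tanh conv stack); constants are stored in the model
  in_center <- mean(X_real)
  in_scale <- max(stats::sd(X_real), 1e-8)
  X_real <- (X_real - in_center) / in_scale

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  params <- .init_params_local(model_config)
  params$input_center <- in_center
  params$input_scale <- in_scale
  tr <- .trainable(params)
  skeleton <- tr
  theta <- nn_pack(tr)
  opt <- adam_init(length(theta))

  n_mix <- if (is.null(config$mixup_per_epoch)) n_real
           else config$mixup_per_epoch
  can_mix <- n_classes_present >= 2 && n_mix > 0
  grid_pts <- grid_stretches(m, model_config$domain)
  hist_rows <- list()
  checkpoints <- list()
  v <- c(rep(config$v_real, n_real), rep(config$v_mix, if (can_mix) n_mix else 0))

  for (epoch in seq_len(config$epochs)) {
    if (can_mix) {
      present <- which(vapply(by_class, length, numeric(1)) > 0)
      pick <- vapply(present, function(ci) {
        idx <- by_class[[ci]]
        idx[sample.int(length(idx), n_mix, replace = TRUE)]
      }, numeric(n_mix))
      pick <- matrix(pick, nrow = n_mix)
      alpha <- matrix(stats::rgamma(n_mix * length(present), 1), n_mix)
      alpha <- alpha / rowSums(alpha)
      X_mix <- matrix(0, n_mix, ncol(X_real))
      Z_mix <- matrix(0, n_mix, d_zeta)
      Gt_mix <- matrix(0, m^2, n_mix); Gz_mix <- matrix(0, m^2, n_mix)
      for (jj in seq_along(present)) {
        sel <- pick[, jj]
        X_mix <- X_mix + alpha[, jj] * X_real[sel, , drop = FALSE]
        Z_mix[, present[jj]] <- Z_mix[, present[jj]] + alpha[, jj]
        aw <- rep(alpha[, jj], each = nrow(Gt_mix))
        Gt_mix <- Gt_mix + truth$theta[, sel, drop = FALSE] * aw
        Gz_mix <- Gz_mix + truth$z[, sel, drop = FALSE] * aw
      }
      X <- rbind(X_real, X_mix)
      Z <- rbind(Z_real, Z_mix)
      Gt <- cbind(truth$theta, Gt_mix); Gz <- cbind(truth$z, Gz_mix)
    } else {
      X <- X_real; Z <- Z_real; Gt <- truth$theta; Gz <- truth$z
    }
    N <- nrow(X)

    tr <- nn_unpack(theta, skeleton)
    params <- .set_trainable(params, tr)
    fb <- .learning_forward_backward(params, X, Z, Gt, Gz, grid_pts, v,
                                     config)
    if (!is.finite(fb$l_total)) {
      history <- do.call(rbind, hist_rows)
      stop(structure(class = c("g2phi_divergence", "error", "condition"),
                     list(message = sprintf(
                       "training diverged at epoch %d (non-finite loss)",
                       epoch), call = sys.call(-1), history = history)))
    }
    lr <- lr_schedule(epoch - 1L, config$epochs, config$lr,
                      config$lr_min_frac, config$cosine_frac)
    stp <- adam_step(opt, theta, fb$grad, lr)
    theta <- stp$theta; opt <- stp$state

    if (epoch %% config$log_every == 0L || epoch == 1L ||
        epoch == config$epochs) {
      hist_rows[[length(hist_rows) + 1L]] <-
        data.frame(epoch = epoch, l_rec = fb$l_rec, l_reg = fb$l_reg,
                   l_total = fb$l_total)
    }
    if (epoch %in% config$checkpoint_epochs) {
      trc <- nn_unpack(theta, skeleton)
      checkpoints[[as.character(epoch)]] <-
        list(decoder = trc$decoder, trunk = trc$trunk, b0 = trc$b0,
             epoch = epoch)
    }
  }
  params <- .set_trainable(params, nn_unpack(theta, skeleton))
  structure(list(params = params, history = do.call(rbind, hist_rows),
                 checkpoints = checkpoints, seed = as.integer(seed),
                 config = config, model_config = model_config,
                 n_train = n_real),
            class = "g2phi_fit")
}

# parameter init that consumes the already-seeded RNG stream
.init_params_local <- function(config) {
  enc <- nn_encoder_init(config$m, in_ch = 2L,
                         channels = config$enc_channels,
                         d_out = config$d_eta)
  dec <- nn_mlp_init(c(config$d_zeta + config$d_eta,
                       rep(config$hidden, config$depth), 2L * config$p))
  trk <- nn_mlp_init(c(2L, rep(config$hidden, config$depth), 2L * config$p))
  structure(list(config = config, encoder = enc, decoder = dec, trunk = trk,
                 b0 = c(theta = 0, z = 0),
                 input_center = 0, input_scale = 1,
                 init_seed = NA_integer_),
            class = "g2phi_params")
}

# One full forward/backward pass of the learning loss.  X: (N, m*m*2)
# encoder inputs; Z: (N, d_zeta); Gt, Gz: (m^2, N) truth per component;
# grid_pts: (m^2, 2) stretch lattice; v: per-sample weights.
.learning_forward_backward <- function(params, X, Z, Gt, Gz, grid_pts, v,
                                       config) {
  cfg <- params$config
  N <- nrow(X); m2 <- nrow(Gt); p <- cfg$p
  enc_f <- nn_encoder_forward(params$encoder, X)
  H <- enc_f$out                                        # (N, d_eta)
  dec_f <- nn_mlp_forward(params$decoder, cbind(Z, H))
  B <- dec_f$out                                        # (N, 2p)
  Bt <- B[, seq_len(p), drop = FALSE]
  Bz <- B[, p + seq_len(p), drop = FALSE]
  trk_f <- nn_mlp_forward(params$trunk,
                          .scale_stretch(grid_pts, cfg$domain))
  Tt <- trk_f$out[, seq_len(p), drop = FALSE]           # (m^2, p)
  Tz <- trk_f$out[, p + seq_len(p), drop = FALSE]
  Pt <- Tt %*% t(Bt) + params$b0[["theta"]]             # (m^2, N)
  Pz <- Tz %*% t(Bz) + params$b0[["z"]]

  Dt <- Pt - Gt; Dz <- Pz - Gz
  Wt <- 1 / abs(Gt + config$eps); Wz <- 1 / abs(Gz + config$eps)
  per_sample <- colSums(Dt^2 * Wt) + colSums(Dz^2 * Wz)
  l_rec <- sum(v * per_sample) / (m2 * N)
  l_reg <- if (N >= 2) latent_regularization(H) else 0
  l_total <- learning_loss(l_rec, l_reg, config$w_rec, config$w_reg)

  # backward
  sc <- config$w_rec / (m2 * N)
  vw <- rep(v * sc, each = m2)
  dPt <- 2 * Dt * Wt * vw
  dPz <- 2 * Dz * Wz * vw
  dBt <- crossprod(dPt, Tt); dBz <- crossprod(dPz, Tz)  # (N, p)
  dTt <- dPt %*% Bt; dTz <- dPz %*% Bz                  # (m^2, p)
  db0 <- c(theta = sum(dPt), z = sum(dPz))
  dec_b <- nn_mlp_backward(params$decoder, dec_f, cbind(dBt, dBz))
  trk_b <- nn_mlp_backward(params$trunk, trk_f, cbind(dTt, dTz))
  dH <- dec_b$dX[, cfg$d_zeta + seq_len(cfg$d_eta), drop = FALSE]
  if (config$w_reg > 0 && N >= 2)
    dH <- dH + config$w_reg * .latent_reg_grad(H)
  enc_b <- nn_encoder_backward(params$encoder, enc_f$cache, dH)

  grad <- nn_pack(list(encoder = enc_b$grads,
                       decoder = list(W = dec_b$W, b = dec_b$b),
                       trunk = list(W = trk_b$W, b = trk_b$b),
                       b0 = db0))
  list(l_rec = l_rec, l_reg = l_reg, l_total = l_total, grad = grad)
}

# learning loss as a function of the packed parameter vector (used by the
# finite-difference gradient checks in the test suite)
.learning_loss_at <- function(theta, skeleton, params, X, Z, Gt, Gz,
                              grid_pts, v, config) {
  params <- .set_trainable(params, nn_unpack(theta, skeleton))
  fb <- .learning_forward_backward(params, X, Z, Gt, Gz, grid_pts, v, config)
  fb$l_total
}

#' Harvest an ensemble from training runs
#'
#' Collects `K = K1 * K2` frozen (branch decoder, trunk net) copies from
#' `K1` independent training runs and `K2` late-stage checkpoint epochs
#' (plus optionally the final weights).  Encoder weights are dropped:
#' inference never uses the branch encoder.
#'
#' @param fits list of `g2phi_fit` objects (the `K1` seeded runs).
#' @param checkpoint_epochs epochs to harvest from each run; `NULL` takes
#'   the final trained weights only.
#' @return object of class `g2phi_ensemble` with elements `members` (each
#'   carrying `decoder`, `trunk`, `b0` and provenance `(seed, epoch)`) and
#'   the shared dimensions.
#' @export
harvest_ensemble <- function(fits, checkpoint_epochs = NULL) {
  if (inherits(fits, "g2phi_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L)
  cfg <- fits[[1L]]$model_config
  members <- list()
  for (fit in fits) {
    if (is.null(checkpoint_epochs)) {
      tr <- .trainable(fit$params)
      members[[length(members) + 1L]] <-
        list(decoder = tr$decoder, trunk = tr$trunk, b0 = tr$b0,
             provenance = list(seed = fit$seed, epoch = fit$config$epochs))
    } else {
      for (ep in checkpoint_epochs) {
        key <- as.character(ep)
        if (is.null(fit$checkpoints[[key]]))
          stop(sprintf("missing checkpoint (seed %d, epoch %d)",
                       fit$seed, ep))
        ck <- fit$checkpoints[[key]]
        members[[length(members) + 1L]] <-
          list(decoder = ck$decoder, trunk = ck$trunk, b0 = ck$b0,
               provenance = list(seed = fit$seed, epoch = ck$epoch))
      }
    }
  }
  structure(list(members = members, config = cfg, K = length(members)),
            class = "g2phi_ensemble")
}

#' @export
print.g2phi_ensemble <- function(x, ...) {
  cat(sprintf("<g2phi_ensemble K=%d members, d_eta=%d, d_zeta=%d>\n",
              x$K, x$config$d_eta, x$config$d_zeta))
  invisible(x)
}
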