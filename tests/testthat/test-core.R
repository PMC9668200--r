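# Core architecture: sub-network contracts, inner-product prediction,
# losses and their closed forms, gradients, serialization.

test_that("branch encoder is deterministic, sensitive and dimension-correct", {
  coh <- tiny_cohort()
  for (de in c(2L, 4L, 6L)) {
    params <- g2phi_init(tiny_model_config(d_eta = de), seed = 1)
    eta <- branch_encode(params, coh[[1]]$grid)
    expect_identical(dim(eta), c(1L, de))
    expect_identical(branch_encode(params, coh[[1]]$grid), eta)
  }
  params <- g2phi_init(tiny_model_config(), seed = 1)
  g2 <- coh[[1]]$grid
  g2$values[4, 5, 1] <- g2$values[4, 5, 1] + 0.1
  expect_false(identical(branch_encode(params, g2),
                         branch_encode(params, coh[[1]]$grid)))
  # batch encoding equals per-sample encoding
  etas <- branch_encode(params, lapply(coh[1:3], function(s) s$grid))
  expect_equal(etas[2, , drop = FALSE], branch_encode(params, coh[[2]]$grid),
               tolerance = 1e-12)
  expect_error(branch_encode(params, stress_grid(array(0, c(5, 5, 2)))),
               "grid size")
})

test_that("branch decoder accepts interior simplex points and is smooth", {
  params <- g2phi_init(g2phi_config(m = 9, p = 8, d_eta = 3, d_zeta = 4,
                                    enc_channels = c(3, 4), hidden = 16,
                                    depth = 2), seed = 2)
  zeta <- c(0.1, 0.3, 0.0, 0.6)  # mixup-interior class feature
  eta <- c(0.5, -1, 0.2)
  b <- branch_decode(params, zeta, eta)
  expect_identical(dim(b$b_theta), c(1L, 8L))
  expect_identical(dim(b$b_z), c(1L, 8L))
  d <- 1e-6
  b2 <- branch_decode(params, zeta + c(d, -d, 0, 0), eta)
  expect_lt(max(abs(b2$b_theta - b$b_theta)), 100 * d)
  expect_error(branch_decode(params, c(1, 0), eta))
})

test_that("trunk net vectorises over stretch states", {
  params <- g2phi_init(tiny_model_config(), seed = 3)
  st <- grid_stretches(31)
  t1 <- trunk_eval(params, st)
  expect_identical(dim(t1$t_theta), c(961L, 4L))
  expect_identical(dim(t1$t_z), c(961L, 4L))
  single <- trunk_eval(params, st[17, ])
  expect_equal(t1$t_theta[17, , drop = FALSE], single$t_theta,
               tolerance = 1e-12)
  expect_identical(trunk_eval(params, st)$t_z, t1$t_z)
})

test_that("prediction equals the explicit inner-product summation", {
  for (p_dim in c(1L, 8L, 64L)) {
    params <- g2phi_init(g2phi_config(m = 9, p = p_dim, d_eta = 2,
                                      d_zeta = 3, enc_channels = c(3, 4),
                                      hidden = 8, depth = 2), seed = p_dim)
    params$b0 <- c(theta = 0.7, z = -0.2)
    zeta <- c(0.2, 0.5, 0.3); eta <- c(0.1, -0.4)
    st <- matrix(c(1.3, 1.5, 1.1, 1.2), 2, byrow = TRUE)
    pred <- predict_stress(params, zeta, eta, st)
    b <- branch_decode(params, zeta, eta)
    tk <- trunk_eval(params, st)
    for (r in 1:2) {
      acc_t <- 0; acc_z <- 0
      for (i in seq_len(p_dim)) {  # brute-force summation oracle
        acc_t <- acc_t + b$b_theta[1, i] * tk$t_theta[r, i]
        acc_z <- acc_z + b$b_z[1, i] * tk$t_z[r, i]
      }
      expect_equal(unname(pred[r, 1]), acc_t + 0.7, tolerance = 1e-12)
      expect_equal(unname(pred[r, 2]), acc_z - 0.2, tolerance = 1e-12)
    }
  }
})

test_that("reconstruction loss reproduces hand-computed values", {
  # single grid point, single sample, eps = 0.01: both components off by 1
  pred <- array(2, c(1, 1, 2)); truth <- array(1, c(1, 1, 2))
  expect_equal(reconstruction_loss(pred, truth, v = 1, eps = 0.01),
               2 / 1.01, tolerance = 1e-12)
  # exact match -> 0
  expect_identical(reconstruction_loss(truth, truth), 0)
  # doubling v doubles the sample's contribution
  expect_equal(reconstruction_loss(pred, truth, v = 2, eps = 0.01),
               4 / 1.01, tolerance = 1e-12)
  # batch version averages over samples
  P <- array(c(rep(2, 2), rep(1, 2)), c(1, 1, 2, 2))
  Tr <- array(1, c(1, 1, 2, 2))
  expect_equal(reconstruction_loss(P, Tr, v = c(1, 1), eps = 0.01),
               (2 / 1.01 + 0) / 2, tolerance = 1e-12)
  expect_error(reconstruction_loss(array(0, c(2, 2, 2)),
                                   array(0, c(3, 3, 2))), "shape")
})

test_that("latent regulariser has the stated closed forms and nonnegativity", {
  # exact standard batch: mean 0, covariance I (whitened construction)
  set.seed(6)
  for (d in c(2L, 4L)) {
    H <- matrix(rnorm(40 * d), 40, d)
    H <- sweep(H, 2, colMeans(H))
    H <- H %*% solve(chol(cov(H)))
    expect_equal(latent_regularization(H), 0, tolerance = 1e-9)
    # scaled: Sigma = 2I, mu = 0 -> (d/2)(2 - 1 - log 2) i.e. for d = 2:
    # 0.5 * (4 - 2 - log 4)
    expect_equal(latent_regularization(sqrt(2) * H),
                 0.5 * (2 * d - d - d * log(2)), tolerance = 1e-9)
  }
  # d = 1 analogue via the diagonal fallback: mu = 1, var = 1 -> 0.5
  H1 <- matrix(c(0, 2), 2, 1) / sqrt(2) + (1 - 1 / sqrt(2))
  expect_equal(apply(H1, 2, mean), 1, tolerance = 1e-12)
  expect_equal(apply(H1, 2, var), 1, tolerance = 1e-12)
  expect_equal(latent_regularization(H1), 0.5, tolerance = 1e-9)
  # nonnegativity over random valid batches
  set.seed(7)
  for (rep in 1:200) {
    H <- matrix(rnorm(12 * 3, sd = runif(1, 0.3, 3)), 12, 3)
    expect_gte(latent_regularization(H), -1e-12)
  }
  # near-singular batches are jittered, never -Inf
  Hs <- cbind(rnorm(10), 0, 0)
  expect_true(is.finite(latent_regularization(Hs)))
})

test_that("learning loss combines terms linearly", {
  expect_equal(learning_loss(2, 3, w_rec = 1, w_reg = 0), 2)
  expect_identical(learning_loss(0, 0), 0)
  expect_equal(learning_loss(2, 3, w_rec = 0.5, w_reg = 2), 7)
})

test_that("backpropagated gradients match finite differences", {
  set.seed(5)
  mc <- tiny_model_config()
  coh <- tiny_cohort()
  tc <- train_config(epochs = 1, w_reg = 0.1, v_mix = 0.5)
  params <- g2phinet:::.init_params_local(mc)
  truth <- g2phinet:::.cohort_truth(coh)
  N <- length(coh)
  gidx <- vapply(coh, function(s) s$genotype_index, numeric(1))
  Z <- matrix(0, N, 3); Z[cbind(seq_len(N), gidx)] <- 1
  X <- g2phinet:::grids_to_inputs(lapply(coh, function(s) s$grid))
  gp <- grid_stretches(9)
  v <- rep(c(1, 0.5), length.out = N)
  tr <- g2phinet:::.trainable(params)
  theta <- g2phinet:::nn_pack(tr)
  fb <- g2phinet:::.learning_forward_backward(params, X, Z, truth$theta,
                                              truth$z, gp, v, tc)
  idx <- sample(length(theta), 40)
  h <- 1e-5
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (g2phinet:::.learning_loss_at(tp, tr, params, X, Z, truth$theta,
                                  truth$z, gp, v, tc) -
       g2phinet:::.learning_loss_at(tm, tr, params, X, Z, truth$theta,
                                    truth$z, gp, v, tc)) / (2 * h)
  }, numeric(1))
  rel <- abs(num - fb$grad[idx]) / pmax(abs(num), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("model serialization restores bit-identical predictions", {
  fit <- tiny_fit()
  path <- withr::local_tempfile(fileext = ".rds")
  save_g2phi(fit$params, path)
  restored <- load_g2phi(path)
  st <- grid_stretches(9)
  zeta <- c(1, 0, 0); eta <- c(0.3, -0.2)
  expect_identical(predict_stress(restored, zeta, eta, st),
                   predict_stress(fit$params, zeta, eta, st))
  eta2 <- branch_encode(restored, tiny_cohort()[[1]]$grid)
  expect_identical(eta2, branch_encode(fit$params, tiny_cohort()[[1]]$grid))
})
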