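# Inference stage: ensemble averaging, fitting loss, regularisers,
# simplex-constrained optimisation and observation builders.

test_that("ensemble prediction equals the brute-force member mean", {
  fit <- tiny_fit()
  ens <- harvest_ensemble(list(fit), checkpoint_epochs = c(40, 60))
  st <- grid_stretches(5)
  zeta <- c(0.2, 0.3, 0.5)
  etas <- matrix(c(0.1, -0.2, 0.4, 0.3), 2, 2, byrow = TRUE)
  pred <- ensemble_predict(ens, zeta, etas, st)
  acc <- matrix(0, nrow(st), 2)
  for (i in 1:2) {  # explicit loop over members
    one <- harvest_ensemble(list(fit),
                            checkpoint_epochs = ens$members[[i]]$provenance$epoch)
    acc <- acc + ensemble_predict(one, zeta, etas[i, , drop = FALSE], st)
  }
  expect_equal(pred, acc / 2, tolerance = 1e-12, ignore_attr = TRUE)
  # identical members with identical etas collapse to one member
  same <- ens; same$members[[2]] <- same$members[[1]]
  p1 <- ensemble_predict(harvest_ensemble(list(fit),
                                          checkpoint_epochs = 40),
                         zeta, etas[1, , drop = FALSE], st)
  p2 <- ensemble_predict(same, zeta, rbind(etas[1, ], etas[1, ]), st)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("fitting loss matches its hand-computed single-point value", {
  fit <- tiny_fit()
  ens <- harvest_ensemble(list(fit))
  # one observation; make predictions differ from truth by a known delta
  st <- matrix(c(1.3, 1.4), 1)
  pred <- ensemble_predict(ens, c(1, 0, 0), c(0, 0), st)
  delta <- 0.05
  obs <- observation_set(st, pred - delta)
  got <- fitting_loss(ens, c(1, 0, 0), c(0, 0), obs, eps = 0.01)
  want <- sum(delta^2 / abs(pred - delta + 0.01))
  expect_equal(got, want, tolerance = 1e-12)
  # exact observations give zero loss, and order does not matter
  st3 <- rbind(c(1.1, 1.2), c(1.5, 1.3), c(1.2, 1.6))
  pr3 <- ensemble_predict(ens, c(1, 0, 0), c(0, 0), st3)
  obs3 <- observation_set(st3, pr3)
  expect_equal(fitting_loss(ens, c(1, 0, 0), c(0, 0), obs3), 0,
               tolerance = 1e-15)
  perm <- c(3, 1, 2)
  obs3p <- observation_set(st3[perm, ], pr3[perm, ])
  delta3 <- pr3 * 1.1
  expect_equal(fitting_loss(ens, c(0, 1, 0), c(1, 1), obs3),
               fitting_loss(ens, c(0, 1, 0), c(1, 1),
                            observation_set(st3[perm, ], pr3[perm, ])),
               tolerance = 1e-12)
})

test_that("the sample-feature regulariser has its closed-form values", {
  expect_identical(eta_regularizer(c(0, 0)), 0)
  expect_equal(eta_regularizer(c(1, 0)), 1, tolerance = 1e-12)
  expect_equal(eta_regularizer(c(1, 1)), 4, tolerance = 1e-12)  # (sqrt2)^4
  expect_equal(eta_regularizer(c(1, 1), mode = "sum_quartic"), 2,
               tolerance = 1e-12)
  # per-member mean over an ensemble
  expect_equal(eta_regularizer(rbind(c(1, 0), c(1, 1))), 2.5,
               tolerance = 1e-12)
})

test_that("classification takes the largest component with low-index ties", {
  expect_identical(classify(c(0.1, 0.3, 0.0, 0.6)), 4L)
  expect_identical(classify(c(0, 1, 0, 0)), 2L)
  expect_identical(classify(c(0.5, 0.5, 0, 0)), 1L)
  # invariance under positive rescaling of the logits
  z <- c(0.4, -1, 2, 0.3)
  for (s in c(0.5, 1, 3)) {
    zeta <- exp(s * z) / sum(exp(s * z))
    expect_identical(classify(zeta), 3L)
  }
})

test_that("structured 3x3 observations sit on the boundary lattice", {
  p <- sample_population(genotype_presets()[[2]], 1, seed = 3)[[1]]
  obs <- make_setup1_observations(p)
  expect_identical(obs$m_prime, 9L)
  expect_identical(obs$setup, "structured_3x3")
  # all four domain corners present
  corners <- expand.grid(c(1, 1.65), c(1, 1.65))
  for (r in seq_len(4)) {
    hit <- any(abs(obs$stretches[, 1] - corners[r, 1]) < 1e-12 &
                 abs(obs$stretches[, 2] - corners[r, 2]) < 1e-12)
    expect_true(hit)
  }
  # values equal the normalised analytic stresses at the lattice
  s <- stress_from_energy(p, obs$stretches[, 1], obs$stretches[, 2])
  expect_equal(obs$stresses,
               matrix(normalize_stress(as.vector(s)), ncol = 2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("unstructured observations avoid the held-out region, seeded", {
  p <- sample_population(genotype_presets()[[4]], 1, seed = 2)[[1]]
  rec <- generate_protocol_record(p, canonical_protocols(), seed = 1)
  obs <- make_setup2_observations(rec, m_prime = 22, seed = 11)
  expect_identical(obs$m_prime, 22L)
  expect_false(any(in_heldout_region(obs$stretches[, 1],
                                     obs$stretches[, 2])))
  obs2 <- make_setup2_observations(rec, m_prime = 22, seed = 11)
  expect_identical(obs$stretches, obs2$stretches)
  expect_error(make_setup2_observations(rec, m_prime = 1000), "observations")
})

test_that("relative L2 error has exact homogeneity and matches brute force", {
  set.seed(14)
  a <- stress_grid(array(rnorm(50), c(5, 5, 2)))
  expect_equal(unname(l2_relative_error(a, a)), c(0, 0))
  b <- a; b$values <- 1.1 * a$values
  expect_equal(unname(l2_relative_error(b, a)), c(0.1, 0.1),
               tolerance = 1e-12)
  c_ <- stress_grid(array(rnorm(50), c(5, 5, 2)))
  got <- l2_relative_error(c_, a)
  for (k in 1:2) {
    expect_equal(unname(got[k]),
                 sqrt(sum((c_$values[, , k] - a$values[, , k])^2)) /
                   sqrt(sum(a$values[, , k]^2)), tolerance = 1e-12)
  }
  expect_error(l2_relative_error(a, stress_grid(array(0.1, c(4, 4, 2)))),
               "shape")
})

test_that("inference starts at the canonical initial point and stays on the simplex", {
  fit <- tiny_fit()
  ens <- harvest_ensemble(list(fit), checkpoint_epochs = c(40, 60))
  # observations generated by the frozen ensemble at a known feature pair;
  # an interior class feature is exactly representable by finite logits,
  # so recovery must be near machine precision
  zstar <- c(0.15, 0.7, 0.15)
  etastar <- matrix(c(0.4, -0.3, -0.1, 0.5), 2, 2, byrow = TRUE)
  g <- seq(1, 1.65, length.out = 3)
  st <- cbind(rep(g, each = 3), rep(g, 3))
  obs <- observation_set(st, ensemble_predict(ens, zstar, etastar, st),
                         setup = "structured_3x3")
  res <- infer_sample(ens, obs, iters = 1200, reconstruct_m = 9)
  # the first recorded zeta is the uniform initialisation
  expect_equal(res$zeta_history[[1]], rep(1 / 3, 3), tolerance = 1e-9)
  # simplex invariant at every recorded iterate
  for (zt in res$zeta_history) {
    expect_true(min(zt) >= 0)
    expect_lt(abs(sum(zt) - 1), 1e-9)
  }
  # self-consistency recovery
  expect_lt(res$fit_loss, 1e-6)
  expect_identical(res$class_index, 2L)
})

test_that("the eta regulariser shrinks fitted sample features", {
  fit <- tiny_fit()
  ens <- harvest_ensemble(list(fit))
  p <- tiny_cohort()[[3]]
  rec_p <- tiny_cohort(with_records = TRUE)[[3]]
  obs <- make_setup2_observations(rec_p$record, m_prime = 15, seed = 4)
  norms <- sapply(c(0, 0.05), function(w) {
    r <- infer_sample(ens, obs, w_reg2 = w, iters = 500, reconstruct_m = 9)
    sqrt(mean(rowSums(r$etas^2)))
  })
  expect_lte(norms[2], norms[1] + 1e-8)
})
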