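# Synthetic constitutive-data generator: analytic law, population
# sampling, grids and protocol records.

test_that("strain energy vanishes at the reference state and is nonnegative", {
  for (spec in genotype_presets()) {
    p <- sample_population(spec, 1, seed = 3)[[1]]
    expect_identical(strain_energy(p, 1, 1), 0)
    st <- grid_stretches(7)
    expect_true(all(strain_energy(p, st[, 1], st[, 2]) >= 0))
  }
})

test_that("a fiber family at unit stretch contributes no energy", {
  # circumferential fiber is unstretched when lambda_theta = 1
  spec <- genotype_spec("one_fiber", c_iso = 1e-12,
                        fiber_c1 = c(0, 5, 0, 0), fiber_c2 = c(0, 2, 0, 0),
                        sample_cv = 0)
  expect_equal(strain_energy(spec, 1, 1.5), 0, tolerance = 1e-9)
})

test_that("zero stiffening exponent falls back to the quadratic limit", {
  spec <- genotype_spec("quad", c_iso = 1e-12, fiber_c1 = c(4, 0, 0, 0),
                        fiber_c2 = rep(0, 4), sample_cv = 0)
  # axial fiber: lambda_i = lambda_z; W = (c1/4)(lz^2-1)^2
  lz <- 1.3
  expect_equal(strain_energy(spec, 1, lz), 4 / 4 * (lz^2 - 1)^2,
               tolerance = 1e-9)
})

test_that("energy matches an independent evaluation of the constitutive law", {
  # independent oracle: direct transcription of the law, written separately
  oracle <- function(p, lt, lz) {
    I1 <- lt^2 + lz^2 + lt^-2 * lz^-2
    w <- p$c_iso / 2 * (I1 - 3)
    for (i in 1:4) {
      li2 <- lt^2 * sin(p$fiber_angle[i])^2 + lz^2 * cos(p$fiber_angle[i])^2
      w <- w + p$fiber_c1[i] / (4 * p$fiber_c2[i]) *
        (exp(p$fiber_c2[i] * (li2 - 1)^2) - 1)
    }
    w
  }
  set.seed(8)
  for (rep in 1:20) {
    p <- sample_population(genotype_presets()[[sample(4, 1)]], 1,
                           seed = sample(1e6, 1))[[1]]
    lt <- runif(1, 1.0, 1.65); lz <- runif(1, 1.0, 1.65)
    expect_equal(strain_energy(p, lt, lz), oracle(p, lt, lz),
                 tolerance = 1e-12)
  }
})

test_that("stresses are zero at reference and match the neo-Hookean closed form", {
  p <- sample_population(genotype_presets()[[2]], 1, seed = 5)[[1]]
  expect_equal(unname(stress_from_energy(p, 1, 1)[1, ]), c(0, 0),
               tolerance = 1e-12)
  iso <- genotype_spec("iso", c_iso = 25, fiber_c1 = rep(0, 4),
                       fiber_c2 = rep(0, 4), sample_cv = 0)
  s <- stress_from_energy(iso, 1.2, 1.0)
  expect_equal(unname(s[1, "sigma_theta"]), 25 * (1.2^2 - 1.2^-2),
               tolerance = 1e-10)
  expect_equal(unname(s[1, "sigma_z"]), 25 * (1 - 1.2^-2),
               tolerance = 1e-10)
})

test_that("analytic stresses match finite differences of the energy", {
  set.seed(21)
  for (rep in 1:100) {
    all5 <- genotype_presets(c("hBAC-mWT", "Fbn1mgR", "Fbln5KO",
                                "hBAC-mNull", "WT"))
    spec <- all5[[sample(5, 1)]]
    p <- sample_population(spec, 1, seed = sample(1e6, 1))[[1]]
    lt <- runif(1, 1.02, 1.6); lz <- runif(1, 1.02, 1.6)
    s <- stress_from_energy(p, lt, lz)
    h <- 1e-6
    fd_t <- lt * (strain_energy(p, lt + h, lz) -
                    strain_energy(p, lt - h, lz)) / (2 * h)
    fd_z <- lz * (strain_energy(p, lt, lz + h) -
                    strain_energy(p, lt, lz - h)) / (2 * h)
    expect_equal(unname(s[1, 1]), fd_t, tolerance = 1e-5)
    expect_equal(unname(s[1, 2]), fd_z, tolerance = 1e-5)
  }
})

test_that("circumferential stress stiffens monotonically in lambda_theta", {
  lt <- seq(1.0, 1.65, length.out = 80)
  for (spec in genotype_presets()) {
    for (lz in c(1.0, 1.3, 1.65)) {
      s <- stress_from_energy(spec, lt, lz)[, "sigma_theta"]
      expect_true(all(diff(s) > 0))
    }
  }
})

test_that("population sampling is seeded, mean-one and respects sample_cv", {
  spec <- genotype_presets()[["Fbln5KO"]]
  a <- sample_population(spec, 4, seed = 9)
  b <- sample_population(spec, 4, seed = 9)
  expect_identical(a, b)
  # zero spread: all specimens identical to the class centre
  spec0 <- genotype_spec("z", 20, c(1, 1, 1, 1), c(1, 1, 1, 1),
                         sample_cv = 0)
  pop0 <- sample_population(spec0, 3, seed = 1)
  expect_true(all(vapply(pop0, function(p) p$c_iso, numeric(1)) == 20))
  # Monte-Carlo moment check at cv = 0.1
  spec1 <- genotype_spec("m", 20, c(1, 1, 1, 1), c(1, 1, 1, 1),
                         sample_cv = 0.1)
  pop <- sample_population(spec1, 10000, seed = 2)
  ciso <- vapply(pop, function(p) p$c_iso, numeric(1))
  cv_hat <- sd(ciso) / mean(ciso)
  expect_lt(abs(cv_hat - 0.1) / 0.1, 0.1)
  expect_lt(abs(mean(ciso) - 20) / 20, 0.01)
  expect_error(genotype_spec("bad", 20, rep(1, 4), rep(1, 4),
                             sample_cv = -0.1))
})

test_that("grid truth matches pointwise normalised analytic stresses", {
  p <- sample_population(genotype_presets()[[1]], 1, seed = 4)[[1]]
  m <- 5L
  g <- generate_grid_truth(p, m = m)
  expect_s3_class(g, "stress_grid")
  expect_identical(dim(g$values), c(m, m, 2L))
  # corner (1, 1) is stress-free hence normalised 0
  expect_equal(g$values[1, 1, 1], 0, tolerance = 1e-12)
  expect_equal(g$values[1, 1, 2], 0, tolerance = 1e-12)
  # layout: first index lambda_z, second lambda_theta, both ascending
  st <- grid_stretches(m)
  for (k in sample(m^2, 6)) {
    s <- stress_from_energy(p, st[k, 1], st[k, 2])
    iz <- (k - 1) %% m + 1; it <- (k - 1) %/% m + 1
    expect_equal(g$values[iz, it, 1], unname(normalize_stress(s[1, 1])),
                 tolerance = 1e-12)
    expect_equal(g$values[iz, it, 2], unname(normalize_stress(s[1, 2])),
                 tolerance = 1e-12)
  }
  # m = 2 grid sits exactly on the domain corners
  g2 <- generate_grid_truth(p, m = 2)
  expect_identical(dim(g2$values), c(2L, 2L, 2L))
  smax <- stress_from_energy(p, 1.65, 1.65)
  expect_equal(g2$values[2, 2, 1], unname(normalize_stress(smax[1, 1])),
               tolerance = 1e-12)
})

test_that("protocol records follow the seven-path battery and honour noise", {
  p <- sample_population(genotype_presets()[[3]], 1, seed = 6)[[1]]
  protos <- canonical_protocols(points_per_path = 25, noise_cv = 0)
  expect_length(protos, 7)
  rec <- generate_protocol_record(p, protos, seed = 2)
  expect_equal(nrow(rec$data), 175)
  expect_length(unique(rec$data$protocol), 7)
  # noiseless: observed stresses equal the analytic law exactly
  s <- stress_from_energy(p, rec$data$lambda_theta, rec$data$lambda_z)
  expect_equal(rec$data$sigma_theta, unname(s[, 1]), tolerance = 1e-12)
  expect_equal(rec$data$sigma_z, unname(s[, 2]), tolerance = 1e-12)
  # no observation enters the held-out extrapolation region
  expect_false(any(in_heldout_region(rec$data$lambda_theta,
                                     rec$data$lambda_z)))
  # seeded determinism with noise on
  protos_n <- canonical_protocols(points_per_path = 10, noise_cv = 0.05)
  r1 <- generate_protocol_record(p, protos_n, seed = 8)
  r2 <- generate_protocol_record(p, protos_n, seed = 8)
  expect_identical(r1, r2)
  r3 <- generate_protocol_record(p, protos_n, seed = 9)
  expect_false(identical(r1$data$sigma_theta, r3$data$sigma_theta))
})

test_that("records subsample to exactly m' stratified observations", {
  p <- sample_population(genotype_presets()[[1]], 1, seed = 4)[[1]]
  rec <- generate_protocol_record(p, canonical_protocols(points_per_path = 25),
                                  seed = 3)
  sub <- subsample_record(rec, m_prime = 22, seed = 5)
  expect_equal(nrow(sub$data), 22)
  # every protocol retains at least one point (22 points over 7 paths)
  expect_length(unique(sub$data$protocol), 7)
  expect_identical(subsample_record(rec, 22, seed = 5)$data, sub$data)
  expect_error(subsample_record(sub, 50), "subsample")
})
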