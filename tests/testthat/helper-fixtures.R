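# Shared fixtures.  Everything is generated in code; the expensive trained
# models are built once per test run and memoised in this environment.

.fixture_env <- new.env(parent = emptyenv())

# a small, fast model configuration for unit tests
tiny_model_config <- function(d_zeta = 3, d_eta = 2, m = 9) {
  g2phi_config(m = m, p = 4, d_eta = d_eta, d_zeta = d_zeta,
               enc_channels = c(3, 4), hidden = 8, depth = 2)
}

tiny_cohort <- function(n_per_class = 2, m = 9, seed = 1,
                        with_records = FALSE) {
  simulate_cohort(genotype_presets()[1:3], n_per_class = n_per_class,
                  seed = seed, m = m, with_records = with_records,
                  points_per_path = 10)
}

# a quickly trained tiny fit (seconds); memoised
tiny_fit <- function() {
  if (is.null(.fixture_env$tiny_fit)) {
    coh <- tiny_cohort()
    tc <- train_config(epochs = 60, lr = 5e-3, log_every = 20,
                       checkpoint_epochs = c(40, 60))
    .fixture_env$tiny_fit <- train_learning_stage(coh, tc,
                                                  tiny_model_config(),
                                                  seed = 42)
  }
  .fixture_env$tiny_fit
}

# The scaled-down study used by the acceptance tests: a four-class cohort
# with the preset moduli, K1 = 3 seeded runs of 2000 epochs with late-stage
# checkpoints, and 20 held-out specimens.  Built once and shared.
acceptance_study <- function() {
  if (is.null(.fixture_env$study)) {
    train <- simulate_cohort(n_per_class = 8, seed = 11,
                             with_records = FALSE)
    test <- simulate_cohort(n_per_class = 5, seed = 77)
    mc <- g2phi_config()
    tc <- train_config(epochs = 2000, log_every = 200,
                       checkpoint_epochs = c(1700, 1800, 1900, 2000))
    fits <- lapply(1:3, function(k)
      train_learning_stage(train, tc, mc, seed = 100 + k))
    .fixture_env$study <- list(train = train, test = test, fits = fits,
                               ensemble = harvest_ensemble(fits),
                               model_config = mc, train_config = tc)
  }
  .fixture_env$study
}

# a d_eta = 6 ensemble for the regularisation trend study; smaller budget
acceptance_study_deta6 <- function() {
  if (is.null(.fixture_env$study6)) {
    train <- simulate_cohort(n_per_class = 8, seed = 11,
                             with_records = FALSE)
    mc <- g2phi_config(d_eta = 6)
    tc <- train_config(epochs = 1500, log_every = 500)
    fit <- train_learning_stage(train, tc, mc, seed = 301)
    .fixture_env$study6 <- list(train = train,
                                ensemble = harvest_ensemble(list(fit)),
                                model_config = mc)
  }
  .fixture_env$study6
}
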