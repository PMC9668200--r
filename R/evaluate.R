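# Evaluation driver: run the inference stage over a set of held-out
# specimens and summarise classification accuracy and reconstruction
# error; plus the figure-style parameter sweep.

#' Evaluate an ensemble on held-out specimens
#'
#' For each test specimen, builds the observation set of the requested
#' setup (structured 3 x 3 boundary lattice, or 22 unstructured
#' protocol-path points), runs [infer_sample()], and compares the predicted
#' class and reconstructed stress grid against the specimen's ground
#' truth.
#'
#' @param ens a [harvest_ensemble()] model.
#' @param test_samples cohort entries (see [simulate_cohort()]); setup 2
#'   requires each entry to carry a `record`.
#' @param setup 1 (structured) or 2 (unstructured).
#' @param m_prime observations per specimen for setup 2 (default 22).
#' @param w_reg2 sample-feature regularisation weight (setup 2).
#' @param seed integer seed (setup-2 subsampling; inference itself is
#'   deterministic).
#' @param ... further arguments passed to [infer_sample()].
#' @return list with `per_sample` data frame (`sample_id`, `genotype_index`,
#'   `predicted`, `correct`, `err_theta`, `err_z`) and summary fields
#'   `accuracy`, `median_err_theta`, `median_err_z`.
#' @export
evaluate_ensemble <- function(ens, test_samples, setup = 1, m_prime = 22,
                              w_reg2 = 0, seed = 1L, ...) {
  stopifnot(inherits(ens, "g2phi_ensemble"), length(test_samples) >= 1L,
            setup %in% c(1, 2))
  rows <- vector("list", length(test_samples))
  for (i in seq_along(test_samples)) {
    s <- test_samples[[i]]
    obs <- if (setup == 1) {
      make_setup1_observations(s$params, domain = ens$config$domain,
                               sigma0 = ens$config$sigma0)
    } else {
      if (is.null(s$record))
        stop("setup 2 needs raw records; simulate with with_records = TRUE")
      make_setup2_observations(s$record, m_prime = m_prime,
                               seed = seed + i, sigma0 = ens$config$sigma0)
    }
    res <- infer_sample(ens, obs, w_reg2 = w_reg2, truth = s$grid, ...)
    rows[[i]] <- data.frame(sample_id = s$sample_id,
                            genotype_index = s$genotype_index,
                            predicted = res$class_index,
                            correct = res$class_index == s$genotype_index,
                            err_theta = res$errors[["theta"]],
                            err_z = res$errors[["z"]])
  }
  per_sample <- do.call(rbind, rows)
  list(per_sample = per_sample,
       accuracy = mean(per_sample$correct),
       median_err_theta = stats::median(per_sample$err_theta),
       median_err_z = stats::median(per_sample$err_z))
}

#' Sweep specification
#'
#' Grid of inference-study cells: sample-feature dimensions, ensemble
#' sizes, regularisation settings and setups, each repeated over seeded
#' replicates.
#'
#' @param d_eta sample-feature dimensions to sweep.
#' @param ensemble_sizes member counts to sweep.
#' @param setups inference setups (subset of `c(1, 2)`).
#' @param regularization `w_reg2` values to sweep (0 = off).
#' @param repeats seeded replicates per cell (default 20).
#' @return object of class `sweep_spec`.
#' @export
sweep_spec <- function(d_eta = c(2, 4, 6), ensemble_sizes = c(1, 3),
                       setups = 1, regularization = 0, repeats = 20) {
  stopifnot(repeats >= 1, all(ensemble_sizes >= 1),
            all(setups %in% c(1, 2)), all(regularization >= 0))
  structure(list(d_eta = d_eta, ensemble_sizes = ensemble_sizes,
                 setups = setups, regularization = regularization,
                 repeats = as.integer(repeats)),
            class = "sweep_spec")
}

#' Run a figure-style parameter sweep
#'
#' For every `d_eta` and replicate seed, trains enough seeded model copies
#' for the largest requested ensemble, then evaluates every (ensemble
#' size, setup, regularisation) cell.  Results append to a tidy long-format
#' CSV (one row per cell per replicate) as they complete, and cells already
#' present in the output file are skipped, so an interrupted sweep is
#' resumable and partial results are preserved.
#'
#' @param spec a [sweep_spec()].
#' @param train_samples,test_samples cohort entries.
#' @param out_csv output CSV path.
#' @param base_train_config a [train_config()] used for every run (scale
#'   `epochs` to the study size).
#' @param base_model_config a [g2phi_config()]; its `d_eta` is overridden
#'   per cell.
#' @param seed top-level integer seed.
#' @param ... passed to [evaluate_ensemble()].
#' @return data frame of all sweep rows (tidy long format).
#' @export
run_sweep <- function(spec, train_samples, test_samples, out_csv,
                      base_train_config = train_config(epochs = 500),
                      base_model_config = g2phi_config(),
                      seed = 1L, ...) {
  stopifnot(inherits(spec, "sweep_spec"))
  done <- if (file.exists(out_csv)) {
    utils::read.csv(out_csv, stringsAsFactors = FALSE)
  } else NULL
  key <- function(d) paste(d$setup, d$d_eta, d$ensemble_size, d$w_reg2,
                           d$rep, sep = "|")
  have <- if (!is.null(done)) key(done) else character(0)
  kmax <- max(spec$ensemble_sizes)
  for (de in spec$d_eta) {
    mc <- base_model_config
    mc$d_eta <- as.integer(de)
    for (rep_i in seq_len(spec$repeats)) {
      cells <- expand.grid(setup = spec$setups,
                           d_eta = de,
                           ensemble_size = spec$ensemble_sizes,
                           w_reg2 = spec$regularization,
                           rep = rep_i)
      if (all(key(cells) %in% have)) next
      run_seed <- seed + 10000L * rep_i + 100L * de
      fits <- lapply(seq_len(kmax), function(k)
        train_learning_stage(train_samples, base_train_config, mc,
                             seed = run_seed + k))
      for (ri in seq_len(nrow(cells))) {
        cell <- cells[ri, ]
        if (key(cell) %in% have) next
        ens <- harvest_ensemble(fits[seq_len(cell$ensemble_size)])
        ev <- evaluate_ensemble(ens, test_samples, setup = cell$setup,
                                w_reg2 = cell$w_reg2,
                                seed = run_seed, ...)
        row <- data.frame(setup = cell$setup, d_eta = cell$d_eta,
                          ensemble_size = cell$ensemble_size,
                          w_reg2 = cell$w_reg2, rep = rep_i,
                          accuracy = ev$accuracy,
                          median_err_theta = ev$median_err_theta,
                          median_err_z = ev$median_err_z)
        utils::write.table(row, out_csv, sep = ",", row.names = FALSE,
                           col.names = !file.exists(out_csv), append =
                             file.exists(out_csv), quote = FALSE)
        have <- c(have, key(cell))
      }
    }
  }
  utils::read.csv(out_csv, stringsAsFactors = FALSE)
}
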