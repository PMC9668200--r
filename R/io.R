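# File formats, configuration and reproducibility plumbing.

.record_cols <- c("sample_id", "genotype", "protocol", "lambda_theta",
                  "lambda_z", "sigma_theta_kpa", "sigma_z_kpa")

#' Write specimen records to CSV
#'
#' One row per observation, columns `sample_id`, `genotype`, `protocol`,
#' `lambda_theta`, `lambda_z`, `sigma_theta_kpa`, `sigma_z_kpa`.  Numeric
#' fields are written with 17 significant digits, so a write/read round
#' trip is lossless.
#'
#' @param records a `sample_record` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_records <- function(records, path) {
  if (inherits(records, "sample_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    stopifnot(inherits(r, "sample_record"))
    data.frame(sample_id = r$sample_id, genotype = r$genotype,
               protocol = r$data$protocol,
               lambda_theta = sprintf("%.17g", r$data$lambda_theta),
               lambda_z = sprintf("%.17g", r$data$lambda_z),
               sigma_theta_kpa = sprintf("%.17g", r$data$sigma_theta),
               sigma_z_kpa = sprintf("%.17g", r$data$sigma_z))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read specimen records from CSV
#'
#' @param path CSV path conforming to the [write_sample_records()] schema.
#' @param genotype_levels optional character vector fixing the genotype ->
#'   class-index mapping; default the order of first appearance.
#' @return list of `sample_record` objects.
#' @export
read_sample_records <- function(path, genotype_levels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.record_cols, names(df))
  if (length(missing))
    stop("read_sample_records(): missing column(s): ",
         paste(missing, collapse = ", "))
  for (cc in c("lambda_theta", "lambda_z", "sigma_theta_kpa",
               "sigma_z_kpa")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v) && !anyNA(df[[cc]]))
      stop("read_sample_records(): non-numeric value in column ", cc,
           " (first bad row ", which(is.na(v))[1L], ")")
    df[[cc]] <- v
  }
  if (is.null(genotype_levels)) genotype_levels <- unique(df$genotype)
  lapply(split(df, factor(df$sample_id, levels = unique(df$sample_id))),
         function(d) {
    structure(list(sample_id = d$sample_id[1L], genotype = d$genotype[1L],
                   genotype_index = match(d$genotype[1L], genotype_levels),
                   data = data.frame(protocol = d$protocol,
                                     lambda_theta = d$lambda_theta,
                                     lambda_z = d$lambda_z,
                                     sigma_theta = d$sigma_theta_kpa,
                                     sigma_z = d$sigma_z_kpa)),
              class = "sample_record")
  })
}

#' Write / read a stress grid as columnar CSV
#'
#' Columns `lambda_z`, `lambda_theta`, `sigma_theta_norm`, `sigma_z_norm`.
#'
#' @param grid a [stress_grid()].
#' @param path CSV path.
#' @return `write_stress_grid()` returns `path` invisibly;
#'   `read_stress_grid()` returns a [stress_grid()].
#' @export
write_stress_grid <- function(grid, path) {
  stopifnot(inherits(grid, "stress_grid"))
  st <- grid_stretches(grid$m, grid$domain)
  df <- data.frame(lambda_z = sprintf("%.17g", st[, 2L]),
                   lambda_theta = sprintf("%.17g", st[, 1L]),
                   sigma_theta_norm = sprintf("%.17g",
                                              as.vector(grid$values[, , 1L])),
                   sigma_z_norm = sprintf("%.17g",
                                          as.vector(grid$values[, , 2L])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stress_grid
#' @export
read_stress_grid <- function(path) {
  df <- utils::read.csv(path)
  need <- c("lambda_z", "lambda_theta", "sigma_theta_norm", "sigma_z_norm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("read_stress_grid(): missing column(s): ",
         paste(missing, collapse = ", "))
  m <- as.integer(sqrt(nrow(df)))
  if (m * m != nrow(df)) stop("read_stress_grid(): not a square grid")
  domain <- range(df$lambda_theta)
  vals <- array(c(df$sigma_theta_norm, df$sigma_z_norm), dim = c(m, m, 2))
  stress_grid(vals, domain = domain, normalized = TRUE)
}

#' Default configuration tree
#'
#' All tunable settings of the pipeline with their package defaults, as a
#' nested list: `model` ([g2phi_config()] arguments), `training`
#' ([train_config()] arguments), `inference` ([infer_sample()] settings)
#' and `simulate` ([simulate_cohort()] settings).
#'
#' @return nested list.
#' @export
default_config <- function() {
  list(
    model = list(m = 31, p = 32, d_eta = 4, d_zeta = 4,
                 enc_channels = c(8, 16, 32), hidden = 64, depth = 3),
    training = list(epochs = 20000, lr = 2e-3, w_rec = 1, w_reg = 0.1,
                    v_real = 1, v_mix = 0.5, eps = 0.01, log_every = 100),
    inference = list(w_fit = 1, w_reg2 = 0, iters = 1500, lr = 0.05,
                     eta_mode = "l2sq_sq"),
    simulate = list(n_per_class = 8, points_per_path = 25,
                    noise_cv = 0.02, lambda_z_iv = 1.45))
}

#' Load and validate a YAML configuration
#'
#' Unknown keys are rejected (listed in the error); values merge over
#' [default_config()].  `d_eta` outside 2..6 is rejected unless
#' `allow_override = TRUE`; `d_zeta >= 2` is always required.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param allow_override allow out-of-range architecture values.
#' @return validated nested configuration list.
#' @export
load_config <- function(path = NULL, allow_override = FALSE) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("load_config(): malformed config file")
    bad <- character(0)
    for (section in names(user)) {
      if (!section %in% names(cfg)) {
        bad <- c(bad, section); next
      }
      for (key in names(user[[section]])) {
        if (!key %in% names(cfg[[section]]))
          bad <- c(bad, paste0(section, ".", key))
      }
    }
    if (length(bad))
      stop("load_config(): unknown key(s): ", paste(bad, collapse = ", "))
    for (section in names(user))
      cfg[[section]] <- utils::modifyList(cfg[[section]], user[[section]])
  }
  if (!allow_override && (cfg$model$d_eta < 2 || cfg$model$d_eta > 6))
    stop("load_config(): model.d_eta must lie in 2..6 ",
         "(use allow_override = TRUE to force)")
  if (cfg$model$d_zeta < 2)
    stop("load_config(): model.d_zeta must be >= 2")
  cfg
}

#' Write a run manifest
#'
#' Records everything needed to re-run a result: the full configuration,
#' the top-level seed, artifact paths, package/R versions and a timestamp.
#'
#' @param path output JSON path.
#' @param config configuration list.
#' @param seed top-level integer seed.
#' @param artifacts named list/vector of artifact paths.
#' @param extra optional named list merged into the manifest.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, artifacts = list(),
                           extra = list()) {
  man <- c(list(config = config, seed = as.integer(seed),
                artifacts = artifacts,
                package = "g2phinet",
                package_version =
                  as.character(utils::packageVersion("g2phinet")),
                r_version = as.character(getRversion()),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}

#' Read a run manifest
#'
#' @param path JSON manifest path.
#' @return manifest list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
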