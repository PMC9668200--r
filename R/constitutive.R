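# Canonical biaxial stretch domain shared by every module.
.default_domain <- c(1.00, 1.65)

# Extrapolation region deliberately left unvisited by the measurement
# protocols, in (lambda_theta, lambda_z) coordinates.
.default_heldout <- list(theta = c(1.40, 1.65), z = c(1.00, 1.40))

#' Define a synthetic genotype class
#'
#' A genotype class is an analytic hyperelastic law: a neo-Hookean
#' ground-matrix term (elastin-dominated isotropic response) plus four
#' Fung-exponential fiber-family terms (collagen-dominated anisotropic
#' response), with a log-normal per-specimen perturbation of the scalar
#' parameters controlled by `sample_cv`.
#'
#' The strain energy density (kPa) is
#' \deqn{W = \frac{c_{iso}}{2}(I_1 - 3) +
#'       \sum_{i=1}^{4} \frac{c_1^i}{4 c_2^i}
#'       \left[e^{c_2^i (\lambda_i^2 - 1)^2} - 1\right],}
#' with incompressible first invariant
#' \eqn{I_1 = \lambda_\theta^2 + \lambda_z^2 +
#' \lambda_\theta^{-2}\lambda_z^{-2}} and fiber stretch
#' \eqn{\lambda_i^2 = \lambda_\theta^2 \sin^2\alpha_i +
#' \lambda_z^2 \cos^2\alpha_i}, angles measured from the axial axis.
#'
#' @param label class name (character scalar).
#' @param c_iso isotropic ground-matrix modulus (kPa), > 0.
#' @param fiber_c1 four fiber stiffness moduli (kPa), >= 0.
#' @param fiber_c2 four dimensionless fiber stiffening exponents, >= 0.
#' @param fiber_angle four fiber angles (radians from the axial axis);
#'   default one axial, one circumferential and a symmetric diagonal pair.
#' @param sample_cv relative standard deviation of the per-specimen
#'   log-normal parameter perturbation, >= 0.
#' @return an object of class `genotype_spec`.
#' @export
genotype_spec <- function(label, c_iso, fiber_c1, fiber_c2,
                          fiber_angle = c(0, pi / 2, pi / 4, -pi / 4),
                          sample_cv = 0.08) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(c_iso), length(c_iso) == 1L, c_iso > 0,
            length(fiber_c1) == 4L, all(fiber_c1 >= 0),
            length(fiber_c2) == 4L, all(fiber_c2 >= 0),
            length(fiber_angle) == 4L,
            is.numeric(sample_cv), length(sample_cv) == 1L)
  if (sample_cv < 0) stop("genotype_spec(): sample_cv must be >= 0")
  structure(list(label = label, c_iso = c_iso,
                 fiber_c1 = as.numeric(fiber_c1),
                 fiber_c2 = as.numeric(fiber_c2),
                 fiber_angle = as.numeric(fiber_angle),
                 sample_cv = sample_cv),
            class = "genotype_spec")
}

#' Built-in genotype presets
#'
#' Five murine aortic phenotype presets.  The neo-Hookean moduli follow the
#' reported elastopathy ordering (25, 29, 17 and 10 kPa for the
#' elastin-amplified, fibrillin-1 deficient, fibulin-5 null and
#' elastin-reduced lines, with a wild-type modulus inside the 21--32 kPa
#' range); fiber-family parameters are chosen so that the four default
#' classes have well-separated stress surfaces while `"WT"` deliberately
#' resembles `"hBAC-mWT"` (a poorly identifiable pair, mirroring the
#' five-class setting).
#'
#' @param labels which presets to return; default the canonical four-class
#'   battery.
#' @return named list of [genotype_spec()] objects.
#' @export
genotype_presets <- function(labels = c("hBAC-mWT", "Fbn1mgR", "Fbln5KO",
                                        "hBAC-mNull")) {
  all <- list(
    "hBAC-mWT" = genotype_spec("hBAC-mWT", c_iso = 25,
                               fiber_c1 = c(1.2, 1.5, 2.0, 2.0),
                               fiber_c2 = c(0.9, 1.0, 1.1, 1.1)),
    "Fbn1mgR" = genotype_spec("Fbn1mgR", c_iso = 29,
                              fiber_c1 = c(0.7, 0.9, 1.3, 1.3),
                              fiber_c2 = c(1.5, 1.6, 1.5, 1.5)),
    "Fbln5KO" = genotype_spec("Fbln5KO", c_iso = 17,
                              fiber_c1 = c(2.5, 3.0, 3.5, 3.5),
                              fiber_c2 = c(0.6, 0.7, 0.8, 0.8)),
    "hBAC-mNull" = genotype_spec("hBAC-mNull", c_iso = 10,
                                 fiber_c1 = c(3.0, 3.5, 4.5, 4.5),
                                 fiber_c2 = c(1.2, 1.3, 1.2, 1.2)),
    "WT" = genotype_spec("WT", c_iso = 26.5,
                         fiber_c1 = c(1.1, 1.4, 1.9, 1.9),
                         fiber_c2 = c(0.95, 1.05, 1.1, 1.1)))
  missing <- setdiff(labels, names(all))
  if (length(missing)) stop("unknown genotype preset(s): ",
                            paste(missing, collapse = ", "))
  all[labels]
}

#' Draw a specimen population from a genotype class
#'
#' Each specimen's scalar parameters (`c_iso`, `fiber_c1`, `fiber_c2`) are
#' independently perturbed by a mean-one log-normal factor whose coefficient
#' of variation equals `spec$sample_cv`; fiber angles are left fixed.
#' Deterministic given `seed`.
#'
#' @param spec a [genotype_spec()].
#' @param n number of specimens, >= 1.
#' @param seed integer seed.
#' @param genotype_index integer class index carried into each specimen.
#' @return list of `sample_params` objects.
#' @export
sample_population <- function(spec, n, seed, genotype_index = 1L) {
  stopifnot(inherits(spec, "genotype_spec"), n >= 1)
  if (spec$sample_cv < 0) stop("sample_cv must be >= 0")
  sdlog <- sqrt(log(1 + spec$sample_cv^2))
  meanlog <- -sdlog^2 / 2  # mean-one correction
  out <- vector("list", n)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  for (i in seq_len(n)) {
    f <- if (sdlog > 0) stats::rlnorm(9, meanlog, sdlog) else rep(1, 9)
    out[[i]] <- structure(list(
      sample_id = sprintf("%s_%02d", spec$label, i),
      genotype = spec$label,
      genotype_index = as.integer(genotype_index),
      c_iso = spec$c_iso * f[1],
      fiber_c1 = spec$fiber_c1 * f[2:5],
      fiber_c2 = spec$fiber_c2 * f[6:9],
      fiber_angle = spec$fiber_angle,
      rng_seed = as.integer(seed)),
      class = "sample_params")
  }
  out
}

# save/restore the global RNG state so that generators are seeded locally
.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Strain energy density of a synthetic specimen
#'
#' Evaluates the neo-Hookean + four-fiber-family Fung-exponential law (see
#' [genotype_spec()]) at one or more biaxial stretch states.  A fiber family
#' with `c2 = 0` uses the quadratic limit
#' \eqn{(c_1/4)(\lambda_i^2-1)^2} rather than dividing by zero.
#'
#' @param params a `sample_params` object (or a [genotype_spec()], whose
#'   central parameters are then used).
#' @param lambda_theta,lambda_z circumferential and axial stretches (> 0),
#'   recycled to a common length.
#' @return strain energy density (kPa), zero at the reference state
#'   `lambda_theta = lambda_z = 1`.
#' @export
strain_energy <- function(params, lambda_theta, lambda_z) {
  p <- .as_material_params(params)
  stopifnot(all(lambda_theta > 0), all(lambda_z > 0))
  lt2 <- lambda_theta^2; lz2 <- lambda_z^2
  i1 <- lt2 + lz2 + 1 / (lt2 * lz2)
  w <- p$c_iso / 2 * (i1 - 3)
  for (i in 1:4) {
    li2 <- lt2 * sin(p$fiber_angle[i])^2 + lz2 * cos(p$fiber_angle[i])^2
    e <- (li2 - 1)^2
    if (p$fiber_c2[i] > 1e-8) {
      w <- w + p$fiber_c1[i] / (4 * p$fiber_c2[i]) *
        (exp(p$fiber_c2[i] * e) - 1)
    } else {
      w <- w + p$fiber_c1[i] / 4 * e
    }
  }
  w
}

#' Cauchy stresses of a synthetic specimen (analytic)
#'
#' Exact stretch-derivatives of [strain_energy()] under the incompressible
#' biaxial constitutive identity \eqn{\sigma_i = \lambda_i \,
#' \partial W/\partial\lambda_i} (radial stretch eliminated as
#' \eqn{1/(\lambda_\theta\lambda_z)}).
#'
#' @inheritParams strain_energy
#' @return matrix with columns `sigma_theta`, `sigma_z` (kPa); one row per
#'   stretch state.  Both are zero at the reference state.
#' @export
stress_from_energy <- function(params, lambda_theta, lambda_z) {
  p <- .as_material_params(params)
  stopifnot(all(lambda_theta > 0), all(lambda_z > 0))
  n <- max(length(lambda_theta), length(lambda_z))
  lt <- rep_len(lambda_theta, n); lz <- rep_len(lambda_z, n)
  lt2 <- lt^2; lz2 <- lz^2
  # isotropic part: sigma_theta = c_iso (lt^2 - lt^-2 lz^-2), and symmetric
  s_th <- p$c_iso * (lt2 - 1 / (lt2 * lz2))
  s_z <- p$c_iso * (lz2 - 1 / (lt2 * lz2))
  for (i in 1:4) {
    sa2 <- sin(p$fiber_angle[i])^2; ca2 <- cos(p$fiber_angle[i])^2
    li2 <- lt2 * sa2 + lz2 * ca2
    fac <- p$fiber_c1[i] * (li2 - 1) *
      exp(pmin(p$fiber_c2[i] * (li2 - 1)^2, 700))
    s_th <- s_th + fac * lt2 * sa2
    s_z <- s_z + fac * lz2 * ca2
  }
  cbind(sigma_theta = s_th, sigma_z = s_z)
}

.as_material_params <- function(params) {
  if (inherits(params, "sample_params")) return(params)
  if (inherits(params, "genotype_spec")) {
    return(structure(list(sample_id = params$label, genotype = params$label,
                          genotype_index = 1L, c_iso = params$c_iso,
                          fiber_c1 = params$fiber_c1,
                          fiber_c2 = params$fiber_c2,
                          fiber_angle = params$fiber_angle, rng_seed = NA),
                     class = "sample_params"))
  }
  stop("expected a sample_params or genotype_spec object")
}

#' Uniform stretch lattice
#'
#' @param m grid size per side (>= 2).
#' @param domain two-element stretch range, default `c(1.00, 1.65)`.
#' @return matrix (m^2, 2) with columns `lambda_theta`, `lambda_z`, ordered
#'   with `lambda_z` varying fastest (first array index = lambda_z,
#'   second = lambda_theta, both ascending).
#' @export
grid_stretches <- function(m = 31, domain = .default_domain) {
  stopifnot(m >= 2, length(domain) == 2L, domain[1] < domain[2])
  g <- seq(domain[1], domain[2], length.out = m)
  cbind(lambda_theta = rep(g, each = m), lambda_z = rep(g, times = m))
}

#' Construct a stress grid object
#'
#' @param values numeric array `(m, m, 2)`; first index lambda_z ascending,
#'   second lambda_theta ascending; third index = (sigma_theta, sigma_z).
#' @param domain stretch domain.
#' @param normalized logical; `TRUE` when values are log-normalised.
#' @param sigma0 normalisation constant (kPa).
#' @return object of class `stress_grid`.
#' @export
stress_grid <- function(values, domain = .default_domain, normalized = TRUE,
                        sigma0 = 1) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            dim(values)[1] == dim(values)[2], dim(values)[3] == 2L,
            all(is.finite(values)))
  structure(list(m = dim(values)[1], values = values, domain = domain,
                 normalized = normalized, sigma0 = sigma0),
            class = "stress_grid")
}

#' @export
print.stress_grid <- function(x, ...) {
  cat(sprintf("<stress_grid m=%d domain=[%.2f, %.2f] %s>\n", x$m,
              x$domain[1], x$domain[2],
              if (x$normalized) "normalized" else "kPa"))
  invisible(x)
}

#' Ground-truth normalised stress grid of a synthetic specimen
#'
#' Evaluates the analytic stresses of `params` on the uniform `m x m`
#' stretch lattice and log-normalises them.
#'
#' @param params `sample_params` (or [genotype_spec()]).
#' @param m grid size (default 31).
#' @param domain stretch domain.
#' @param sigma0 normalisation constant (kPa).
#' @return a [stress_grid()] of normalised stresses.
#' @export
generate_grid_truth <- function(params, m = 31, domain = .default_domain,
                                sigma0 = 1) {
  st <- grid_stretches(m, domain)
  s <- stress_from_energy(params, st[, 1], st[, 2])
  if (any(s <= -sigma0)) {
    stop("generate_grid_truth(): stresses fall outside the validity region",
         " of the log transform over this domain")
  }
  vals <- array(normalize_stress(as.vector(s), sigma0), dim = c(m, m, 2))
  stress_grid(vals, domain = domain, normalized = TRUE, sigma0 = sigma0)
}

#' The canonical seven-protocol measurement battery
#'
#' Three distension sweeps at axial stretch fixed to 95/100/105 % of the in
#' vivo value and four axial-extension sweeps at path levels indexed by
#' fixed transmural pressures of 10/60/100/140 mmHg.  Pressure levels index
#' smooth monotone path offsets on the stretch plane; no vessel equilibrium
#' problem is solved.  Paths are laid out so that the extrapolation region
#' `(lambda_theta, lambda_z) in [1.40, 1.65] x [1.00, 1.40]` is never
#' visited.
#'
#' @param points_per_path measurement points per protocol (>= 2).
#' @param noise_cv relative multiplicative measurement-noise std.
#' @param lambda_z_iv in vivo axial stretch (default 1.45).
#' @return list of `protocol_spec` objects, length 7.
#' @export
canonical_protocols <- function(points_per_path = 25, noise_cv = 0.02,
                                lambda_z_iv = 1.45) {
  stopifnot(points_per_path >= 2, noise_cv >= 0)
  dist <- lapply(c(0.95, 1.00, 1.05), function(f) {
    structure(list(kind = "distension", fixed_axial_fraction = f,
                   fixed_pressure = NA_real_, lambda_z_iv = lambda_z_iv,
                   points_per_path = points_per_path, noise_cv = noise_cv,
                   tag = sprintf("P_sweep_%.0f%%iv", 100 * f)),
              class = "protocol_spec")
  })
  ext <- lapply(c(10, 60, 100, 140), function(p) {
    structure(list(kind = "extension", fixed_axial_fraction = NA_real_,
                   fixed_pressure = p, lambda_z_iv = lambda_z_iv,
                   points_per_path = points_per_path, noise_cv = noise_cv,
                   tag = sprintf("L_sweep_%dmmHg", p)),
              class = "protocol_spec")
  })
  c(dist, ext)
}

# Stretch path of one protocol.  Distension: lambda_z fixed at
# fraction * lambda_z_iv while lambda_theta sweeps with the pressure
# parameter t in [10, 140] mmHg; paths whose fixed lambda_z lies below the
# held-out-region boundary cap their circumferential sweep below it.
# Extension: lambda_theta fixed at a pressure-indexed level while lambda_z
# sweeps.
.protocol_path <- function(proto, domain = .default_domain,
                           heldout = .default_heldout) {
  n <- proto$points_per_path
  t <- seq(0, 1, length.out = n)  # scaled pressure/force parameter
  if (proto$kind == "distension") {
    lz <- proto$fixed_axial_fraction * proto$lambda_z_iv
    lt_max <- if (lz <= heldout$z[2]) heldout$theta[1] - 0.02
              else domain[2] - 0.03
    lt <- 1.02 + (lt_max - 1.02) * t^0.65  # compliant early, stiff late
    data.frame(protocol = proto$tag, lambda_theta = lt, lambda_z = lz)
  } else {
    frac <- (proto$fixed_pressure - 10) / 130
    lt <- 1.06 + 0.28 * frac^0.8           # pressure-indexed level < 1.40
    lz <- 1.02 + (domain[2] - 0.05 - 1.02) * t^0.8
    data.frame(protocol = proto$tag, lambda_theta = lt, lambda_z = lz)
  }
}

#' Generate a specimen's raw measurement record
#'
#' Evaluates the specimen's analytic stresses along the protocol paths and
#' applies multiplicative log-normal measurement noise of relative std
#' `noise_cv` (taken from each protocol spec).  Deterministic given `seed`.
#'
#' @param params `sample_params`.
#' @param protocols list of protocol specs, e.g. [canonical_protocols()].
#' @param seed integer seed for the measurement noise.
#' @param domain stretch domain.
#' @param sigma0 validity floor for stresses (kPa).
#' @return object of class `sample_record`: `sample_id`, `genotype`,
#'   `genotype_index` and a data frame `data` with columns `protocol`,
#'   `lambda_theta`, `lambda_z`, `sigma_theta`, `sigma_z` (kPa).
#' @export
generate_protocol_record <- function(params, protocols = canonical_protocols(),
                                     seed = 1L, domain = .default_domain,
                                     sigma0 = 1) {
  stopifnot(inherits(params, "sample_params"), length(protocols) >= 1)
  paths <- do.call(rbind, lapply(protocols, .protocol_path, domain = domain))
  bad <- paths$lambda_theta < domain[1] - 1e-9 |
    paths$lambda_theta > domain[2] + 1e-9 |
    paths$lambda_z < domain[1] - 1e-9 | paths$lambda_z > domain[2] + 1e-9
  if (any(bad)) {
    stop("generate_protocol_record(): ", sum(bad),
         " path point(s) leave the stretch domain [", domain[1], ", ",
         domain[2], "]")
  }
  s <- stress_from_energy(params, paths$lambda_theta, paths$lambda_z)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  cv <- vapply(protocols, function(p) p$noise_cv, numeric(1))
  cv <- rep(cv, vapply(protocols, function(p) p$points_per_path, numeric(1)))
  if (any(cv > 0)) {
    sdlog <- sqrt(log(1 + cv^2))
    fac_t <- exp(stats::rnorm(nrow(s), -sdlog^2 / 2, sdlog))
    fac_z <- exp(stats::rnorm(nrow(s), -sdlog^2 / 2, sdlog))
    s[, 1] <- s[, 1] * fac_t
    s[, 2] <- s[, 2] * fac_z
  }
  if (any(s <= -sigma0)) {
    stop("generate_protocol_record(): noisy stresses violate the ",
         "log-transform validity floor -sigma0; reduce noise_cv")
  }
  structure(list(sample_id = params$sample_id, genotype = params$genotype,
                 genotype_index = params$genotype_index,
                 data = data.frame(protocol = paths$protocol,
                                   lambda_theta = paths$lambda_theta,
                                   lambda_z = paths$lambda_z,
                                   sigma_theta = s[, 1], sigma_z = s[, 2])),
            class = "sample_record")
}

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("<sample_record %s genotype=%s n_obs=%d>\n", x$sample_id,
              x$genotype, nrow(x$data)))
  invisible(x)
}

#' Thin a measurement record to a fixed number of points
#'
#' Stratified across protocols: each protocol contributes
#' floor-proportionally, with the remainder assigned by largest fractional
#' share; points within a protocol are sampled without replacement.
#' Deterministic given `seed`.
#'
#' @param record a `sample_record`.
#' @param m_prime target number of observations (default 22).
#' @param seed integer seed.
#' @return a `sample_record` with exactly `m_prime` rows.
#' @export
subsample_record <- function(record, m_prime = 22, seed = 1L) {
  stopifnot(inherits(record, "sample_record"))
  n <- nrow(record$data)
  if (n < m_prime) stop("record has only ", n, " observations; cannot ",
                        "subsample to ", m_prime)
  tab <- table(record$data$protocol)
  share <- m_prime * as.numeric(tab) / n
  take <- floor(share)
  rem <- m_prime - sum(take)
  if (rem > 0) {
    ord <- order(share - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  }
  take <- pmin(take, as.numeric(tab))
  # if capping left a deficit, spread it over protocols with spare points
  deficit <- m_prime - sum(take)
  while (deficit > 0) {
    spare <- which(take < as.numeric(tab))
    take[spare[1]] <- take[spare[1]] + 1
    deficit <- deficit - 1
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  keep <- unlist(lapply(seq_along(tab), function(i) {
    idx <- which(record$data$protocol == names(tab)[i])
    if (take[i] == 0) return(integer(0))
    sort(sample(idx, take[i]))
  }))
  record$data <- record$data[sort(keep), , drop = FALSE]
  rownames(record$data) <- NULL
  record
}

#' Is a stretch state inside the held-out extrapolation region?
#'
#' @param lambda_theta,lambda_z stretch coordinates.
#' @param heldout list with elements `theta` and `z`, each a range.
#' @return logical vector.
#' @export
in_heldout_region <- function(lambda_theta, lambda_z,
                              heldout = .default_heldout) {
  lambda_theta >= heldout$theta[1] & lambda_theta <= heldout$theta[2] &
    lambda_z >= heldout$z[1] & lambda_z <= heldout$z[2]
}
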