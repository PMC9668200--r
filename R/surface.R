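# Physics-constrained strain-energy surface fitting.  One specimen's
# scattered biaxial measurements are fitted by a smooth scalar energy
# surface w(lambda_z, lambda_theta); stresses follow from the exact
# constitutive identity sigma_i = lambda_i dw/dlambda_i.  The surface is a
# total-degree tensor polynomial in the shifted, scaled stretches, which is
# linear in its coefficients, so every stretch-derivative needed by the two
# convexity penalties (Hessians of the energy and of both stress
# components) is exact and the penalised fit is a deterministic
# quasi-Newton optimisation.

#' Penalty configuration for the energy-surface fit
#'
#' @param colloc collocation points for the convexity checks, matrix
#'   `(n, 2)` with columns `(lambda_theta, lambda_z)`; default the 31 x 31
#'   training lattice.
#' @param threshold stretch threshold of the stress-convexity region:
#'   the stress-Hessian penalty is active only where
#'   `max(lambda_z, lambda_theta) > threshold` (default 1.45), where the
#'   stress-stretch curve is J-shaped.
#' @param weight_energy,weight_stress nonnegative penalty weights.
#' @param hinge_tol hinge tolerance on negative Hessian eigenvalues.
#' @param domain stretch domain.
#' @return object of class `penalty_config`.
#' @export
penalty_config <- function(colloc = grid_stretches(31),
                           threshold = 1.45,
                           weight_energy = 1e-4, weight_stress = 1e-4,
                           hinge_tol = 1e-6, domain = .default_domain) {
  stopifnot(is.matrix(colloc), ncol(colloc) == 2L, nrow(colloc) >= 1L,
            weight_energy >= 0, weight_stress >= 0, hinge_tol >= 0,
            threshold > domain[1], threshold < domain[2])
  structure(list(colloc = colloc, threshold = threshold,
                 weight_energy = weight_energy,
                 weight_stress = weight_stress,
                 hinge_tol = hinge_tol, domain = domain),
            class = "penalty_config")
}

# monomial exponent table for total degree <= deg with i + j >= 2, so the
# surface and its gradient vanish at the reference state (1, 1)
.surface_powers <- function(deg) {
  pw <- expand.grid(i = 0:deg, j = 0:deg)
  pw <- pw[pw$i + pw$j >= 2 & pw$i + pw$j <= deg, , drop = FALSE]
  as.matrix(pw[order(pw$i + pw$j, pw$i), ])
}

#' Create a polynomial strain-energy surface
#'
#' The surface is \eqn{w(\lambda_\theta, \lambda_z) = \sum_k c_k u^{i_k}
#' v^{j_k}} (kPa) in the scaled coordinates \eqn{u = (\lambda_\theta -
#' 1)/s}, \eqn{v = (\lambda_z - 1)/s} with `s` the domain width; monomials
#' are restricted to total degree in `[2, degree]` so that both the energy
#' and the stresses vanish at the reference state.
#'
#' @param degree maximum total degree (default 10).
#' @param coef coefficient vector (default all zero); length must match the
#'   monomial table.
#' @param domain stretch domain.
#' @return object of class `energy_surface`.
#' @export
energy_surface <- function(degree = 10, coef = NULL,
                           domain = .default_domain) {
  stopifnot(degree >= 2)
  pw <- .surface_powers(degree)
  if (is.null(coef)) coef <- numeric(nrow(pw))
  stopifnot(length(coef) == nrow(pw))
  structure(list(degree = degree, powers = pw, coef = as.numeric(coef),
                 scale = domain[2] - domain[1], domain = domain,
                 fitted = FALSE, diagnostics = NULL),
            class = "energy_surface")
}

#' @export
print.energy_surface <- function(x, ...) {
  cat(sprintf("<energy_surface degree=%d (%d coefficients)%s>\n", x$degree,
              length(x$coef), if (x$fitted) " fitted" else ""))
  if (x$fitted && !is.null(x$diagnostics)) {
    d <- x$diagnostics
    cat(sprintf("  data loss %.3e | energy penalty %.3e | stress penalty %.3e\n",
                d$data_loss, d$penalty_energy, d$penalty_stress))
  }
  invisible(x)
}

# basis matrix of the (a, b)-th mixed derivative wrt (lambda_theta,
# lambda_z): rows = evaluation points, cols = monomials
.surface_basis <- function(surf, lt, lz, a = 0L, b = 0L) {
  u <- (lt - surf$domain[1]) / surf$scale
  v <- (lz - surf$domain[1]) / surf$scale
  pw <- surf$powers
  n <- length(u); K <- nrow(pw)
  B <- matrix(0, n, K)
  for (k in seq_len(K)) {
    i <- pw[k, 1L]; j <- pw[k, 2L]
    if (i < a || j < b) next
    ci <- if (a > 0) prod(i:(i - a + 1L)) else 1
    cj <- if (b > 0) prod(j:(j - b + 1L)) else 1
    B[, k] <- ci * cj * u^(i - a) * v^(j - b)
  }
  B / surf$scale^(a + b)
}

#' Evaluate a strain-energy surface
#'
#' @param surf an [energy_surface()].
#' @param lambda_theta,lambda_z stretches (vectors, recycled).
#' @return energy density values (kPa).
#' @export
surface_energy <- function(surf, lambda_theta, lambda_z) {
  n <- max(length(lambda_theta), length(lambda_z))
  lt <- rep_len(lambda_theta, n); lz <- rep_len(lambda_z, n)
  as.vector(.surface_basis(surf, lt, lz) %*% surf$coef)
}

#' Stresses of an energy surface (exact derivatives)
#'
#' Applies the constitutive identity \eqn{\sigma_i = \lambda_i \partial
#' w/\partial\lambda_i} using the exact analytic gradient of the
#' polynomial surface (not finite differences).
#'
#' @inheritParams surface_energy
#' @return matrix with columns `sigma_theta`, `sigma_z` (kPa).
#' @export
surface_stresses <- function(surf, lambda_theta, lambda_z) {
  stopifnot(inherits(surf, "energy_surface"))
  n <- max(length(lambda_theta), length(lambda_z))
  lt <- rep_len(lambda_theta, n); lz <- rep_len(lambda_z, n)
  st <- lt * as.vector(.surface_basis(surf, lt, lz, a = 1L) %*% surf$coef)
  sz <- lz * as.vector(.surface_basis(surf, lt, lz, b = 1L) %*% surf$coef)
  cbind(sigma_theta = st, sigma_z = sz)
}

# closed-form eigenvalues of symmetric 2x2 Hessians given rows (h11, h12,
# h22); returns a 2-column matrix (lambda_min, lambda_max)
.sym2x2_eigen <- function(h11, h12, h22) {
  tr2 <- (h11 + h22) / 2
  disc <- sqrt(pmax(((h11 - h22) / 2)^2 + h12^2, 0))
  cbind(tr2 - disc, tr2 + disc)
}

# squared-hinge penalty on negative eigenvalues: mean over points of
# sum_k max(0, -(lambda_k + tol))^2
.eigen_hinge <- function(eigs, tol) {
  if (length(eigs) == 0L) return(0)
  h <- pmax(0, -(eigs + tol))
  sum(h^2) / nrow(eigs)
}

# Hessian rows of w wrt (lambda_z, lambda_theta) at the given points:
# returns list of basis matrices so gradients wrt coef are immediate
.energy_hessian_bases <- function(surf, lt, lz) {
  list(zz = .surface_basis(surf, lt, lz, a = 0L, b = 2L),
       zt = .surface_basis(surf, lt, lz, a = 1L, b = 1L),
       tt = .surface_basis(surf, lt, lz, a = 2L, b = 0L))
}

# Hessian bases of the two stress components.  With w_t = dw/dlambda_theta
# etc., sigma_theta = lambda_theta * w_t, so e.g.
# d2 sigma_theta / dlambda_theta2 = 2 w_tt + lambda_theta w_ttt.
.stress_hessian_bases <- function(surf, lt, lz) {
  B <- function(a, b) .surface_basis(surf, lt, lz, a = a, b = b)
  w_tt <- B(2L, 0L); w_tz <- B(1L, 1L); w_zz <- B(0L, 2L)
  w_ttt <- B(3L, 0L); w_ttz <- B(2L, 1L); w_tzz <- B(1L, 2L)
  w_zzz <- B(0L, 3L)
  list(theta = list(tt = 2 * w_tt + lt * w_ttt,
                    tz = w_tz + lt * w_ttz,
                    zz = lt * w_tzz),
       z = list(tt = lz * w_ttz,
                tz = w_tz + lz * w_tzz,
                zz = 2 * w_zz + lz * w_zzz))
}

#' Convexity penalty on the strain energy
#'
#' Squared hinge on negative eigenvalues of the Hessian of `w` with respect
#' to `(lambda_z, lambda_theta)`, averaged over the collocation points.
#' Zero iff the Hessian is positive semidefinite (within the hinge
#' tolerance) everywhere on the collocation set.
#'
#' @param surf an [energy_surface()].
#' @param cfg a [penalty_config()].
#' @return scalar >= 0.
#' @export
convexity_penalty_energy <- function(surf, cfg = penalty_config()) {
  stopifnot(inherits(surf, "energy_surface"),
            inherits(cfg, "penalty_config"))
  if (nrow(cfg$colloc) == 0L) stop("empty collocation set")
  lt <- cfg$colloc[, 1L]; lz <- cfg$colloc[, 2L]
  Bs <- .energy_hessian_bases(surf, lt, lz)
  eigs <- .sym2x2_eigen(as.vector(Bs$zz %*% surf$coef),
                        as.vector(Bs$zt %*% surf$coef),
                        as.vector(Bs$tt %*% surf$coef))
  .eigen_hinge(eigs, cfg$hinge_tol)
}

#' Convexity penalty on the stress components (large stretches)
#'
#' Squared hinge on negative Hessian eigenvalues of
#' \eqn{\sigma_\theta(\lambda_z, \lambda_\theta)} and
#' \eqn{\sigma_z(\lambda_z, \lambda_\theta)}, evaluated only at collocation
#' points with `max(lambda_z, lambda_theta) > cfg$threshold`.  Returns 0
#' when the active set is empty.
#'
#' @inheritParams convexity_penalty_energy
#' @return scalar >= 0.
#' @export
convexity_penalty_stress <- function(surf, cfg = penalty_config()) {
  stopifnot(inherits(surf, "energy_surface"),
            inherits(cfg, "penalty_config"))
  if (nrow(cfg$colloc) == 0L) stop("empty collocation set")
  act <- pmax(cfg$colloc[, 1L], cfg$colloc[, 2L]) > cfg$threshold
  if (!any(act)) return(0)
  lt <- cfg$colloc[act, 1L]; lz <- cfg$colloc[act, 2L]
  Bs <- .stress_hessian_bases(surf, lt, lz)
  pen <- 0
  for (comp in Bs) {
    eigs <- .sym2x2_eigen(as.vector(comp$zz %*% surf$coef),
                          as.vector(comp$tz %*% surf$coef),
                          as.vector(comp$tt %*% surf$coef))
    pen <- pen + .eigen_hinge(eigs, cfg$hinge_tol)
  }
  pen
}

# gradient wrt coef of an eigenvalue-hinge penalty whose Hessian entries
# are (B11 c, B12 c, B22 c); closed-form eigenvector sensitivities
.eigen_hinge_grad <- function(coef, B11, B12, B22, tol) {
  h11 <- as.vector(B11 %*% coef)
  h12 <- as.vector(B12 %*% coef)
  h22 <- as.vector(B22 %*% coef)
  npts <- length(h11)
  half_diff <- (h11 - h22) / 2
  disc <- sqrt(pmax(half_diff^2 + h12^2, 1e-300))
  g <- numeric(length(coef))
  for (sgn in c(-1, 1)) {
    lam <- (h11 + h22) / 2 + sgn * disc
    act <- lam < -tol
    if (!any(act)) next
    wt <- -2 * pmax(0, -(lam + tol))[act] / npts   # d pen / d lam
    # d lam / d h11 = 1/2 + sgn*half_diff/(2*disc), etc.
    d11 <- 0.5 + sgn * half_diff[act] / (2 * disc[act])
    d22 <- 0.5 - sgn * half_diff[act] / (2 * disc[act])
    d12 <- sgn * h12[act] / disc[act]
    g <- g + crossprod(B11[act, , drop = FALSE], wt * d11)[, 1L] +
      crossprod(B22[act, , drop = FALSE], wt * d22)[, 1L] +
      crossprod(B12[act, , drop = FALSE], wt * d12)[, 1L]
  }
  g
}

#' Fit a strain-energy surface to one specimen's measurements
#'
#' Minimises a relative-quadratic data mismatch on log-normalised stresses
#' plus the two weighted convexity penalties (and a small ridge term for
#' conditioning) over the polynomial coefficients, by L-BFGS-B with exact
#' analytic gradients.  If a penalty remains above the hinge tolerance at
#' convergence, the penalty weights are increased (x20) and the fit is
#' restarted warm, up to `penalty_rounds` times.  The whole procedure is
#' deterministic.
#'
#' @param record a `sample_record` (kPa stresses).
#' @param cfg a [penalty_config()].
#' @param degree polynomial total degree (default 10).
#' @param eps stabiliser of the relative-quadratic data loss.
#' @param ridge ridge weight on the coefficients.
#' @param maxit L-BFGS-B iterations per round.
#' @param penalty_rounds maximum penalty-escalation rounds.
#' @param sigma0 normalisation constant (kPa).
#' @return a fitted [energy_surface()] with a `diagnostics` list
#'   (`data_loss`, `penalty_energy`, `penalty_stress`, `rounds`,
#'   `convergence`).
#' @export
fit_energy_surface <- function(record, cfg = penalty_config(), degree = 10,
                               eps = 0.01, ridge = 1e-8, maxit = 400,
                               penalty_rounds = 3, sigma0 = 1) {
  stopifnot(inherits(record, "sample_record"), nrow(record$data) >= 1L)
  if (nrow(record$data) == 1L)
    warning("fit_energy_surface(): a single observation under-determines ",
            "the surface; the fit is dominated by the penalties")
  surf <- energy_surface(degree, domain = cfg$domain)
  dat <- record$data
  # data-term design matrices: sigma = lambda * d(basis)/d(lambda) %*% coef
  A_t <- dat$lambda_theta *
    .surface_basis(surf, dat$lambda_theta, dat$lambda_z, a = 1L)
  A_z <- dat$lambda_z *
    .surface_basis(surf, dat$lambda_theta, dat$lambda_z, b = 1L)
  y_t <- normalize_stress(dat$sigma_theta, sigma0)
  y_z <- normalize_stress(dat$sigma_z, sigma0)
  den_t <- abs(y_t + eps); den_z <- abs(y_z + eps)
  nobs <- nrow(dat)
  lt <- cfg$colloc[, 1L]; lz <- cfg$colloc[, 2L]
  He <- .energy_hessian_bases(surf, lt, lz)
  act <- pmax(lt, lz) > cfg$threshold
  Hs <- if (any(act)) .stress_hessian_bases(surf, lt[act], lz[act]) else NULL

  data_fg <- function(coef) {
    st <- as.vector(A_t %*% coef) / sigma0
    sz <- as.vector(A_z %*% coef) / sigma0
    pt <- safe_log1p(st); pz <- safe_log1p(sz)
    rt <- pt - y_t; rz <- pz - y_z
    loss <- mean(rt^2 / den_t + rz^2 / den_z)
    gt <- 2 * rt / den_t * safe_log1p_grad(st) / nobs / sigma0
    gz <- 2 * rz / den_z * safe_log1p_grad(sz) / nobs / sigma0
    list(value = loss,
         grad = crossprod(A_t, gt)[, 1L] + crossprod(A_z, gz)[, 1L])
  }
  pen_fg <- function(coef, we, ws) {
    v <- 0; g <- numeric(length(coef))
    if (we > 0) {
      eigs <- .sym2x2_eigen(as.vector(He$zz %*% coef),
                            as.vector(He$zt %*% coef),
                            as.vector(He$tt %*% coef))
      v <- v + we * .eigen_hinge(eigs, cfg$hinge_tol)
      g <- g + we * .eigen_hinge_grad(coef, He$zz, He$zt, He$tt,
                                      cfg$hinge_tol)
    }
    if (ws > 0 && !is.null(Hs)) {
      for (comp in Hs) {
        eigs <- .sym2x2_eigen(as.vector(comp$zz %*% coef),
                              as.vector(comp$tz %*% coef),
                              as.vector(comp$tt %*% coef))
        v <- v + ws * .eigen_hinge(eigs, cfg$hinge_tol)
        g <- g + ws * .eigen_hinge_grad(coef, comp$zz, comp$tz, comp$tt,
                                        cfg$hinge_tol)
      }
    }
    list(value = v, grad = g)
  }

  coef <- surf$coef
  we <- cfg$weight_energy; ws <- cfg$weight_stress
  conv <- NA_integer_
  for (round in seq_len(max(1, penalty_rounds))) {
    fn <- function(cc) {
      d <- data_fg(cc); p <- pen_fg(cc, we, ws)
      d$value + p$value + ridge * sum(cc^2)
    }
    gr <- function(cc) {
      d <- data_fg(cc); p <- pen_fg(cc, we, ws)
      d$grad + p$grad + 2 * ridge * cc
    }
    fit <- stats::optim(coef, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit))
    coef <- fit$par
    conv <- fit$convergence
    if (!is.finite(fit$value))
      stop("fit_energy_surface(): divergent fit (non-finite loss)")
    surf$coef <- coef
    pe <- convexity_penalty_energy(surf, cfg)
    ps <- convexity_penalty_stress(surf, cfg)
    if (pe <= cfg$hinge_tol && ps <= cfg$hinge_tol) break
    we <- we * 20; ws <- ws * 20
  }
  surf$coef <- coef
  surf$fitted <- TRUE
  surf$diagnostics <- list(data_loss = data_fg(coef)$value,
                           penalty_energy = convexity_penalty_energy(surf, cfg),
                           penalty_stress = convexity_penalty_stress(surf, cfg),
                           rounds = round, convergence = conv,
                           n_obs = nobs)
  surf
}

#' Resample a fitted surface onto the structured stress grid
#'
#' @param surf a fitted [energy_surface()].
#' @param m grid size (default 31).
#' @param sigma0 normalisation constant (kPa).
#' @return a normalised [stress_grid()].  Stresses below the log-transform
#'   floor are clamped to it (documented; only reachable for a badly
#'   under-determined fit).
#' @export
resample_to_grid <- function(surf, m = 31, sigma0 = 1) {
  stopifnot(inherits(surf, "energy_surface"))
  st <- grid_stretches(m, surf$domain)
  s <- surface_stresses(surf, st[, 1L], st[, 2L])
  s <- pmax(s, -0.99 * sigma0)
  vals <- array(normalize_stress(as.vector(s), sigma0), dim = c(m, m, 2))
  stress_grid(vals, domain = surf$domain, normalized = TRUE, sigma0 = sigma0)
}
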