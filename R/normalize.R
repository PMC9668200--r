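#' Log-normalise a Cauchy stress
#'
#' Biaxial wall stresses span more than two orders of magnitude over the
#' working stretch domain, so all learning and fitting operates on the
#' log-transformed, normalised stress
#' \deqn{\tilde\sigma = \ln(\sigma/\sigma_0 + 1),}
#' with reference stress \eqn{\sigma_0 = 1} kPa.  The map is strictly
#' monotone and invertible; [denormalize_stress()] is its exact inverse.
#'
#' @param sigma numeric vector of stresses (kPa).
#' @param sigma0 reference stress (kPa), default 1.
#' @return dimensionless normalised stress, same shape as `sigma`.
#' @seealso [denormalize_stress()]
#' @export
#' @examples
#' normalize_stress(0)            # 0
#' normalize_stress(exp(1) - 1)   # 1
normalize_stress <- function(sigma, sigma0 = 1) {
  stopifnot(is.numeric(sigma), length(sigma0) == 1L, sigma0 > 0)
  if (any(sigma <= -sigma0, na.rm = TRUE)) {
    stop("normalize_stress(): stress must exceed -sigma0 = ", -sigma0,
         " kPa for the log transform to be defined")
  }
  log(sigma / sigma0 + 1)
}

#' Invert the log-normalisation of stress
#'
#' @param sigma_norm normalised stress (dimensionless).
#' @param sigma0 reference stress (kPa), default 1.
#' @return stress in kPa.
#' @export
denormalize_stress <- function(sigma_norm, sigma0 = 1) {
  stopifnot(is.numeric(sigma_norm), length(sigma0) == 1L, sigma0 > 0)
  sigma0 * (exp(sigma_norm) - 1)
}

# Smooth extension of log1p used inside fitting objectives only: below
# `lo` the curve continues linearly (value and slope matched) so that a
# transient iterate with sigma < -1 kPa cannot produce NaN.  Final fitted
# surfaces are validated against the strict transform.
safe_log1p <- function(x, lo = -0.5) {
  out <- x
  low <- x < lo
  out[!low] <- log1p(x[!low])
  out[low] <- log1p(lo) + (x[low] - lo) / (1 + lo)
  out
}

# derivative of safe_log1p
safe_log1p_grad <- function(x, lo = -0.5) {
  g <- ifelse(x < lo, 1 / (1 + lo), 1 / (1 + x))
  g
}
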