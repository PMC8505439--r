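# Poisson Fisher information and Cramer-Rao lower bounds for the
# eight-parameter image formation model.

#' Fisher information matrix at a parameter point
#'
#' Poisson imaging Fisher matrix
#' `I_ij = sum_k (dmu_k/dTheta_i)(dmu_k/dTheta_j) / mu_k` over the ROI
#' pixels, built from the analytic model derivatives. Angle entries are per
#' degree.
#'
#' @param theta an [emitterParams()] vector (needs `b > 0`).
#' @param basis a [PupilBasis-class], or an [OpticalConfig-class] (a
#'   zero-aberration basis is then built).
#' @param zernike aberration coefficients (mlambda), used when `basis` is a
#'   configuration.
#' @return symmetric 8 x 8 matrix with dimnames in parameter order.
#' @export
fisherMatrix <- function(theta, basis, zernike = rep(0, 12)) {
  if (is(basis, "OpticalConfig")) basis <- buildPupil(basis, zernike)
  m <- modelWithDerivatives(theta, basis)
  mu <- as.vector(m$mu)
  if (any(mu <= 0))
    stop("Fisher information undefined: zero-expectation pixels (need b > 0)")
  I <- crossprod(m$D, m$D / mu)
  dimnames(I) <- list(colnames(m$D), colnames(m$D))
  I
}

#' Cramer-Rao lower bound per parameter
#'
#' Square roots of the diagonal of the inverse Fisher matrix: the minimum
#' attainable standard deviation of an unbiased estimator of each of the
#' eight parameters, in nm (x, y, z), photons (N), photons/pixel (b),
#' degrees (phi, theta) and g2 units. Structurally non-identifiable
#' parameters (e.g. the azimuth of a dipole on the optical axis, or the
#' orientation of a fully free dipole) are reported as `Inf` rather than
#' raising an error.
#'
#' @inheritParams fisherMatrix
#' @return named numeric vector of length 8.
#' @examples
#' \donttest{
#' cfg <- opticalConfig(pupilSamples = 32L)
#' crlb(emitterParams(N = 4000, b = 10, theta = 60), cfg)
#' }
#' @export
crlb <- function(theta, basis, zernike = rep(0, 12)) {
  I <- fisherMatrix(theta, basis, zernike)
  crlbFromFisher(I)
}

crlbFromFisher <- function(I) {
  d <- diag(I)
  keep <- d > max(d) * 1e-12
  out <- rep(Inf, length(d))
  names(out) <- rownames(I)
  if (any(keep)) {
    Ik <- I[keep, keep, drop = FALSE]
    inv <- tryCatch(solve(Ik), error = function(e) {
      # ridge fallback for numerically singular information
      solve(Ik + diag(1e-10 * max(diag(Ik)), nrow(Ik)))
    })
    v <- diag(inv)
    v[v < 0] <- Inf
    out[keep] <- sqrt(v)
  }
  out
}
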