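# Vectorial pupil construction: Fresnel transmission through the
# medium/coverslip/immersion stack, aplanatic apodization, supercritical
# angle fluorescence (SAF), vortex phase and Zernike aberrations.

#' Vortex phase-mask phase profile
#'
#' Phase delay of a spiral phase plate of the given topological charge at
#' pupil azimuth `beta`: a single ramp from 0 to 2*pi*|charge|, so radially
#' opposing pupil points always differ by pi (for |charge| = 1). The phase is
#' independent of the pupil radius.
#'
#' @param beta pupil azimuth (radians).
#' @param charge topological charge: +1, -1 or 0.
#' @return phase in radians, same shape as `beta`.
#' @examples
#' vortexPhase(pi / 2, 1L)
#' @export
vortexPhase <- function(beta, charge = 1L) {
  if (!(charge %in% c(-1L, 0L, 1L)))
    stop("unsupported vortex charge: ", charge)
  charge * beta
}

# Amplitude transmission (s and p) through one interface; Snell handled via
# the conserved transverse wavevector, cos(theta) may be complex (SAF).
fresnelTs <- function(n1, n2, c1, c2) 2 * n1 * c1 / (n1 * c1 + n2 * c2)
fresnelTp <- function(n1, n2, c1, c2) 2 * n1 * c1 / (n2 * c1 + n1 * c2)

#' Build the sampled vectorial pupil
#'
#' Samples the pupil on a `pupilSamples` x `pupilSamples` Cartesian grid over
#' the unit disk and assembles, per grid point, the 2 x 3 complex matrix that
#' couples the dipole components (x, y, z) into the two transverse field
#' components on the camera. The amplitudes include s/p Fresnel transmission
#' through the three-layer stack, the aplanatic `1/sqrt(cos theta_imm)`
#' apodization and the supercritical zone (pupil radii beyond
#' `nMedium/NA`), where the medium-side axial wavevector is complex and the
#' coupling is evanescent. The static phase map combines the vortex ramp
#' (when `vortexCharge != 0`) and the Zernike aberration phase
#' `sum_j A_j Z_j(rho, beta)` with coefficients in mlambda. Emitter and
#' stage defocus are applied per emitter by the imaging routines using the
#' stored axial wavevectors (the two defocus terms carry opposite signs).
#'
#' @param config an [OpticalConfig-class].
#' @param zernike aberration coefficients in mlambda, one per entry of
#'   `modes` (default: 12 zeros on Noll modes 5 to 16).
#' @param modes Noll indices of the aberration modes.
#' @return A [PupilBasis-class] object.
#' @examples
#' pb <- buildPupil(opticalConfig(pupilSamples = 32L))
#' @export
buildPupil <- function(config, zernike = rep(0, 12), modes = 5:16) {
  stopifnot(is(config, "OpticalConfig"))
  validObject(config)
  if (length(zernike) != length(modes))
    stop("zernike must have one coefficient per mode (expected ",
         length(modes), ", got ", length(zernike), ")")
  P <- config@pupilSamples
  du <- 2 / P
  uu <- seq(-1 + du / 2, 1 - du / 2, length.out = P)
  U <- matrix(uu, P, P)
  V <- matrix(uu, P, P, byrow = TRUE)
  rho <- sqrt(U^2 + V^2)
  beta <- atan2(V, U)

  na <- config@na
  nm <- config@nMedium; nc <- config@nCoverslip; ni <- config@nImmersion
  k0 <- 2 * pi / config@wavelength
  a <- k0 * na

  # transverse wavevector is conserved: sin(theta_x) = na * rho / n_x
  csqrt <- function(x) matrix(sqrt(as.complex(x)), P, P)
  sinM <- na * rho / nm
  cosM <- csqrt(1 - sinM^2)                   # imaginary in the SAF zone
  cosM <- ifelse(Im(cosM) < 0, -cosM, cosM)   # decay into the medium
  dim(cosM) <- c(P, P)
  cosC <- csqrt(1 - (na * rho / nc)^2)
  cosI <- csqrt(1 - (na * rho / ni)^2)

  # collection path via reciprocity: transmission of the reversed wave
  # immersion -> coverslip -> medium; keeps the supercritical-angle
  # enhancement (the medium-side local field) instead of vanishing at the
  # critical angle.
  Ts <- fresnelTs(ni, nc, cosI, cosC) * fresnelTs(nc, nm, cosC, cosM)
  Tp <- fresnelTp(ni, nc, cosI, cosC) * fresnelTp(nc, nm, cosC, cosM)

  # aperture with a one-sample anti-aliased rim. Radial amplitude weighting:
  # aplanatic collection apodization 1/sqrt(cos theta_imm) combined with
  # flux-normalized interface transmission 1/sqrt(cos theta_imm cos theta_med),
  # i.e. A = 1/(cos theta_imm * sqrt(cos theta_med)). The 1/sqrt(cos theta_med)
  # factor carries the integrable near-singularity of the back-focal-plane
  # intensity at the critical angle for an emitter at the coverslip.
  apo <- pmin(pmax((1 - rho) / du + 0.5, 0), 1) /
    pmax(Re(cosI), 1e-8) / sqrt(pmax(Mod(cosM), 1e-8))

  cb <- cos(beta); sb <- sin(beta)
  # medium-side p/s unit vectors and camera-side projections
  qxx <- apo * (Tp * cosM * cb * cb + Ts * sb * sb)
  qxy <- apo * (Tp * cosM * cb * sb - Ts * sb * cb)
  qxz <- apo * (-Tp * sinM * cb)
  qyx <- apo * (Tp * cosM * sb * cb - Ts * cb * sb)
  qyy <- apo * (Tp * cosM * sb * sb + Ts * cb * cb)
  qyz <- apo * (-Tp * sinM * sb)
  q <- list(xx = qxx, xy = qxy, xz = qxz, yx = qyx, yy = qyy, yz = qyz)

  W <- vortexPhase(beta, config@vortexCharge)
  if (any(zernike != 0)) {
    for (i in seq_along(modes))
      if (zernike[i] != 0)
        W <- W + 2 * pi * zernike[i] / 1000 * zernikeNoll(modes[i], rho, beta)
  }
  phasor <- exp(1i * W)
  A <- lapply(q, function(m) m * phasor)

  kzMed <- k0 * nm * cosM
  kzImm <- k0 * ni * cosI

  os <- config@oversampling
  S <- config@roiSize * os
  sub <- (seq_len(S) - (S + 1) / 2) * config@pixelSize / os
  K <- exp(1i * a * outer(sub, uu))

  new("PupilBasis", config = config, zernike = as.numeric(zernike),
      modes = as.integer(modes), q = q, phase = W, A = A,
      kzMed = kzMed, kzImm = kzImm, U = U, V = V, rho = rho,
      a = a, du = du, K = K, subpix = sub)
}
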