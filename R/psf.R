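# Vectorial PSF image formation. Internally fields are evaluated with
# x along matrix rows; public images follow the (row = y, col = x)
# convention, with positions in nm relative to the ROI center and z > 0
# pointing from the coverslip into the medium.

#' Emitter parameter vector
#'
#' The eight quantities fitted per emitter: lateral position (nm, relative
#' to the ROI center), axial position z (nm, positive into the medium),
#' signal photons N (captured into the NA, spread over the entire image
#' plane), background b (photons/pixel), azimuthal angle phi (deg, [0, 180)),
#' polar angle theta (deg, [0, 180)) and the degree of orientational
#' constraint g2 in [0, 1] (0 = freely rotating, 1 = fixed dipole).
#'
#' @param x,y,z position (nm).
#' @param N signal photons.
#' @param b background photons per pixel.
#' @param phi,theta dipole orientation (degrees).
#' @param g2 rotational constraint.
#' @return named numeric vector of length 8.
#' @examples
#' emitterParams(N = 4000, b = 10, phi = 45, theta = 60, g2 = 0.75)
#' @export
emitterParams <- function(x = 0, y = 0, z = 0, N = 4000, b = 10,
                          phi = 90, theta = 90, g2 = 0.75) {
  if (g2 < 0 || g2 > 1) stop("g2 must lie in [0, 1]")
  if (N < 0 || b < 0) stop("N and b must be non-negative")
  c(x = x, y = y, z = z, N = N, b = b, phi = phi, theta = theta, g2 = g2)
}

#' Map dipole angles to the canonical hemisphere
#'
#' A dipole axis is antipodally symmetric: (theta, phi) and
#' (180 - theta, phi + 180) produce identical images. Estimates are reported
#' on the canonical hemisphere theta in [0, 180), phi in [0, 180).
#'
#' @param phi,theta angles in degrees.
#' @return named vector `c(phi, theta)` on the canonical hemisphere.
#' @export
canonicalAngles <- function(phi, theta) {
  theta <- theta %% 360
  if (theta >= 180) { theta <- 360 - theta; phi <- phi + 180 }
  phi <- phi %% 360
  if (phi >= 180) { phi <- phi - 180; theta <- 180 - theta }
  theta <- theta %% 180
  c(phi = phi, theta = theta)
}

dipoleVector <- function(phiDeg, thetaDeg) {
  p <- phiDeg * pi / 180; t <- thetaDeg * pi / 180
  c(sin(t) * cos(p), sin(t) * sin(p), cos(t))
}

# Evaluate the six complex field components (and optionally their x/y/z
# gradients) on the oversampled image grid for an emitter at (x, y, z) with
# the stage at zStage. Returns pupil-side quantities needed for the
# full-plane (Parseval) normalization.
fieldSet <- function(basis, x, y, z, zStage = 0, grad = FALSE) {
  K <- basis@K; du2 <- basis@du^2
  dyn <- exp(1i * (basis@kzMed * z - basis@kzImm * zStage -
                     basis@a * (basis@U * x + basis@V * y)))
  Q <- lapply(basis@A, function(m) m * dyn)
  tK <- t(K)
  E <- lapply(Q, function(m) du2 * (K %*% m %*% tK))
  out <- list(E = E, Q = Q)
  if (grad) {
    gx <- -1i * basis@a * basis@U
    gy <- -1i * basis@a * basis@V
    gz <- 1i * basis@kzMed
    out$Ex <- lapply(Q, function(m) du2 * (K %*% (m * gx) %*% tK))
    out$Ey <- lapply(Q, function(m) du2 * (K %*% (m * gy) %*% tK))
    out$Ez <- lapply(Q, function(m) du2 * (K %*% (m * gz) %*% tK))
  }
  out
}

# Parseval constant: integral over the full image plane of |E|^2 equals
# c0 * sum(|Q|^2) with the field conventions of fieldSet.
parsevalC0 <- function(basis) (2 * pi / basis@a)^2 * basis@du^2

# pixel binning of an oversampled intensity map: sums os x os subpixel
# blocks and multiplies by the subpixel area, yielding per-pixel integrals.
binPixels <- function(img, roi, os, pixelSize) {
  if (os == 1L) return(img * pixelSize^2)
  B <- matrix(0, roi, roi * os)
  for (p in seq_len(roi)) B[p, ((p - 1) * os + 1):(p * os)] <- 1
  (B %*% img %*% t(B)) * (pixelSize / os)^2
}

freeSums <- function(fs, basis, z) {
  decay <- exp(-2 * pmax(Im(basis@kzMed), 0) * z)
  w2 <- Reduce(`+`, lapply(basis@q, function(m) abs(m)^2))
  Sfree <- sum(w2 * decay)
  dSfree <- sum(w2 * decay * (-2 * pmax(Im(basis@kzMed), 0)))
  list(S = Sfree, dz = dSfree)
}

# Hermitian 3x3 pupil Gram matrices per polarization for the fixed dipole
# normalization: Sfix(Omega) = sum_l d' M_l d.
fixedGram <- function(basis, z, withZ = FALSE) {
  decay <- exp(-2 * pmax(Im(basis@kzMed), 0) * z)
  dz <- -2 * pmax(Im(basis@kzMed), 0)
  gram <- function(j1, j2, j3, w) {
    qs <- list(basis@q[[j1]], basis@q[[j2]], basis@q[[j3]])
    M <- matrix(0 + 0i, 3, 3)
    for (a in 1:3) for (b in a:3) {
      M[a, b] <- sum(Conj(qs[[a]]) * qs[[b]] * w)
      M[b, a] <- Conj(M[a, b])
    }
    M
  }
  Mx <- gram("xx", "xy", "xz", decay)
  My <- gram("yx", "yy", "yz", decay)
  out <- list(M = Re(Mx + My))
  if (withZ) out$Mz <- Re(gram("xx", "xy", "xz", decay * dz) +
                            gram("yx", "yy", "yz", decay * dz))
  out
}

intensitySum <- function(E) Reduce(`+`, lapply(E, function(m) abs(m)^2))

combineDipole <- function(E, d)
  list(x = E$xx * d[1] + E$xy * d[2] + E$xz * d[3],
       y = E$yx * d[1] + E$yy * d[2] + E$yz * d[3])

#' Fixed-dipole PSF component
#'
#' Pixel-integrated image of the fixed-dipole PSF for the orientation in
#' `theta`, normalized so that its integral over the entire image plane is 3
#' (so the image-formation mixture integrates to 1). The degree of
#' constraint `g2` in `theta` is ignored.
#'
#' @param theta an [emitterParams()] vector.
#' @param basis a [PupilBasis-class].
#' @param zStage stage defocus (nm); opposes the emitter z in sign.
#' @return `roiSize x roiSize` matrix (row = y, col = x).
#' @export
psfFixed <- function(theta, basis, zStage = 0) {
  cfg <- basis@config
  fs <- fieldSet(basis, theta["x"], theta["y"], theta["z"], zStage)
  d <- dipoleVector(theta["phi"], theta["theta"])
  F <- combineDipole(fs$E, d)
  G <- combineDipole(fs$Q, d)
  Sfix <- sum(abs(G$x)^2) + sum(abs(G$y)^2)
  raw <- abs(F$x)^2 + abs(F$y)^2
  img <- binPixels(3 * raw / (parsevalC0(basis) * Sfix),
                   cfg@roiSize, cfg@oversampling, cfg@pixelSize)
  t(img)
}

#' Free-dipole PSF component
#'
#' Pixel-integrated image of the freely rotating dipole PSF (incoherent
#' average over orientations, equivalently the sum over three orthogonal
#' dipoles), normalized to integrate to 3 over the full image plane. It is
#' rotationally symmetric about the optical axis when aberrations are zero
#' and independent of the dipole angles by construction.
#'
#' @param basis a [PupilBasis-class].
#' @param z emitter depth (nm).
#' @param zStage stage defocus (nm).
#' @return `roiSize x roiSize` matrix (row = y, col = x).
#' @export
psfFree <- function(basis, z = 0, zStage = 0) {
  cfg <- basis@config
  fs <- fieldSet(basis, 0, 0, z, zStage)
  Sfree <- sum(vapply(fs$Q, function(m) sum(abs(m)^2), numeric(1)))
  raw <- intensitySum(fs$E)
  img <- binPixels(3 * raw / (parsevalC0(basis) * Sfree),
                   cfg@roiSize, cfg@oversampling, cfg@pixelSize)
  t(img)
}

#' Expected photon image of an emitter
#'
#' Image formation model: the expected photon count per pixel is
#' `mu = N * [(1 - g2)/3 * Hfree + g2/3 * Hfixed] + b`, where the bracketed
#' mixture integrates to 1 over the entire image plane, so `N` counts the
#' photons captured into the NA over the whole field and `b` is a flat
#' background per pixel. Pixel values are integrals over the pixel area,
#' computed by oversampling and binning.
#'
#' @param theta an [emitterParams()] vector.
#' @param basis a [PupilBasis-class] (from [buildPupil()]).
#' @param zStage stage defocus (nm).
#' @return `roiSize x roiSize` matrix of expected photons/pixel
#'   (row = y, col = x).
#' @examples
#' pb <- buildPupil(opticalConfig(pupilSamples = 32L))
#' mu <- imageModel(emitterParams(), pb)
#' @export
imageModel <- function(theta, basis, zStage = 0) {
  m <- modelWithDerivatives(theta, basis, zStage, derivatives = FALSE)
  if (theta["b"] == 0 && any(m$mu <= 0))
    warning("b = 0 with zero-expectation pixels: Poisson likelihood is singular")
  m$mu
}

# Core model evaluation; optionally returns the 8 per-pixel partial
# derivatives (d mu / d Theta) needed by the Fisher matrix and the MLE.
# Angle derivatives are per degree.
modelWithDerivatives <- function(theta, basis, zStage = 0, derivatives = TRUE) {
  cfg <- basis@config
  x <- theta[["x"]]; y <- theta[["y"]]; z <- theta[["z"]]
  N <- theta[["N"]]; b <- theta[["b"]]; g2 <- theta[["g2"]]
  c0 <- parsevalC0(basis)
  fs <- fieldSet(basis, x, y, z, zStage, grad = derivatives)

  d <- dipoleVector(theta[["phi"]], theta[["theta"]])
  p <- theta[["phi"]] * pi / 180; tt <- theta[["theta"]] * pi / 180
  dTheta <- c(cos(tt) * cos(p), cos(tt) * sin(p), -sin(tt))
  dPhi <- c(-sin(tt) * sin(p), sin(tt) * cos(p), 0)

  fr <- freeSums(fs, basis, z)
  gm <- fixedGram(basis, z, withZ = derivatives)
  Sfix <- drop(d %*% gm$M %*% d)

  F <- combineDipole(fs$E, d)
  rawFree <- intensitySum(fs$E)
  rawFix <- abs(F$x)^2 + abs(F$y)^2
  bracketSub <- (1 - g2) * rawFree / (c0 * fr$S) + g2 * rawFix / (c0 * Sfix)

  bin <- function(m) binPixels(m, cfg@roiSize, cfg@oversampling, cfg@pixelSize)
  mu <- N * bin(bracketSub) + b
  out <- list(mu = t(mu))
  if (!derivatives) return(out)

  re2 <- function(A, B) 2 * (Re(A) * Re(B) + Im(A) * Im(B))  # 2 Re(conj(A) B)
  gradFree <- function(Eg) Reduce(`+`, Map(function(e, g) re2(e, g), fs$E, Eg))
  gradFixF <- function(Eg) {
    Fg <- combineDipole(Eg, d)
    re2(F$x, Fg$x) + re2(F$y, Fg$y)
  }
  dBdx <- (1 - g2) * gradFree(fs$Ex) / (c0 * fr$S) +
    g2 * gradFixF(fs$Ex) / (c0 * Sfix)
  dBdy <- (1 - g2) * gradFree(fs$Ey) / (c0 * fr$S) +
    g2 * gradFixF(fs$Ey) / (c0 * Sfix)

  dRawFreeZ <- gradFree(fs$Ez)
  dRawFixZ <- gradFixF(fs$Ez)
  dSfixZ <- drop(d %*% gm$Mz %*% d)
  dBdz <- (1 - g2) * (dRawFreeZ * fr$S - rawFree * fr$dz) / (c0 * fr$S^2) +
    g2 * (dRawFixZ * Sfix - rawFix * dSfixZ) / (c0 * Sfix^2)

  angGrad <- function(dd) {
    Fg <- combineDipole(fs$E, dd)
    dRaw <- re2(F$x, Fg$x) + re2(F$y, Fg$y)
    dS <- 2 * drop(d %*% gm$M %*% dd)
    g2 * (dRaw * Sfix - rawFix * dS) / (c0 * Sfix^2) * pi / 180
  }
  dBdphi <- angGrad(dPhi)
  dBdtheta <- angGrad(dTheta)
  dBdg2 <- -rawFree / (c0 * fr$S) + rawFix / (c0 * Sfix)

  K2 <- cfg@roiSize^2
  D <- cbind(
    x = as.vector(t(N * bin(dBdx))),
    y = as.vector(t(N * bin(dBdy))),
    z = as.vector(t(N * bin(dBdz))),
    N = as.vector(t(bin(bracketSub))),
    b = rep(1, K2),
    phi = as.vector(t(N * bin(dBdphi))),
    theta = as.vector(t(N * bin(dBdtheta))),
    g2 = as.vector(t(N * bin(dBdg2))))
  out$D <- D
  out
}

#' Per-pixel model derivatives
#'
#' Partial derivatives of the expected photon image with respect to the
#' eight emitter parameters, evaluated analytically (angles per degree).
#' Central finite differences on [imageModel()] are the reference these
#' must agree with.
#'
#' @inheritParams imageModel
#' @return list with `mu` (expected image, row = y) and `D`, a
#'   `npixels x 8` matrix of derivatives in the parameter order of
#'   [emitterParams()]; pixels are flattened row-major from the public
#'   image orientation.
#' @export
modelDerivatives <- function(theta, basis, zStage = 0) {
  if (theta[["b"]] <= 0)
    warning("derivatives with b = 0: Fisher weights are singular on empty pixels")
  modelWithDerivatives(theta, basis, zStage, derivatives = TRUE)
}

#' Fraction of signal photons captured inside the ROI
#'
#' Ratio of the image-formation mixture mass inside the ROI to its
#' full-plane mass (= 1 by normalization), for an in-focus centered emitter.
#' The reference case is a freely rotating dipole (g2 = 0).
#'
#' @param config an [OpticalConfig-class].
#' @param mode `"vortex"` or `"standard"` (no phase mask); overrides the
#'   configured charge.
#' @param theta optional [emitterParams()] overriding the reference emitter.
#' @return capture fraction in (0, 1).
#' @examples
#' \donttest{roiCaptureFraction(opticalConfig(), "vortex")}
#' @export
roiCaptureFraction <- function(config, mode = c("vortex", "standard"),
                               theta = NULL) {
  mode <- match.arg(mode)
  config@vortexCharge <- if (mode == "vortex") 1L else 0L
  if (is.null(theta)) theta <- emitterParams(N = 1, b = 0, g2 = 0)
  theta[["N"]] <- 1; theta[["b"]] <- 0
  basis <- buildPupil(config)
  sum(imageModel(theta, basis))
}
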