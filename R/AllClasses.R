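#' @import methods
NULL

#' Optical and camera configuration
#'
#' Immutable collection of the optical constants that define the imaging
#' model: objective NA, emission wavelength, the refractive index stack
#' (imaging medium / coverslip / immersion oil), object-space pixel pitch,
#' fitting ROI size, pupil sampling, the topological charge of the vortex
#' phase mask, and the per-pixel oversampling factor used for pixel
#' integration.
#'
#' The defaults reproduce the reference configuration: NA 1.45, wavelength
#' 597.5 nm, indices 1.33/1.523/1.518, 65 nm pixels and a 15 x 15 ROI.
#'
#' @slot na numerical aperture (dimensionless).
#' @slot wavelength emission wavelength (nm).
#' @slot nMedium,nCoverslip,nImmersion refractive indices of the imaging
#'   medium, coverslip and immersion oil.
#' @slot pixelSize object-space pixel pitch (nm).
#' @slot roiSize ROI side length in pixels (odd, >= 7).
#' @slot pupilSamples pupil grid side length (>= 32).
#' @slot vortexCharge topological charge of the phase mask: +1, -1 or 0
#'   (0 = standard, unengineered PSF).
#' @slot oversampling per-pixel subsampling factor for pixel integration.
#' @export
setClass("OpticalConfig", representation(
  na = "numeric", wavelength = "numeric",
  nMedium = "numeric", nCoverslip = "numeric", nImmersion = "numeric",
  pixelSize = "numeric", roiSize = "integer",
  pupilSamples = "integer", vortexCharge = "integer",
  oversampling = "integer"
))

setValidity("OpticalConfig", function(object) {
  msg <- character()
  if (object@na > object@nImmersion)
    msg <- c(msg, "NA must not exceed the immersion refractive index")
  if (object@roiSize %% 2L != 1L || object@roiSize < 7L)
    msg <- c(msg, "roiSize must be odd and >= 7")
  if (object@pupilSamples < 32L)
    msg <- c(msg, "pupilSamples must be >= 32")
  if (!(object@vortexCharge %in% c(-1L, 0L, 1L)))
    msg <- c(msg, "vortexCharge must be one of -1, 0, +1")
  if (object@oversampling < 1L)
    msg <- c(msg, "oversampling must be >= 1")
  if (any(c(object@na, object@wavelength, object@pixelSize) <= 0))
    msg <- c(msg, "na, wavelength and pixelSize must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an optical configuration
#'
#' @param na numerical aperture.
#' @param wavelength emission wavelength (nm).
#' @param nMedium,nCoverslip,nImmersion refractive index stack.
#' @param pixelSize object-space pixel size (nm).
#' @param roiSize ROI side (pixels, odd).
#' @param pupilSamples pupil grid side.
#' @param vortexCharge +1, -1 or 0 (standard PSF).
#' @param oversampling per-pixel subsampling factor.
#' @return An [OpticalConfig-class] object.
#' @examples
#' cfg <- opticalConfig()
#' cfg
#' @export
opticalConfig <- function(na = 1.45, wavelength = 597.5,
                          nMedium = 1.33, nCoverslip = 1.523,
                          nImmersion = 1.518, pixelSize = 65,
                          roiSize = 15L, pupilSamples = 64L,
                          vortexCharge = 1L, oversampling = 3L) {
  new("OpticalConfig", na = na, wavelength = wavelength,
      nMedium = nMedium, nCoverslip = nCoverslip, nImmersion = nImmersion,
      pixelSize = pixelSize, roiSize = as.integer(roiSize),
      pupilSamples = as.integer(pupilSamples),
      vortexCharge = as.integer(vortexCharge),
      oversampling = as.integer(oversampling))
}

#' @describeIn OpticalConfig-class numerical aperture accessor
#' @param object an `OpticalConfig`.
#' @export
setGeneric("objectiveNA", function(object) standardGeneric("objectiveNA"))
#' @export
setMethod("objectiveNA", "OpticalConfig", function(object) object@na)

#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @describeIn OpticalConfig-class object-space pixel size (nm)
#' @export
setMethod("pixelSize", "OpticalConfig", function(object) object@pixelSize)

#' @export
setGeneric("roiSize", function(object) standardGeneric("roiSize"))
#' @describeIn OpticalConfig-class ROI side length (pixels)
#' @export
setMethod("roiSize", "OpticalConfig", function(object) object@roiSize)

#' @export
setGeneric("vortexCharge", function(object) standardGeneric("vortexCharge"))
#' @describeIn OpticalConfig-class vortex phase-mask topological charge
#' @export
setMethod("vortexCharge", "OpticalConfig", function(object) object@vortexCharge)

setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig\n",
      sprintf("  NA %.3f, lambda %.1f nm, n = %.3f/%.3f/%.3f\n",
              object@na, object@wavelength, object@nMedium,
              object@nCoverslip, object@nImmersion),
      sprintf("  pixel %.1f nm, ROI %d x %d px, pupil %d x %d, charge %+d, oversampling %d\n",
              object@pixelSize, object@roiSize, object@roiSize,
              object@pupilSamples, object@pupilSamples,
              object@vortexCharge, object@oversampling), sep = "")
})

#' Sampled pupil-plane field basis
#'
#' Holds the vectorial pupil of the imaging model sampled on a Cartesian
#' grid inside the unit disk: the 2 x 3 complex amplitude matrix coupling
#' the dipole components (x, y, z) into the two transverse camera field
#' components, including Fresnel transmission through the
#' medium/coverslip/immersion stack, aplanatic apodization and the
#' supercritical-angle (evanescent) zone; the static phase map (vortex
#' ramp plus Zernike aberrations); and the axial wavevectors used for the
#' emitter- and stage-side defocus terms.
#'
#' Objects are created by [buildPupil()] and consumed by the PSF and
#' fitting routines.
#'
#' @slot config the [OpticalConfig-class] used to build the basis.
#' @slot zernike Zernike coefficients (mlambda) for the modes in `modes`.
#' @slot modes Noll indices of the aberration modes.
#' @slot q list of six complex pupil amplitude matrices, order
#'   (l = 1,2) x (j = x,y,z).
#' @slot phase static phase map W (radians): vortex plus aberrations.
#' @slot A list of six matrices `q * exp(iW)` (precombined).
#' @slot kzMed,kzImm complex axial wavevectors (rad/nm) on the grid;
#'   `kzMed` is complex in the supercritical zone.
#' @slot U,V,rho normalized pupil coordinate grids.
#' @slot a lateral wavenumber scale `2 pi NA / lambda` (rad/nm).
#' @slot du pupil grid spacing.
#' @slot K complex DFT kernel mapping the pupil to the oversampled
#'   image-plane grid.
#' @slot subpix subpixel center coordinates (nm, relative to ROI center).
#' @export
setClass("PupilBasis", representation(
  config = "OpticalConfig", zernike = "numeric", modes = "integer",
  q = "list", phase = "matrix", A = "list",
  kzMed = "matrix", kzImm = "matrix",
  U = "matrix", V = "matrix", rho = "matrix",
  a = "numeric", du = "numeric", K = "matrix", subpix = "numeric"
))

setMethod("show", "PupilBasis", function(object) {
  cat("PupilBasis\n",
      sprintf("  pupil %d x %d (du = %.4f), image grid %d x %d subpixels\n",
              nrow(object@rho), ncol(object@rho), object@du,
              length(object@subpix), length(object@subpix)),
      sprintf("  aberrations: %s mlambda on Noll modes %s\n",
              paste(signif(object@zernike, 3), collapse = " "),
              paste(object@modes, collapse = " ")), sep = "")
})

#' Field-dependent aberration map (Nodal Aberration Theory)
#'
#' Represents the 12 Zernike aberration coefficients as smooth functions of
#' the field position, with the functional forms prescribed by Nodal
#' Aberration Theory: the astigmatism pair as a complex quadratic polynomial
#' in the complex field coordinate h, the coma pair as a complex linear
#' polynomial, and the remaining modes as real 2D quadratics.
#'
#' @slot modes Noll indices of the mapped modes (default 5:16).
#' @slot astig complex coefficients (c0, c1, c2) of the astigmatism pair.
#' @slot coma complex coefficients (b0, b1) of the coma pair.
#' @slot others real coefficient matrix, one row per remaining mode, columns
#'   (1, hx, hy, hx^2, hx*hy, hy^2).
#' @slot otherModes Noll indices of the rows of `others`.
#' @slot fovRadius field normalization radius (same units as bead positions).
#' @slot residualRms per-mode root-mean-square fit residual (mlambda).
#' @export
setClass("AberrationMap", representation(
  modes = "integer", astig = "complex", coma = "complex",
  others = "matrix", otherModes = "integer",
  fovRadius = "numeric", residualRms = "numeric"
))

setValidity("AberrationMap", function(object) {
  msg <- character()
  if (length(object@astig) != 3L) msg <- c(msg, "astig needs 3 coefficients")
  if (length(object@coma) != 2L) msg <- c(msg, "coma needs 2 coefficients")
  if (object@fovRadius <= 0) msg <- c(msg, "fovRadius must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AberrationMap", function(object) {
  nodes <- natNodes(object)
  cat("AberrationMap (NAT)\n",
      sprintf("  modes: Noll %s\n", paste(object@modes, collapse = " ")),
      sprintf("  astigmatism nodes (normalized field): %s\n",
              paste(sprintf("(%.3f, %.3f)", Re(nodes$astig), Im(nodes$astig)),
                    collapse = " ")),
      sprintf("  coma node: (%.3f, %.3f)\n",
              Re(nodes$coma), Im(nodes$coma)),
      sprintf("  FOV radius: %.1f\n", object@fovRadius), sep = "")
})
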