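# Readers and writers: TIFF stacks, CSV localization tables, YAML
# configuration and aberration maps. Lengths are nm and angles degrees in
# all files.

#' Read a (multi-page) TIFF stack
#'
#' @param path TIFF file.
#' @param gain,offset optional camera calibration; when supplied, frames
#'   are converted from ADU to photons via [photonConvert()].
#' @return list of numeric matrices (row = y, col = x).
#' @export
readStack <- function(path, gain = NULL, offset = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  imgsInt <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  imgsRaw <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgsInt)) { imgsInt <- list(imgsInt); imgsRaw <- list(imgsRaw) }
  frames <- lapply(seq_along(imgsInt), function(i) {
    mi <- imgsInt[[i]]
    # integer TIFFs (camera ADU) come back as counts under as.is;
    # float TIFFs are only valid in the normalized read
    m <- if (all(is.finite(mi)) && max(abs(mi)) < 2^31 - 1 &&
             all(mi == round(mi)) && min(mi) >= 0) mi * 1.0 else
               imgsRaw[[i]] * 1.0
    if (length(dim(m)) == 3) m <- m[, , 1]
    m
  })
  if (!is.null(gain)) frames <- lapply(frames, photonConvert, gain = gain,
                                       offset = offset %||% 0)
  frames
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a stack of images as multi-page TIFF
#'
#' Images whose values all lie in \[0, 1\] are stored as 32-bit float;
#' photon-scale images are rounded and stored as 16-bit integer counts
#' (the format cannot represent fractional values above 1).
#'
#' @param frames list of numeric matrices (or one matrix).
#' @param path output file.
#' @export
writeStack <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1] >= 0 && rng[2] <= 1) {
    tiff::writeTIFF(frames, path, bits.per.sample = 32, reduce = FALSE)
  } else {
    ints <- lapply(frames, function(m) pmin(pmax(round(m), 0), 65535) / 65535)
    tiff::writeTIFF(ints, path, bits.per.sample = 16, reduce = FALSE)
  }
  invisible(path)
}

#' Write / read a localization table
#'
#' CSV with the estimator schema (positions in nm, angles in degrees,
#' per-parameter CRLBs, chi-squared and rejection reason). The round-trip
#' is lossless up to numeric text precision.
#'
#' @param table localization data.frame.
#' @param path file path.
#' @return `readLocs` returns the data.frame.
#' @export
writeLocs <- function(table, path) {
  utils::write.csv(format(table, digits = 12, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLocs
#' @export
readLocs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

configSchema <- c("na", "wavelength", "n_medium", "n_coverslip",
                  "n_immersion", "pixel_size")

#' Read a run configuration from YAML
#'
#' Expects an `optics` block (keys `na`, `wavelength`, `n_medium`,
#' `n_coverslip`, `n_immersion`, `pixel_size`, and optionally `roi_size`,
#' `pupil_samples`, `vortex_charge`, `oversampling`), an optional `camera`
#' block (`gain`, `offset`), and an optional `fitting` block whose defaults
#' are the standard stopping and filter constants (`max_iter` 30,
#' `loglik_tol` 1e-6, `chi2_min` 0.75, `chi2_max` 3, `max_center_dist_px`
#' 3).
#'
#' @param path YAML file.
#' @return list with `optics` (an [OpticalConfig-class]), `camera`,
#'   `fitting`, and `raw` (the parsed file, echoed for provenance).
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  o <- y$optics %||% y
  missing <- setdiff(configSchema, names(o))
  if (length(missing))
    stop("config schema error: missing key(s) ",
         paste(missing, collapse = ", "))
  optics <- opticalConfig(
    na = o$na, wavelength = o$wavelength, nMedium = o$n_medium,
    nCoverslip = o$n_coverslip, nImmersion = o$n_immersion,
    pixelSize = o$pixel_size, roiSize = o$roi_size %||% 15L,
    pupilSamples = o$pupil_samples %||% 64L,
    vortexCharge = o$vortex_charge %||% 1L,
    oversampling = o$oversampling %||% 3L)
  fitting <- utils::modifyList(
    list(max_iter = 30L, loglik_tol = 1e-6, chi2_min = 0.75, chi2_max = 3,
         max_center_dist_px = 3),
    y$fitting %||% list())
  list(optics = optics, camera = y$camera, fitting = fitting, raw = y)
}

#' Serialize / restore an aberration map
#'
#' YAML with mode names, the complex NAT polynomial coefficients (as
#' re/im pairs), the real quadratic coefficients of the remaining modes,
#' and the FOV normalization radius.
#'
#' @param map an [AberrationMap-class].
#' @param path file path.
#' @export
writeAberrationMap <- function(map, path) {
  y <- list(
    modes = as.integer(map@modes),
    fov_radius = map@fovRadius,
    astigmatism = list(re = Re(map@astig), im = Im(map@astig)),
    coma = list(re = Re(map@coma), im = Im(map@coma)),
    others = stats::setNames(lapply(seq_len(nrow(map@others)), function(i)
      as.numeric(map@others[i, ])), rownames(map@others)))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname writeAberrationMap
#' @return `readAberrationMap` returns the [AberrationMap-class].
#' @export
readAberrationMap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  others <- do.call(rbind, y$others)
  rownames(others) <- names(y$others)
  new("AberrationMap", modes = as.integer(y$modes),
      astig = complex(real = y$astigmatism$re, imaginary = y$astigmatism$im),
      coma = complex(real = y$coma$re, imaginary = y$coma$im),
      others = others,
      otherModes = as.integer(sub("noll", "", names(y$others))),
      fovRadius = y$fov_radius, residualRms = numeric(0))
}

#' Render localizations as a Gaussian-blurred image
#'
#' Convenience super-resolution renderer: each accepted localization adds
#' a unit-integral Gaussian of width equal to its lateral uncertainty.
#'
#' @param table localization data.frame (`x_nm`, `y_nm`, `crlb_x`,
#'   `crlb_y`, `rejected_reason`).
#' @param pixelSize super-resolution pixel (nm, default 6.5).
#' @param sigmaFloor minimum rendering sigma (nm).
#' @return matrix image (row = y, col = x) with attributes `xRange`,
#'   `yRange`.
#' @export
renderGaussian <- function(table, pixelSize = 6.5, sigmaFloor = 3) {
  tab <- table[table$rejected_reason == "none", , drop = FALSE]
  if (!nrow(tab)) stop("no accepted localizations to render")
  xr <- range(tab$x_nm) + c(-50, 50)
  yr <- range(tab$y_nm) + c(-50, 50)
  nx <- ceiling(diff(xr) / pixelSize); ny <- ceiling(diff(yr) / pixelSize)
  img <- matrix(0, ny, nx)
  xs <- xr[1] + (seq_len(nx) - 0.5) * pixelSize
  ys <- yr[1] + (seq_len(ny) - 0.5) * pixelSize
  for (i in seq_len(nrow(tab))) {
    sx <- max(tab$crlb_x[i], sigmaFloor); sy <- max(tab$crlb_y[i], sigmaFloor)
    gx <- stats::dnorm(xs, tab$x_nm[i], sx)
    gy <- stats::dnorm(ys, tab$y_nm[i], sy)
    img <- img + outer(gy, gx) * pixelSize^2
  }
  attr(img, "xRange") <- xr; attr(img, "yRange") <- yr
  img
}
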