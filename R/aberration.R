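# Field-dependent aberration calibration: per-bead Zernike retrieval from
# through-focus stacks, and Nodal Aberration Theory (NAT) fitting of the
# coefficient field-dependence. NAT constrains the astigmatism pair to a
# complex quadratic and the coma pair to a complex linear polynomial in the
# complex field coordinate h, producing the characteristic zero loci
# ("nodes"): up to two for astigmatism, one for coma.

# free-dipole expected images and derivatives for a through-focus bead
# stack, including derivatives with respect to the Zernike coefficients
# (pure phase modes, so the normalization is coefficient-independent).
beadStackModel <- function(par, basis0, zStage, zernikeMaps, derivatives = TRUE) {
  cfg <- basis0@config
  nz <- length(zernikeMaps)
  W <- basis0@phase
  for (j in seq_len(nz))
    if (par$zern[j] != 0)
      W <- W + 2 * pi * par$zern[j] / 1000 * zernikeMaps[[j]]
  basis <- basis0
  basis@A <- lapply(basis0@q, function(m) m * exp(1i * W))
  c0 <- parsevalC0(basis)
  out <- vector("list", length(zStage))
  scale <- 2 * pi / 1000
  for (s in seq_along(zStage)) {
    fs <- fieldSet(basis, par$x, par$y, par$z, zStage[s], grad = derivatives)
    Sfree <- sum(vapply(fs$Q, function(m) sum(abs(m)^2), numeric(1)))
    dSz <- sum(vapply(fs$Q, function(m)
      sum(abs(m)^2 * (-2 * pmax(Im(basis@kzMed), 0))), numeric(1)))
    raw <- intensitySum(fs$E)
    bin <- function(m) t(binPixels(m, cfg@roiSize, cfg@oversampling,
                                   cfg@pixelSize))
    B <- raw / (c0 * Sfree)
    mu <- par$N * bin(B) + par$b
    sl <- list(mu = mu)
    if (derivatives) {
      re2 <- function(A, Bc) 2 * (Re(A) * Re(Bc) + Im(A) * Im(Bc))
      gsum <- function(Eg) Reduce(`+`, Map(re2, fs$E, Eg))
      sl$dx <- par$N * bin(gsum(fs$Ex) / (c0 * Sfree))
      sl$dy <- par$N * bin(gsum(fs$Ey) / (c0 * Sfree))
      sl$dz <- par$N * bin((gsum(fs$Ez) * Sfree - raw * dSz) / (c0 * Sfree^2))
      sl$dN <- bin(B)
      sl$dzern <- vector("list", nz)
      for (j in seq_len(nz)) {
        Ej <- lapply(fs$Q, function(m)
          basis0@du^2 * (basis@K %*% (m * (1i * scale * zernikeMaps[[j]])) %*%
                           t(basis@K)))
        sl$dzern[[j]] <- par$N * bin(gsum(Ej) / (c0 * Sfree))
      }
    }
    out[[s]] <- sl
  }
  out
}

#' Retrieve Zernike aberrations from a bead through-focus stack
#'
#' Joint maximum likelihood fit over all focal slices of a through-focus
#' stack of a bead (modeled as a freely rotating dipole): lateral position,
#' focus offset, a shared photon count per slice, background, and the
#' Zernike coefficients of the configured modes.
#'
#' @param zstack list of photon images (row = y, col = x), one per slice.
#' @param zPositions stage z per slice (nm; opposing sign to emitter z).
#' @param config an [OpticalConfig-class] whose `roiSize` matches the
#'   slices.
#' @param modes Noll indices of the fitted aberration modes.
#' @param maxIter,tol optimization controls.
#' @return list with `zernike` (mlambda), `theta` (x, y, z, N, b), `chi2`
#'   (normalized, pooled over slices), `converged`.
#' @export
retrieveBeadZernikes <- function(zstack, zPositions, config, modes = 5:16,
                                 maxIter = 60L, tol = 1e-7) {
  stopifnot(length(zstack) == length(zPositions))
  basis0 <- buildPupil(config, rep(0, length(modes)), modes)
  beta <- atan2(basis0@V, basis0@U)
  zernikeMaps <- lapply(modes, function(j) zernikeNoll(j, basis0@rho, beta))
  K2 <- config@roiSize^2
  nAll <- unlist(zstack)

  ini <- initialEstimate(zstack[[which.min(abs(zPositions))]], config, 0.5)
  par <- list(x = ini[["x"]], y = ini[["y"]], z = 0,
              N = ini[["N"]], b = ini[["b"]], zern = rep(0, length(modes)))

  packMu <- function(md) unlist(lapply(md, `[[`, "mu"))
  packD <- function(md) {
    cols <- c(list(x = unlist(lapply(md, `[[`, "dx")),
                   y = unlist(lapply(md, `[[`, "dy")),
                   z = unlist(lapply(md, `[[`, "dz")),
                   N = unlist(lapply(md, `[[`, "dN")),
                   b = rep(1, length(md) * K2)),
              stats::setNames(lapply(seq_along(modes), function(j)
                unlist(lapply(md, function(s) s$dzern[[j]]))),
                paste0("z", modes)))
    do.call(cbind, cols)
  }
  getEta <- function(p) c(p$x, p$y, p$z, log(p$N), log(max(p$b, 1e-3)), p$zern)
  setEta <- function(e) list(x = e[1], y = e[2], z = e[3], N = exp(e[4]),
                             b = exp(e[5]), zern = e[-(1:5)])

  md <- beadStackModel(par, basis0, zPositions, zernikeMaps)
  mu <- pmax(packMu(md), 1e-12)
  ll <- poissonLogLik(nAll, mu)
  lambda <- 1e-3; converged <- FALSE
  for (iter in seq_len(maxIter)) {
    D <- packD(md)
    J <- c(1, 1, 1, par$N, par$b, rep(1, length(modes)))
    De <- sweep(D, 2, J, `*`)
    score <- crossprod(De, nAll / mu - 1)
    I <- crossprod(De, De / mu)
    ok <- FALSE
    for (try in 1:8) {
      H <- I + lambda * diag(pmax(diag(I), 1e-8))
      delta <- tryCatch(solve(H, score), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      parNew <- setEta(getEta(par) + as.vector(delta))
      mdNew <- beadStackModel(parNew, basis0, zPositions, zernikeMaps)
      muNew <- pmax(packMu(mdNew), 1e-12)
      llNew <- poissonLogLik(nAll, muNew)
      if (is.finite(llNew) && llNew >= ll - 1e-9) {
        dll <- abs(llNew - ll) / max(abs(ll), 1e-8)
        par <- parNew; md <- mdNew; mu <- muNew; ll <- llNew
        lambda <- max(lambda / 5, 1e-8); ok <- TRUE
        if (dll < tol) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!ok) { converged <- TRUE; break }
    if (converged) break
  }
  if (!converged)
    warning("bead calibration did not converge; coefficients unreliable")
  list(zernike = stats::setNames(par$zern, paste0("noll", modes)),
       theta = c(x = par$x, y = par$y, z = par$z, N = par$N, b = par$b),
       chi2 = mean((nAll - mu)^2 / mu), converged = converged)
}

#' Fit a NAT aberration map to bead calibrations
#'
#' Weighted least squares of the Nodal-Aberration-Theory field polynomials
#' to per-bead Zernike coefficients: the astigmatism pair (Noll 6 + i Noll
#' 5) as `c0 + c1 h + c2 h^2` and the coma pair (Noll 8 + i Noll 7) as
#' `b0 + b1 h` in the normalized complex field coordinate
#' `h = (x + i y)/fovRadius`; all remaining modes as real quadratics in
#' (hx, hy).
#'
#' @param calibrations data.frame with columns `fieldX`, `fieldY` (same
#'   units as `fovRadius`), one column per mode named `noll5` ... `noll16`,
#'   and optionally `weight` (inverse-variance weights).
#' @param fovRadius field normalization radius; default: the largest bead
#'   field radius.
#' @param modes Noll indices present (must contain 5:8).
#' @return An [AberrationMap-class].
#' @export
fitNatMap <- function(calibrations, fovRadius = NULL, modes = 5:16) {
  need <- paste0("noll", modes)
  if (!all(need %in% names(calibrations)))
    stop("calibrations must contain columns ", paste(need, collapse = ", "))
  if (nrow(calibrations) < 12)
    stop("need at least 12 beads spread over the FOV")
  if (is.null(fovRadius))
    fovRadius <- max(sqrt(calibrations$fieldX^2 + calibrations$fieldY^2))
  h <- complex(real = calibrations$fieldX, imaginary = calibrations$fieldY) /
    fovRadius
  w <- if ("weight" %in% names(calibrations)) calibrations$weight else
    rep(1, nrow(calibrations))
  sw <- sqrt(w / mean(w))

  cplxFit <- function(obs, deg) {
    X <- sapply(0:deg, function(k) h^k)
    if (qr(X)$rank < ncol(X))
      stop("rank-deficient design: bead field positions cannot constrain ",
           "degree-", deg, " NAT terms (beads collinear or coincident?)")
    qr.solve(X * sw, obs * sw)
  }
  astigObs <- complex(real = calibrations$noll6, imaginary = calibrations$noll5)
  comaObs <- complex(real = calibrations$noll8, imaginary = calibrations$noll7)
  astig <- cplxFit(astigObs, 2)
  coma <- cplxFit(comaObs, 1)

  otherModes <- setdiff(modes, 5:8)
  Xr <- cbind(1, Re(h), Im(h), Re(h)^2, Re(h) * Im(h), Im(h)^2)
  if (qr(Xr)$rank < ncol(Xr))
    stop("rank-deficient design: bead field positions cannot constrain ",
         "quadratic terms (beads collinear?)")
  others <- t(vapply(otherModes, function(mo) {
    qr.solve(Xr * sw, calibrations[[paste0("noll", mo)]] * sw)
  }, numeric(6)))
  rownames(others) <- paste0("noll", otherModes)

  map <- new("AberrationMap", modes = as.integer(modes), astig = astig,
             coma = coma, others = others,
             otherModes = as.integer(otherModes), fovRadius = fovRadius,
             residualRms = numeric(0))
  # residuals at the calibration positions themselves (corner beads may
  # sit just outside the normalization radius; that is not extrapolation)
  pred <- t(vapply(seq_len(nrow(calibrations)), function(i)
    suppressWarnings(
      evaluateMap(map, c(calibrations$fieldX[i], calibrations$fieldY[i]))),
    numeric(length(modes))))
  obs <- as.matrix(calibrations[need])
  map@residualRms <- stats::setNames(
    sqrt(colMeans((pred - obs)^2)), need)
  map
}

#' Evaluate an aberration map at a field position
#'
#' @param map an [AberrationMap-class].
#' @param fieldPosition numeric `c(x, y)` in the units of the map's
#'   `fovRadius`.
#' @return named vector of Zernike coefficients (mlambda) for the map's
#'   modes; carries attribute `extrapolated = TRUE` when the position lies
#'   outside the calibrated radius (with a warning).
#' @export
evaluateMap <- function(map, fieldPosition) {
  h <- complex(real = fieldPosition[1], imaginary = fieldPosition[2]) /
    map@fovRadius
  extra <- Mod(h) > 1.0001
  if (extra)
    warning("field position outside the calibrated FOV radius; extrapolating")
  a <- map@astig[1] + map@astig[2] * h + map@astig[3] * h^2
  cm <- map@coma[1] + map@coma[2] * h
  out <- stats::setNames(numeric(length(map@modes)),
                         paste0("noll", map@modes))
  out["noll5"] <- Im(a); out["noll6"] <- Re(a)
  out["noll7"] <- Im(cm); out["noll8"] <- Re(cm)
  if (length(map@otherModes)) {
    Xr <- c(1, Re(h), Im(h), Re(h)^2, Re(h) * Im(h), Im(h)^2)
    out[rownames(map@others)] <- as.vector(map@others %*% Xr)
  }
  if (extra) attr(out, "extrapolated") <- TRUE
  out
}

#' Field nodes of a NAT map
#'
#' Zero loci of the paired aberrations: the (up to) two roots of the
#' astigmatism quadratic and the single root of the coma linear polynomial,
#' in normalized field coordinates.
#'
#' @param map an [AberrationMap-class].
#' @return list with complex vectors `astig` (length 2) and `coma`
#'   (length 1).
#' @export
natNodes <- function(map) {
  c2 <- map@astig[3]; c1 <- map@astig[2]; c0 <- map@astig[1]
  astig <- if (Mod(c2) < 1e-12 * max(Mod(c1), Mod(c0), 1)) {
    if (Mod(c1) > 0) -c0 / c1 else complex(0)
  } else {
    disc <- sqrt(c1^2 - 4 * c2 * c0)
    c((-c1 + disc) / (2 * c2), (-c1 - disc) / (2 * c2))
  }
  coma <- if (Mod(map@coma[2]) > 0) -map@coma[1] / map@coma[2] else complex(0)
  list(astig = astig, coma = coma)
}

#' Simulate a bead through-focus stack
#'
#' Synthetic free-dipole z-stack for calibration tests: a bead at the given
#' position imaged at the given stage positions with known aberrations and
#' Poisson noise.
#'
#' @param config an [OpticalConfig-class].
#' @param zernike true coefficients (mlambda) on `modes`.
#' @param zPositions stage z per slice (nm).
#' @param N photons per slice; `b` background per pixel.
#' @param x,y bead position offset (nm).
#' @param seed integer seed (`NULL` for noiseless expected images).
#' @param modes Noll indices.
#' @return list of photon images.
#' @export
simulateBeadStack <- function(config, zernike, zPositions, N = 1e5, b = 20,
                              x = 0, y = 0, seed = 1, modes = 5:16) {
  basis <- buildPupil(config, zernike, modes)
  if (!is.null(seed)) set.seed(seed)
  lapply(zPositions, function(zs) {
    th <- emitterParams(x = x, y = y, z = 0, N = N, b = b, g2 = 0)
    mu <- imageModel(th, basis, zStage = zs)
    if (is.null(seed)) mu else
      matrix(stats::rpois(length(mu), as.vector(mu)), nrow(mu), ncol(mu))
  })
}
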