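# Maximum likelihood fitting of single-emitter ROIs with the vectorial
# PSF model, plus the standard acceptance filters: convergence within 30
# iterations at 1e-6 relative log-likelihood tolerance, a 3-pixel
# center-distance cut, and a normalized chi-squared window of [0.75, 3].

#' Normalized chi-squared goodness-of-fit statistic
#'
#' `chi2 = (1/K) sum_k (n_k - mu_k)^2 / mu_k` over the K ROI pixels.
#' For data drawn from the model this concentrates around 1.
#'
#' @param roi observed photon image.
#' @param mu expected photon image (all entries > 0).
#' @return normalized chi-squared value.
#' @export
chi2Statistic <- function(roi, mu) {
  if (any(mu <= 0)) stop("chi2Statistic requires strictly positive mu")
  mean((roi - mu)^2 / mu)
}

# cached in-ROI capture fraction of the free-dipole mixture for a basis
basisCapture <- function(basis) {
  mu <- modelWithDerivatives(emitterParams(N = 1, b = 0, g2 = 0),
                             basis, derivatives = FALSE)$mu
  sum(mu)
}

#' First-pass parameter estimate from an ROI
#'
#' Background from the median of the ROI border ring, lateral position from
#' the background-subtracted centroid, and the photon count from the
#' background-corrected ROI sum divided by the ROI capture fraction of the
#' free-dipole PSF. Orientation is left at the multi-start default
#' (phi = 90, theta = 90, g2 = 0.75); [fitMLE()] screens an orientation grid
#' from this starting point.
#'
#' @param roi photon image (row = y, col = x).
#' @param config an [OpticalConfig-class].
#' @param captureFraction optional precomputed ROI capture fraction.
#' @return an [emitterParams()] vector.
#' @export
initialEstimate <- function(roi, config, captureFraction = 0.46) {
  K <- nrow(roi)
  if (all(roi <= 0)) stop("degenerate input: all-zero ROI")
  border <- c(roi[1, ], roi[K, ], roi[-c(1, K), 1], roi[-c(1, K), K])
  b0 <- max(stats::median(border), 1e-2)
  w <- pmax(roi - b0, 0)
  ctr <- (K + 1) / 2
  px <- config@pixelSize
  if (sum(w) > 0) {
    xs <- (col(roi) - ctr) * px
    ys <- (row(roi) - ctr) * px
    x0 <- sum(w * xs) / sum(w)
    y0 <- sum(w * ys) / sum(w)
  } else x0 <- y0 <- 0
  N0 <- max((sum(roi) - b0 * K^2) / captureFraction, 10)
  emitterParams(x = x0, y = y0, z = 0, N = N0, b = b0,
                phi = 90, theta = 90, g2 = 0.75)
}

poissonLogLik <- function(n, mu) sum(n * log(mu) - mu)

# parameter transforms: positivity for N and b, logistic for g2
toEta <- function(theta) {
  g2 <- min(max(theta[["g2"]], 1e-4), 1 - 1e-4)
  c(theta[["x"]], theta[["y"]], theta[["z"]], log(theta[["N"]]),
    log(max(theta[["b"]], 1e-3)), theta[["phi"]], theta[["theta"]],
    log(g2 / (1 - g2)))
}
fromEta <- function(eta) {
  g2 <- 1 / (1 + exp(-eta[8]))
  c(x = eta[1], y = eta[2], z = eta[3], N = exp(eta[4]), b = exp(eta[5]),
    phi = eta[6], theta = eta[7], g2 = g2)
}
etaJacobian <- function(theta)
  c(1, 1, 1, theta[["N"]], theta[["b"]],
    1, 1, theta[["g2"]] * (1 - theta[["g2"]]))

#' Maximum likelihood fit of one ROI
#'
#' Maximizes the Poisson log-likelihood of the eight-parameter image model
#' by damped Fisher scoring with analytic derivatives, starting from a
#' screened orientation grid (6 azimuths x 3 polar angles, best initial
#' likelihoods refined to convergence; best final likelihood kept). N, b
#' are fitted on a log scale and g2 through a logistic transform to respect
#' their ranges. Iteration stops when the relative change of successive
#' log-likelihood values drops below `tol` or after `maxIter` iterations.
#'
#' Fits are flagged as rejected when non-converged (`max_iter`), when the
#' fitted position is more than `maxCenterDistPx` pixels from the ROI
#' center (`center_distance`), or when the normalized chi-squared lies
#' outside `chi2Bounds` (`chi2_range`).
#'
#' @param roi observed photon image (row = y, col = x).
#' @param basis a [PupilBasis-class] for the ROI's field position.
#' @param init optional [emitterParams()] starting point; default
#'   [initialEstimate()].
#' @param maxIter iteration cap (default 30).
#' @param tol relative log-likelihood stopping tolerance (default 1e-6).
#' @param chi2Bounds acceptance window for the normalized chi-squared.
#' @param maxCenterDistPx center-distance rejection radius in pixels.
#' @param nRefine number of screened orientation starts refined fully.
#' @return list with `theta` (canonicalized estimates), `crlb`, `chi2`,
#'   `logLik`, `nIterations`, `converged` and `rejectedReason`
#'   (`"none"` if all filters pass).
#' @export
fitMLE <- function(roi, basis, init = NULL, maxIter = 30L, tol = 1e-6,
                   chi2Bounds = c(0.75, 3), maxCenterDistPx = 3,
                   nRefine = 2L) {
  cfg <- basis@config
  if (any(roi < 0)) stop("ROI must be non-negative (photon units)")
  if (is.null(init))
    init <- initialEstimate(roi, cfg, basisCapture(basis))
  n <- as.vector(roi)

  starts <- orientationStarts(roi, basis, init, nRefine)
  best <- NULL
  for (s in starts) {
    fit <- fisherScoring(n, basis, s, maxIter, tol)
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }
  theta <- best$theta
  ang <- canonicalAngles(theta[["phi"]], theta[["theta"]])
  theta[["phi"]] <- ang[["phi"]]; theta[["theta"]] <- ang[["theta"]]

  m <- modelWithDerivatives(theta, basis)
  mu <- as.vector(m$mu)
  cr <- crlbFromFisher(crossprod(m$D, m$D / mu))
  chi2 <- mean((n - mu)^2 / mu)

  reason <- "none"
  if (!best$converged) reason <- "max_iter"
  else if (max(abs(theta[c("x", "y")])) > maxCenterDistPx * cfg@pixelSize)
    reason <- "center_distance"
  else if (chi2 < chi2Bounds[1] || chi2 > chi2Bounds[2]) reason <- "chi2_range"

  list(theta = theta, crlb = cr, chi2 = chi2, logLik = best$logLik,
       nIterations = best$nIterations, converged = best$converged,
       rejectedReason = reason)
}

# screen a 6 x 3 orientation grid (plus the init orientation) by initial
# likelihood, reusing one field evaluation; returns the nRefine best starts.
orientationStarts <- function(roi, basis, init, nRefine) {
  cfg <- basis@config
  n <- as.vector(roi)
  fs <- fieldSet(basis, init[["x"]], init[["y"]], init[["z"]])
  c0 <- parsevalC0(basis)
  Sfree <- sum(vapply(fs$Q, function(m) sum(abs(m)^2), numeric(1)))
  rawFree <- intensitySum(fs$E)
  gm <- fixedGram(basis, init[["z"]])
  grid <- expand.grid(phi = seq(15, 165, by = 30),
                      theta = c(45, 90, 135))
  cand <- rbind(grid, c(init[["phi"]], init[["theta"]]))
  ll <- numeric(nrow(cand))
  g2 <- init[["g2"]]
  for (i in seq_len(nrow(cand))) {
    d <- dipoleVector(cand$phi[i], cand$theta[i])
    F <- combineDipole(fs$E, d)
    Sfix <- drop(d %*% gm$M %*% d)
    B <- (1 - g2) * rawFree / (c0 * Sfree) +
      g2 * (abs(F$x)^2 + abs(F$y)^2) / (c0 * Sfix)
    mu <- init[["N"]] *
      t(binPixels(B, cfg@roiSize, cfg@oversampling, cfg@pixelSize)) +
      init[["b"]]
    ll[i] <- poissonLogLik(n, as.vector(mu))
  }
  ord <- order(ll, decreasing = TRUE)[seq_len(min(nRefine, nrow(cand)))]
  lapply(ord, function(i) {
    s <- init
    s[["phi"]] <- cand$phi[i]; s[["theta"]] <- cand$theta[i]
    s
  })
}

fisherScoring <- function(n, basis, theta, maxIter, tol) {
  eta <- toEta(theta)
  theta <- fromEta(eta)
  m <- modelWithDerivatives(theta, basis)
  mu <- pmax(as.vector(m$mu), 1e-12)
  ll <- poissonLogLik(n, mu)
  lambda <- 1e-3
  iter <- 0L
  converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    J <- etaJacobian(theta)
    De <- sweep(m$D, 2, J, `*`)
    score <- crossprod(De, n / mu - 1)
    I <- crossprod(De, De / mu)
    accepted <- FALSE
    for (try in 1:8) {
      H <- I + lambda * diag(pmax(diag(I), 1e-8))
      delta <- tryCatch(solve(H, score), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      etaNew <- eta + as.vector(delta)
      etaNew[8] <- min(max(etaNew[8], -12), 12)   # keep logit finite
      thetaNew <- fromEta(etaNew)
      mNew <- modelWithDerivatives(thetaNew, basis)
      muNew <- pmax(as.vector(mNew$mu), 1e-12)
      llNew <- poissonLogLik(n, muNew)
      if (is.finite(llNew) && llNew >= ll - 1e-9) {
        accepted <- TRUE
        lambda <- max(lambda / 5, 1e-8)
        dll <- abs(llNew - ll) / max(abs(ll), 1e-8)
        eta <- etaNew; theta <- thetaNew; m <- mNew; mu <- muNew; ll <- llNew
        if (dll < tol) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!accepted) { converged <- TRUE; break }  # stalled at a maximum
    if (converged) break
  }
  list(theta = theta, logLik = ll, nIterations = iter, converged = converged)
}
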