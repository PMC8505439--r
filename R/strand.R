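# Orientation analyses along DNA strands: wobble-cone conversion, strand
# axis splines, relative azimuth, orientation-subset periodicity.

#' Convert rotational constraint g2 to a wobble-cone half-angle
#'
#' Uniform wobble-in-cone model: a dipole diffusing uniformly in a cone of
#' semi-angle alpha has second-order orientation parameter
#' `g2 = cos(alpha) (1 + cos(alpha)) / 2`. The inverse is the closed form
#' `cos(alpha) = (sqrt(1 + 8 g2) - 1) / 2`.
#'
#' @param g2 rotational constraint in \[0, 1\].
#' @return cone half-angle alpha in degrees.
#' @examples
#' g2ToConeAngle(1)    # 0: fully fixed
#' g2ToConeAngle(0.4)  # ~58 degrees
#' @export
g2ToConeAngle <- function(g2) {
  if (any(g2 < 0 | g2 > 1)) stop("g2 must lie in [0, 1]")
  acos((sqrt(1 + 8 * g2) - 1) / 2) * 180 / pi
}

#' @rdname g2ToConeAngle
#' @param alpha cone half-angle in degrees, in \[0, 90\].
#' @export
coneAngleToG2 <- function(alpha) {
  if (any(alpha < 0 | alpha > 90)) stop("alpha must lie in [0, 90] degrees")
  ca <- cos(alpha * pi / 180)
  ca * (1 + ca) / 2
}

#' Strand axis: smoothing-spline curve through localizations
#'
#' Holds a densely sampled smoothing-spline curve through the
#' localizations of one strand, with arc length and local tangent angles
#' (computed by central finite differences along the curve).
#'
#' @slot curve n x 2 matrix of (x, y) curve samples (nm).
#' @slot arc arc length at each sample (nm).
#' @slot tangent local tangent angle (deg) at each sample.
#' @slot rotation rotation angle (deg) of the internal parameterization
#'   axis.
#' @export
setClass("StrandAxis", representation(
  curve = "matrix", arc = "numeric", tangent = "numeric",
  rotation = "numeric"))

setMethod("show", "StrandAxis", function(object) {
  cat(sprintf("StrandAxis: %d samples, length %.0f nm, mean tangent %.1f deg\n",
              nrow(object@curve), max(object@arc),
              mean(object@tangent) %% 180))
})

#' Fit a strand axis to localizations
#'
#' Rotates the localizations onto their principal axis, fits a smoothing
#' spline of the transverse against the longitudinal coordinate (smoothing
#' parameter 0.1 on the conventional 0 = least-squares line to
#' 1 = interpolation scale), and samples the curve densely. Tangents are
#' computed by central finite differences on the sampled curve.
#'
#' @param locs data.frame or matrix with `x`, `y` columns (nm).
#' @param smoothing smoothing parameter p in (0, 1\]; the spline penalty is
#'   `(1 - p)/p` per unit curvature on the normalized abscissa.
#' @param nSamples number of curve samples.
#' @return A [StrandAxis-class] object.
#' @export
fitStrandAxis <- function(locs, smoothing = 0.1, nSamples = 512L) {
  locs <- as.matrix(as.data.frame(locs)[, c("x", "y")])
  if (nrow(locs) < 10) stop("need at least 10 localizations to fit an axis")
  ctr <- colMeans(locs)
  Xc <- sweep(locs, 2, ctr)
  pc <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)$vectors
  rotAngle <- atan2(pc[2, 1], pc[1, 1])
  R <- matrix(c(cos(rotAngle), -sin(rotAngle),
                sin(rotAngle), cos(rotAngle)), 2, 2)
  P <- Xc %*% R  # column 1: longitudinal s, column 2: transverse t
  s <- P[, 1]; tv <- P[, 2]
  # p interpolates between the least-squares line (p -> 0) and an
  # interpolating spline (p -> 1); the curvature penalty (1-p)/p is applied
  # per observation on the unit-normalized abscissa
  lambda <- (1 - smoothing) / smoothing / length(s)
  fit <- stats::smooth.spline(s, tv, lambda = lambda, keep.data = FALSE)
  sg <- seq(min(s), max(s), length.out = nSamples)
  tg <- stats::predict(fit, sg)$y
  curve <- cbind(sg, tg) %*% t(R)
  curve <- sweep(curve, 2, ctr, `+`)
  dxy <- apply(curve, 2, function(v) {
    n <- length(v)
    c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1])
  })
  tangent <- (atan2(dxy[, 2], dxy[, 1]) * 180 / pi) %% 180
  seg <- sqrt(rowSums(dxy^2))
  arc <- cumsum(seg) - seg[1]
  new("StrandAxis", curve = curve, arc = arc, tangent = tangent,
      rotation = rotAngle * 180 / pi)
}

#' Azimuth relative to the local strand axis
#'
#' For each localization, finds the nearest point on the strand curve
#' (ties broken by smaller arc length), and returns the azimuthal angle
#' relative to the local tangent, wrapped into \[0, 180), together with the
#' signed perpendicular distance to the axis and the arc-length position.
#'
#' @param records data.frame with `x`, `y` (nm) and an azimuth column
#'   (`phi_deg` or `phi`).
#' @param axis a [StrandAxis-class].
#' @return data.frame with `deltaPhi` (deg), `distance` (signed nm, positive
#'   to the left of the tangent), and `arc` (nm).
#' @export
relativeAzimuth <- function(records, axis) {
  records <- as.data.frame(records)
  phi <- if ("phi_deg" %in% names(records)) records$phi_deg else records$phi
  cx <- axis@curve[, 1]; cy <- axis@curve[, 2]
  out <- vapply(seq_len(nrow(records)), function(i) {
    d2 <- (cx - records$x[i])^2 + (cy - records$y[i])^2
    j <- which(d2 == min(d2))[1]          # arc-length tie-break: first
    tg <- axis@tangent[j] * pi / 180
    dx <- records$x[i] - cx[j]; dy <- records$y[i] - cy[j]
    dist <- -sin(tg) * dx + cos(tg) * dy  # signed perpendicular offset
    dphi <- (phi[i] - axis@tangent[j]) %% 180
    c(dphi, dist, axis@arc[j])
  }, numeric(3))
  data.frame(deltaPhi = out[1, ], distance = out[2, ], arc = out[3, ])
}

#' Peak of the g2 distribution and its cone angle
#'
#' Kernel-density mode of the g2 values with the corresponding
#' wobble-in-cone half-angle.
#'
#' @param g2 numeric vector of g2 estimates (>= 100 values).
#' @return list with `g2Peak` and `alpha` (deg).
#' @export
g2HistogramPeak <- function(g2) {
  g2 <- g2[is.finite(g2)]
  if (length(g2) < 100) stop("need at least 100 g2 records")
  d <- stats::density(g2, from = 0, to = 1, n = 512)
  pk <- d$x[which.max(d$y)]
  list(g2Peak = pk, alpha = g2ToConeAngle(min(max(pk, 0), 1)))
}

localMaxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Periodicity of localizations along a strand by binned autocorrelation
#'
#' Bins the arc-length positions of an orientation subset of localizations
#' (default bin width 6.5 nm), computes the mean-subtracted normalized
#' autocorrelation of the bin counts, and searches for a comb of at least
#' three equidistant peaks with prominence above twice the noise MAD of
#' the autocorrelation. Reports the detected period (peak spacing) or `NA`
#' when no reliable comb exists (including when the data span fewer than
#' three periods).
#'
#' @param records data.frame with `x`, `y` and orientation columns
#'   (`deltaPhi` or `phi_deg`/`phi`, `theta_deg`/`theta`).
#' @param axis a [StrandAxis-class] used for arc-length projection
#'   (ignored when `records` already has an `arc` column).
#' @param subset optional list with `phiRange` and/or `thetaRange`
#'   (degrees; `phiRange` applies to `deltaPhi`, wrap-aware on \[0, 180)).
#' @param binWidth bin width along the strand (nm, default 6.5).
#' @param minPeaks minimum number of equidistant peaks (default 3).
#' @param prominence peak threshold in units of the autocorrelation noise
#'   MAD (default 2).
#' @return list with `lag` (nm), `acf`, `peaks` (lag positions), `period`
#'   (nm or NA), `reliable` (logical).
#' @export
periodicityAutocorrelation <- function(records, axis = NULL, subset = NULL,
                                       binWidth = 6.5, minPeaks = 3L,
                                       prominence = 2) {
  records <- as.data.frame(records)
  if (!"arc" %in% names(records)) {
    if (is.null(axis)) stop("need either an `arc` column or a strand axis")
    ra <- relativeAzimuth(records, axis)
    records$arc <- ra$arc
    if (!"deltaPhi" %in% names(records)) records$deltaPhi <- ra$deltaPhi
  }
  if (!is.null(subset)) {
    if (!is.null(subset$phiRange)) {
      lo <- subset$phiRange[1] %% 180; hi <- subset$phiRange[2] %% 180
      dp <- records$deltaPhi %% 180
      keep <- if (lo <= hi) dp >= lo & dp <= hi else dp >= lo | dp <= hi
      records <- records[keep, , drop = FALSE]
    }
    if (!is.null(subset$thetaRange)) {
      th <- if ("theta_deg" %in% names(records)) records$theta_deg else
        records$theta
      records <- records[th >= subset$thetaRange[1] &
                           th <= subset$thetaRange[2], , drop = FALSE]
    }
  }
  if (nrow(records) < 10)
    return(list(lag = numeric(0), acf = numeric(0), peaks = numeric(0),
                period = NA_real_, reliable = FALSE))
  arc <- records$arc
  brks <- seq(min(arc), max(arc) + binWidth, by = binWidth)
  counts <- as.vector(table(cut(arc, brks, include.lowest = TRUE,
                                right = FALSE)))
  x <- counts - mean(counts)
  nb <- length(x)
  maxLag <- floor(nb / 2)
  denom <- sum(x^2)
  ac <- vapply(0:maxLag, function(k)
    sum(x[seq_len(nb - k)] * x[seq_len(nb - k) + k]) / denom, numeric(1))
  lag <- (0:maxLag) * binWidth

  # noise level: spread of the autocorrelation around its smooth trend
  sm <- if (length(ac) >= 9) stats::runmed(ac, 9) else ac
  noise <- max(stats::mad(ac - sm), 1e-6)
  idx <- localMaxima(ac)
  idx <- idx[idx > 2 & ac[idx] > 0]
  # peak prominence over the deepest adjacent valley
  prom <- vapply(idx, function(i) {
    lo <- max(c(1, idx[idx < i] + 0))
    left <- min(ac[lo:i]); right <- min(ac[i:min(length(ac), i + 15)])
    ac[i] - max(left, right)
  }, numeric(1))
  idx <- idx[prom > prominence * noise]
  peaks <- lag[idx]
  period <- NA_real_; reliable <- FALSE
  if (length(peaks) >= minPeaks) {
    base <- stats::median(diff(peaks))
    if (is.finite(base) && base > 2 * binWidth) {
      k <- round(peaks / base)
      if (length(unique(k)) >= minPeaks && all(k >= 1)) {
        fit <- stats::lm.fit(cbind(k), peaks)
        per <- fit$coefficients[[1]]
        resid <- peaks - k * per
        if (max(abs(resid)) <= max(1.5 * binWidth, 0.1 * per)) {
          period <- per
          reliable <- (max(arc) - min(arc)) >= minPeaks * period
        }
      }
    }
  }
  list(lag = lag, acf = ac, peaks = peaks, period = period,
       reliable = reliable)
}

#' Per-strand analysis report
#'
#' Convenience summary of one strand: relative-azimuth median and MAD, g2
#' distribution peak and cone angle, line-width FWHM of the perpendicular
#' residuals (polar-filtered to 35-145 degrees), and the detected
#' localization periodicity.
#'
#' @param records localization data.frame (accepted rows) with `x`, `y`,
#'   `phi_deg`, `theta_deg`, `g2`.
#' @param axis optional precomputed [StrandAxis-class].
#' @param thetaFilter polar band used for the line-width statistic (deg).
#' @return one-row data.frame.
#' @export
strandReport <- function(records, axis = NULL,
                         thetaFilter = c(35, 145)) {
  records <- as.data.frame(records)
  if (is.null(axis)) axis <- fitStrandAxis(records)
  ra <- relativeAzimuth(records, axis)
  th <- if ("theta_deg" %in% names(records)) records$theta_deg else
    records$theta
  inBand <- th >= thetaFilter[1] & th <= thetaFilter[2]
  fwhm <- if (sum(inBand) >= 10) {
    d <- stats::density(ra$distance[inBand])
    half <- max(d$y) / 2
    above <- range(d$x[d$y >= half])
    diff(above)
  } else NA_real_
  g2pk <- tryCatch(g2HistogramPeak(records$g2),
                   error = function(e) list(g2Peak = NA, alpha = NA))
  per <- periodicityAutocorrelation(cbind(records, arc = ra$arc,
                                          deltaPhi = ra$deltaPhi))
  data.frame(nLoc = nrow(records),
             deltaPhiMedian = stats::median(ra$deltaPhi),
             deltaPhiMad = stats::mad(ra$deltaPhi),
             g2Peak = g2pk$g2Peak, alpha = g2pk$alpha,
             fwhm_nm = fwhm, period_nm = per$period)
}
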