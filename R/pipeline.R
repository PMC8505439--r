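# Frame-level processing: photon conversion, candidate detection, ROI
# fitting orchestration, frame-to-frame linking, and fine drift correction.

#' Convert camera ADU to photons
#'
#' `(ADU - offset) / gain`, clamped at zero (negative excursions from
#' readout noise around empty pixels are truncated).
#'
#' @param adu ADU image or stack (matrix or array).
#' @param gain camera gain (ADU/photon), > 0.
#' @param offset camera offset (ADU).
#' @return photon image of the same shape.
#' @examples
#' photonConvert(matrix(120, 2, 2), gain = 2, offset = 100)
#' @export
photonConvert <- function(adu, gain, offset) {
  if (gain <= 0) stop("camera gain must be positive")
  pmax((adu - offset) / gain, 0)
}

#' Detect candidate emitters in a photon frame
#'
#' Thresholds the frame at `background + thresholdOffset` photons, groups
#' the super-threshold pixels into connected components (discarding
#' components below `minPixels`), and returns one candidate per component
#' at the local intensity centroid.
#'
#' @param frame photon image (row = y, col = x).
#' @param background background estimate (photons/pixel); default: frame
#'   median.
#' @param thresholdOffset photons above background (default 10).
#' @param minPixels minimum number of super-threshold pixels per candidate
#'   (default 4, suppressing isolated shot-noise pixels that the merging
#'   dilation would otherwise group).
#' @return data.frame with `row`, `col` centroid pixel coordinates and
#'   `npix` component sizes; zero rows on a blank frame.
#' @export
detectCandidates <- function(frame, background = NULL, thresholdOffset = 10,
                             minPixels = 4L) {
  if (is.null(background)) background <- stats::median(frame)
  mask <- frame > background + thresholdOffset
  if (!any(mask)) return(data.frame(row = numeric(), col = numeric(),
                                    npix = integer()))
  # dilate before labeling so the lobes of one donut-shaped spot (separated
  # by its dark ring) merge into a single candidate
  grown <- EBImage::dilate(mask * 1, EBImage::makeBrush(7, "disc"))
  lab <- EBImage::bwlabel(grown)
  lab[!mask] <- 0   # centroid and size from the original pixels
  ids <- setdiff(unique(as.vector(lab)), 0)
  out <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < minPixels) return(NULL)
    w <- frame[idx] - background
    w <- pmax(w, 1e-9)
    data.frame(row = sum(idx[, 1] * w) / sum(w),
               col = sum(idx[, 2] * w) / sum(w), npix = nrow(idx))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(row = numeric(), col = numeric(),
                               npix = integer()) else out
}

emptyLocTable <- function() {
  cols <- c("frame", "x_nm", "y_nm", "z_nm", "photons", "background",
            "phi_deg", "theta_deg", "g2",
            paste0("crlb_", c("x", "y", "z", "photons", "background",
                              "phi", "theta", "g2")),
            "chi2", "n_iterations", "field_x_px", "field_y_px",
            "rejected_reason")
  df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                      cols))
  df$rejected_reason <- character(0)
  df
}

#' Fit all emitters in a frame stack
#'
#' Full localization pipeline over a stack of photon frames: candidate
#' detection, ROI extraction, per-ROI aberration lookup (when an
#' [AberrationMap-class] is supplied), maximum likelihood fitting and the
#' acceptance filters. Rejected fits are kept in the table with their
#' rejection reason.
#'
#' @param frames list of photon images (row = y, col = x).
#' @param config an [OpticalConfig-class].
#' @param aberrationMap optional [AberrationMap-class]; field positions are
#'   measured in pixels from the frame center.
#' @param thresholdOffset detection threshold above background (photons).
#' @param ... further arguments passed to [fitMLE()].
#' @return localization data.frame (one row per fitted ROI) with position
#'   estimates in nm relative to the frame center, photon counts,
#'   orientation estimates, per-parameter CRLBs, the chi-squared statistic
#'   and the rejection reason (`"none"` for accepted fits).
#' @export
processStack <- function(frames, config, aberrationMap = NULL,
                         thresholdOffset = 10, ...) {
  if (length(frames) == 0) return(emptyLocTable())
  roi <- config@roiSize
  half <- (roi - 1) / 2
  px <- config@pixelSize
  basisCache <- list()
  zeroBasis <- buildPupil(config)
  capture <- basisCapture(zeroBasis)
  rows <- list()
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    cand <- detectCandidates(fr, thresholdOffset = thresholdOffset)
    if (!nrow(cand)) next
    ctr <- c((nrow(fr) + 1) / 2, (ncol(fr) + 1) / 2)
    for (i in seq_len(nrow(cand))) {
      r0 <- round(cand$row[i]); c0 <- round(cand$col[i])
      if (nrow(fr) < roi || ncol(fr) < roi) next
      # clamp the cut so near-edge candidates keep a full ROI
      r0 <- min(max(r0, half + 1), nrow(fr) - half)
      c0 <- min(max(c0, half + 1), ncol(fr) - half)
      roiImg <- fr[(r0 - half):(r0 + half), (c0 - half):(c0 + half)]
      fieldPx <- c(c0 - ctr[2], r0 - ctr[1])
      if (!is.null(aberrationMap)) {
        zern <- suppressWarnings(evaluateMap(aberrationMap, fieldPx))
        key <- paste(round(zern, 1), collapse = ",")
        if (is.null(basisCache[[key]])) {
          basisCache[[key]] <- buildPupil(config, zern, aberrationMap@modes)
          if (length(basisCache) > 64) basisCache <- basisCache[-1]
        }
        basis <- basisCache[[key]]
      } else basis <- zeroBasis
      init <- initialEstimate(roiImg, config, capture)
      fit <- fitMLE(roiImg, basis, init, ...)
      th <- fit$theta
      rows[[length(rows) + 1]] <- data.frame(
        frame = f,
        x_nm = th[["x"]] + (c0 - ctr[2]) * px,
        y_nm = th[["y"]] + (r0 - ctr[1]) * px,
        z_nm = th[["z"]], photons = th[["N"]], background = th[["b"]],
        phi_deg = th[["phi"]], theta_deg = th[["theta"]], g2 = th[["g2"]],
        crlb_x = fit$crlb[["x"]], crlb_y = fit$crlb[["y"]],
        crlb_z = fit$crlb[["z"]], crlb_photons = fit$crlb[["N"]],
        crlb_background = fit$crlb[["b"]], crlb_phi = fit$crlb[["phi"]],
        crlb_theta = fit$crlb[["theta"]], crlb_g2 = fit$crlb[["g2"]],
        chi2 = fit$chi2, n_iterations = fit$nIterations,
        field_x_px = fieldPx[1], field_y_px = fieldPx[2],
        rejected_reason = fit$rejectedReason,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(emptyLocTable())
  do.call(rbind, rows)
}

wrapAngleDiff <- function(a, b, period = 180) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

#' Link localizations of the same emitter across frames
#'
#' Greedy frame-to-frame linking of accepted localizations: two
#' localizations in consecutive frames are linked when every position and
#' orientation difference (x, y, z, phi, theta; azimuth compared on the
#' hemisphere) is below `factor` times the larger of the two uncertainties.
#' Linked records are merged by inverse-variance weighting.
#'
#' @param table localization data.frame from [processStack()].
#' @param factor the uncertainty multiple (default 3).
#' @return list with `tracks` (list of row-index vectors) and `merged`
#'   (data.frame of per-track inverse-variance-weighted estimates, total
#'   photons, and track length).
#' @export
linkLocalizations <- function(table, factor = 3) {
  acc <- which(table$rejected_reason == "none")
  tab <- table[acc, , drop = FALSE]
  ord <- order(tab$frame)
  tab <- tab[ord, , drop = FALSE]
  orig <- acc[ord]
  n <- nrow(tab)
  trackOf <- integer(n)
  tracks <- list()
  pars <- list(c("x_nm", "crlb_x"), c("y_nm", "crlb_y"), c("z_nm", "crlb_z"),
               c("phi_deg", "crlb_phi"), c("theta_deg", "crlb_theta"))
  linkable <- function(i, j) {
    for (p in pars) {
      d <- if (p[1] == "phi_deg")
        wrapAngleDiff(tab[i, p[1]], tab[j, p[1]]) else
          abs(tab[i, p[1]] - tab[j, p[1]])
      lim <- factor * max(tab[i, p[2]], tab[j, p[2]])
      if (!is.finite(lim) || d >= lim) {
        if (!is.finite(lim)) next  # unconstrained parameter: skip criterion
        return(FALSE)
      }
    }
    TRUE
  }
  for (i in seq_len(n)) {
    prev <- which(tab$frame == tab$frame[i] - 1 & trackOf[seq_len(n)] > 0 &
                    seq_len(n) < i)
    linked <- FALSE
    if (length(prev)) {
      dists <- sqrt((tab$x_nm[prev] - tab$x_nm[i])^2 +
                      (tab$y_nm[prev] - tab$y_nm[i])^2)
      for (j in prev[order(dists)]) {
        tr <- trackOf[j]
        last <- tracks[[tr]][length(tracks[[tr]])]
        if (tab$frame[last] != tab$frame[i] - 1) next
        if (linkable(last, i)) {
          tracks[[tr]] <- c(tracks[[tr]], i)
          trackOf[i] <- tr
          linked <- TRUE
          break
        }
      }
    }
    if (!linked) {
      tracks[[length(tracks) + 1]] <- i
      trackOf[i] <- length(tracks)
    }
  }
  merged <- do.call(rbind, lapply(tracks, function(idx) {
    wmean <- function(v, s) {
      w <- 1 / pmax(s, 1e-9)^2
      sum(v * w) / sum(w)
    }
    data.frame(
      nLinked = length(idx),
      frameFirst = tab$frame[idx[1]],
      x_nm = wmean(tab$x_nm[idx], tab$crlb_x[idx]),
      y_nm = wmean(tab$y_nm[idx], tab$crlb_y[idx]),
      z_nm = wmean(tab$z_nm[idx], tab$crlb_z[idx]),
      phi_deg = wmean(tab$phi_deg[idx], tab$crlb_phi[idx]),
      theta_deg = wmean(tab$theta_deg[idx], tab$crlb_theta[idx]),
      g2 = mean(tab$g2[idx]),
      photons = sum(tab$photons[idx]),
      crlb_x = 1 / sqrt(sum(1 / pmax(tab$crlb_x[idx], 1e-9)^2)),
      crlb_y = 1 / sqrt(sum(1 / pmax(tab$crlb_y[idx], 1e-9)^2)))
  }))
  list(tracks = lapply(tracks, function(idx) orig[idx]), merged = merged)
}

#' Fine drift correction from strand residuals
#'
#' Estimates a common lateral drift trajectory from the perpendicular
#' residuals of localizations around their strand axes: per frame bin, the
#' per-strand mean residuals are projected onto x/y through the strand
#' normals and combined by weighted least squares (weights from
#' localization precision and count). Needs strands of at least two
#' distinct orientations to constrain both axes.
#'
#' @param residuals data.frame with columns `frame`, `residual` (signed
#'   perpendicular distance to the strand axis, nm), `normalAngle` (deg,
#'   direction of the strand normal), `strand` (id), and optionally
#'   `weight`.
#' @param frameBin number of frames pooled per drift sample.
#' @return data.frame `frame`, `dx`, `dy` (nm): the estimated drift
#'   trajectory (to be subtracted from localizations).
#' @export
fineDrift <- function(residuals, frameBin = 1L) {
  angles <- tapply(residuals$normalAngle, residuals$strand,
                   function(a) stats::median(a %% 180))
  if (length(angles) >= 2) {
    spread <- max(wrapAngleDiff(max(angles), min(angles)),
                  diff(range(angles %% 180)))
    if (spread < 10)
      warning("all strands nearly parallel: drift is unconstrained along ",
              "their common axis")
  } else warning("fewer than 2 strands: drift only constrained along one axis")
  residuals$bin <- (residuals$frame - 1) %/% frameBin
  bins <- sort(unique(residuals$bin))
  out <- do.call(rbind, lapply(bins, function(bn) {
    rb <- residuals[residuals$bin == bn, ]
    w <- if ("weight" %in% names(rb)) rb$weight else rep(1, nrow(rb))
    nx <- cos(rb$normalAngle * pi / 180)
    ny <- sin(rb$normalAngle * pi / 180)
    A <- cbind(nx, ny)
    fit <- tryCatch(stats::lm.wfit(A, rb$residual, w), error = function(e) NULL)
    d <- if (is.null(fit) || any(is.na(fit$coefficients))) c(0, 0) else
      fit$coefficients
    data.frame(bin = bn, dx = d[1], dy = d[2])
  }))
  frames <- sort(unique(residuals$frame))
  data.frame(frame = frames,
             dx = out$dx[match((frames - 1) %/% frameBin, out$bin)],
             dy = out$dy[match((frames - 1) %/% frameBin, out$bin)])
}
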