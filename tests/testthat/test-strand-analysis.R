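# Wobble-cone conversion, strand splines, relative azimuth, periodicity.

test_that("wobble-cone anchors and round trip", {
  expect_equal(g2ToConeAngle(1), 0)
  expect_equal(round(g2ToConeAngle(0.4)), 58)
  expect_equal(round(g2ToConeAngle(0.86), 1), 25.4, tolerance = 0.11)
  g2 <- seq(0, 1, length.out = 101)
  expect_equal(coneAngleToG2(g2ToConeAngle(g2)), g2, tolerance = 1e-10)
  expect_error(g2ToConeAngle(1.2), "g2")
  expect_error(coneAngleToG2(120), "alpha")
})

test_that("strand axis fits lines and arcs and is rotation-equivariant", {
  set.seed(1)
  # exact line along x
  line <- data.frame(x = seq(0, 4000, length.out = 200), y = 0)
  ax <- fitStrandAxis(line)
  expect_lt(max(abs(ax@curve[, 2])), 1e-6)
  expect_true(all(pmin(ax@tangent %% 180, 180 - ax@tangent %% 180) < 0.01))
  # shallow circular arc with 5 nm noise
  R <- 20000
  s <- seq(-2000, 2000, length.out = 300)
  arc <- data.frame(x = R * sin(s / R), y = R * (1 - cos(s / R)))
  arcN <- arc + matrix(rnorm(600, 0, 5), ncol = 2)
  axA <- fitStrandAxis(arcN)
  dev <- abs(sqrt(axA@curve[, 1]^2 + (axA@curve[, 2] - R)^2) - R)
  n <- length(dev)
  # spline end segments are unpenalized; judge the interior of the strand
  expect_lt(max(dev[round(n * 0.1):round(n * 0.9)]), 3)
  # rotating the input rotates the tangents
  ang <- 30 * pi / 180
  Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  rot <- as.data.frame(as.matrix(arcN) %*% t(Rm))
  names(rot) <- c("x", "y")
  axR <- fitStrandAxis(rot)
  mid <- round(nrow(axA@curve) / 2)
  d <- (axR@tangent[mid] - axA@tangent[mid]) %% 180
  expect_lt(min(d, 180 - d - 30, abs(d - 30)), 0.5)
  expect_error(fitStrandAxis(line[1:5, ]), "at least 10")
})

test_that("relative azimuth is measured against the local tangent", {
  line <- data.frame(x = seq(0, 4000, length.out = 100), y = 0)
  ax <- fitStrandAxis(line)
  rec <- data.frame(x = c(1000, 2000), y = c(30, -40), phi = c(90, 30))
  ra <- relativeAzimuth(rec, ax)
  expect_equal(ra$deltaPhi, c(90, 30), tolerance = 0.1)
  expect_equal(ra$distance, c(30, -40), tolerance = 1)
  expect_equal(ra$arc, c(1000, 2000), tolerance = 25)
})

test_that("generator statistics (deltaPhi median/MAD) are recovered", {
  lay <- strandLayout(nLoc = 600, length = 8000, angle = 25, deltaPhi = 82,
                      phiMad = 17, seed = 6)
  ax <- fitStrandAxis(lay)
  ra <- relativeAzimuth(lay, ax)
  expect_equal(median(ra$deltaPhi), 82, tolerance = 2 / 82 * 1.2)
  expect_equal(mad(ra$deltaPhi, constant = 1), 17, tolerance = 3 / 17)
  # global rotation+translation invariance of the statistics
  ang <- 40 * pi / 180
  lay2 <- lay
  lay2$x <- cos(ang) * lay$x - sin(ang) * lay$y + 5000
  lay2$y <- sin(ang) * lay$x + cos(ang) * lay$y - 2000
  lay2$phi <- (lay$phi + 40) %% 180
  ra2 <- relativeAzimuth(lay2, fitStrandAxis(lay2))
  expect_equal(median(ra2$deltaPhi), median(ra$deltaPhi), tolerance = 1.5)
  expect_equal(mad(ra2$deltaPhi), mad(ra$deltaPhi), tolerance = 1.5)
})

test_that("g2 histogram peak finds the mode", {
  expect_equal(g2HistogramPeak(rep(0.8, 200))$g2Peak, 0.8, tolerance = 0.02)
  set.seed(10)
  g2s <- pmin(pmax(rnorm(5000, 0.8, 0.06), 0), 1)
  pk <- g2HistogramPeak(g2s)
  expect_equal(pk$g2Peak, 0.8, tolerance = 0.02)
  # the 0.86 mode of surface-immobilized emitters maps to 25.3-25.4 deg
  expect_equal(g2ToConeAngle(0.86), 25.4, tolerance = 0.1)
  expect_error(g2HistogramPeak(rep(0.5, 10)), "100")
})

test_that("binned autocorrelation detects a 150 nm orientation period", {
  lay <- strandLayout(nLoc = 900, length = 3000, deltaPhi = 118,
                      phiMad = 8, thetaRange = c(20, 45), period = 150,
                      width = 6, seed = 14)
  ax <- fitStrandAxis(lay)
  pa <- periodicityAutocorrelation(lay, ax, binWidth = 6.5)
  expect_true(pa$reliable)
  expect_equal(pa$period, 150, tolerance = 7 / 150)
  # autocorrelation normalization
  expect_equal(pa$acf[1], 1)
  # doubling the bin width coarsens lags but keeps the period
  pa2 <- periodicityAutocorrelation(lay, ax, binWidth = 13)
  expect_equal(pa2$period, 150, tolerance = 14 / 150)
})

test_that("uniform strands rarely produce a spurious period", {
  fp <- 0
  for (s in 1:25) {
    lay <- strandLayout(nLoc = 500, length = 3000, period = NA,
                        seed = 100 + s)
    ax <- fitStrandAxis(lay)
    pa <- periodicityAutocorrelation(lay, ax)
    if (pa$reliable) fp <- fp + 1
  }
  expect_lte(fp / 25, 0.08)
})

test_that("orientation subsets filter wrap-aware", {
  lay <- strandLayout(nLoc = 400, seed = 3)
  ax <- fitStrandAxis(lay)
  ra <- relativeAzimuth(lay, ax)
  rec <- cbind(lay, arc = ra$arc, deltaPhi = ra$deltaPhi)
  pa <- periodicityAutocorrelation(rec,
                                   subset = list(phiRange = c(170, 10)))
  # the wrap interval keeps only deltaPhi near 0/180
  dp <- rec$deltaPhi %% 180
  nKept <- sum(dp >= 170 | dp <= 10)
  expect_true(is.na(pa$period) || nKept >= 10)
})

test_that("strand report aggregates the per-strand statistics", {
  lay <- strandLayout(nLoc = 500, deltaPhi = 82, phiMad = 17,
                      g2Mean = 0.8, seed = 4)
  lay$phi_deg <- lay$phi; lay$theta_deg <- lay$theta
  rep <- strandReport(lay)
  expect_equal(rep$deltaPhiMedian, 82, tolerance = 4)
  expect_equal(rep$g2Peak, 0.8, tolerance = 0.04)
  expect_true(rep$fwhm_nm > 10 && rep$fwhm_nm < 60)
})
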