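# CRLB computation, initial estimates, chi-squared statistic and MLE
# fitting with the acceptance filters.

test_that("position CRLB scales as 1/sqrt(N) in the shot-noise limit", {
  pb <- cachedBasis()
  th1 <- emitterParams(N = 2000, b = 1e-4, theta = 70, g2 = 0.75)
  th4 <- emitterParams(N = 8000, b = 1e-4, theta = 70, g2 = 0.75)
  c1 <- crlb(th1, pb); c4 <- crlb(th4, pb)
  expect_equal(c1[["x"]] / c4[["x"]], 2, tolerance = 0.02)
  expect_equal(c1[["y"]] / c4[["y"]], 2, tolerance = 0.02)
})

test_that("azimuth CRLB diverges toward the optical axis", {
  pb <- cachedBasis()
  cr <- sapply(c(20, 15, 10, 5), function(t)
    crlb(emitterParams(N = 4000, b = 10, theta = t, g2 = 1), pb)[["phi"]])
  expect_true(all(diff(cr) > 0))
  # exactly on the axis the azimuth is unidentifiable
  cAx <- crlb(emitterParams(N = 4000, b = 10, theta = 0, g2 = 1), pb)
  expect_true(is.infinite(cAx[["phi"]]))
  # a fully free dipole carries no orientation information at all
  cFree <- crlb(emitterParams(N = 4000, b = 10, g2 = 0), pb)
  expect_true(is.infinite(cFree[["phi"]]) && is.infinite(cFree[["theta"]]))
  expect_true(is.finite(cFree[["x"]]))
})

test_that("initial estimate recovers position, background and photons", {
  pb <- cachedBasis()
  cfg <- pb@config
  th <- emitterParams(x = 0, y = 0, N = 5000, b = 10, theta = 90)
  mu <- imageModel(th, pb)
  init <- initialEstimate(mu, cfg, basisCapture <- sum(imageModel(
    emitterParams(N = 1, b = 0, g2 = 0), pb)))
  expect_lt(abs(init[["x"]]), 0.2 * cfg@pixelSize)
  expect_lt(abs(init[["y"]]), 0.2 * cfg@pixelSize)
  # border median carries a share of the PSF tails on top of b
  expect_equal(init[["b"]], 10, tolerance = 0.3)
  expect_equal(init[["N"]], 5000, tolerance = 0.25)
  # uniform ROI: photon estimate collapses to (almost) nothing
  flat <- matrix(10, 15, 15)
  initFlat <- initialEstimate(flat, cfg, 0.46)
  expect_lt(initFlat[["N"]], 50)
  expect_error(initialEstimate(matrix(0, 15, 15), cfg), "degenerate")
})

test_that("normalized chi-squared behaves as a goodness-of-fit statistic", {
  pb <- cachedBasis()
  mu <- imageModel(emitterParams(), pb)
  expect_equal(chi2Statistic(mu, mu), 0)
  expect_error(chi2Statistic(mu, mu - max(mu)), "positive")
  set.seed(7)
  chis <- replicate(100, {
    n <- matrix(rpois(length(mu), as.vector(mu)), nrow(mu))
    chi2Statistic(n, mu)
  })
  expect_equal(mean(chis), 1, tolerance = 0.05)
})

test_that("MLE recovers the truth from a noiseless image", {
  pb <- cachedBasis()
  th <- emitterParams(x = 15, y = -22, z = 30, N = 4000, b = 10,
                      phi = 70, theta = 60, g2 = 0.8)
  mu <- imageModel(th, pb)
  cr <- crlb(th, pb)
  init <- th
  for (p in c("x", "y", "z", "phi", "theta"))
    init[[p]] <- th[[p]] + 0.5 * cr[[p]]
  init[["g2"]] <- 0.7
  fit <- fitMLE(mu, pb, init = init)
  expect_true(fit$converged)
  expect_lt(abs(fit$theta[["x"]] - 15), 0.1)
  expect_lt(abs(fit$theta[["y"]] + 22), 0.1)
  expect_lt(abs(fit$theta[["phi"]] - 70), 0.1)
  expect_lt(abs(fit$theta[["theta"]] - 60), 0.1)
  expect_lt(abs(fit$theta[["g2"]] - 0.8), 0.005)
  expect_lt(fit$chi2, 1e-4)
  # chi2 = 0 lies below the acceptance window, so the filter flags it
  expect_equal(fit$rejectedReason, "chi2_range")
})

test_that("multi-start fitting finds the global orientation optimum", {
  pb <- cachedBasis()
  set.seed(21)
  for (thTrue in list(c(10, 35), c(160, 120), c(90, 150))) {
    th <- emitterParams(N = 6000, b = 8, phi = thTrue[1], theta = thTrue[2],
                        g2 = 0.9)
    roi <- simulateRoi(th, pb, seed = 100 + thTrue[1])
    fit <- fitMLE(roi, pb)
    reps <- rbind(c(fit$theta[["phi"]], fit$theta[["theta"]]),
                  c(fit$theta[["phi"]] + 180, 180 - fit$theta[["theta"]]),
                  c(fit$theta[["phi"]] - 180, 180 - fit$theta[["theta"]]))
    dphi <- min(abs(reps[, 1] - thTrue[1]))
    expect_lt(dphi, 15)
  }
})

test_that("inconsistent data is rejected by the chi-squared filter", {
  pb <- cachedBasis()
  set.seed(5)
  noise <- matrix(runif(225, 0, 40), 15, 15)
  fit <- fitMLE(noise, pb)
  expect_false(fit$rejectedReason == "none")
})

test_that("estimator is near-efficient on a small Poisson ensemble", {
  bm <- benchmarkPrecision(smallCfg(), n = 60, useMLE = TRUE, seed = 13)
  expect_gte(bm$convergedFraction, 0.95)
  # per-parameter standardized errors (error / instance CRLB) have spread
  # near 1 for an efficient estimator; allow generous slack at n = 60
  expect_true(all(bm$sdStandardized < 1.5))
  expect_true(all(abs(bm$bias / bm$crlbMean) < 0.5))
})

test_that("canonical hemisphere mapping respects dipole symmetry", {
  expect_equal(unname(canonicalAngles(200, 60)), c(20, 120))
  expect_equal(unname(canonicalAngles(-10, 60)), c(170, 120))
  expect_equal(unname(canonicalAngles(90, 200)), c(270 %% 180, 180 - 160))
  a <- canonicalAngles(135.2, 44.8)
  expect_equal(unname(a), c(135.2, 44.8))
})
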