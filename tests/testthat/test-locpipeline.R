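# Frame-level pipeline: photon conversion, detection, stack processing,
# linking, fine drift.

test_that("photon conversion is affine with clamping", {
  expect_equal(photonConvert(matrix(120, 2, 2), gain = 2, offset = 100),
               matrix(10, 2, 2))
  expect_equal(photonConvert(matrix(100, 2, 2), gain = 2, offset = 100),
               matrix(0, 2, 2))
  expect_equal(photonConvert(matrix(90, 1, 1), 2, 100), matrix(0, 1, 1))
  expect_error(photonConvert(matrix(1), gain = 0, offset = 0), "gain")
})

test_that("candidate detection finds isolated emitters and not noise", {
  pb <- cachedBasis()
  set.seed(31)
  # blank frames: background only
  hits <- sapply(1:10, function(i) {
    fr <- matrix(rpois(64 * 64, 10), 64, 64)
    nrow(detectCandidates(fr))
  })
  expect_lt(mean(hits), 0.5)
  # one bright vortex emitter
  found <- 0; errs <- c()
  for (i in 1:20) {
    mv <- makeMovie(data.frame(x = 130, y = -65, z = 0, N = 4000, phi = 90,
                               theta = 80, g2 = 0.75, frameOn = 1,
                               frameOff = 1),
                    nFrames = 1, frameSize = 64L, config = smallCfg(),
                    b = 10, seed = 40 + i)
    cand <- detectCandidates(mv$frames[[1]])
    if (nrow(cand) == 1) {
      found <- found + 1
      # truth at x=130nm,y=-65nm from center -> col 35, row 31 (65nm px)
      errs <- c(errs, abs(cand$col - 35), abs(cand$row - 31))
    }
  }
  expect_gte(found, 19)
  expect_lt(max(errs), 1.6)
  # two well-separated emitters
  mv2 <- suppressWarnings(
    makeMovie(data.frame(x = c(-600, 600), y = 0, z = 0, N = 4000,
                         phi = 90, theta = 80, g2 = 0.75,
                         frameOn = 1, frameOff = 1),
              nFrames = 1, frameSize = 64L, config = smallCfg(),
              b = 10, seed = 77))
  expect_equal(nrow(detectCandidates(mv2$frames[[1]])), 2)
})

test_that("stack processing localizes a small synthetic movie", {
  layout <- data.frame(x = c(-900, 900), y = c(-470, 470), z = 0, N = 5000,
                       phi = c(40, 120), theta = c(70, 100), g2 = 0.8,
                       frameOn = 1, frameOff = 4)
  mv <- makeMovie(layout, nFrames = 4, frameSize = 64L, config = smallCfg(),
                  b = 10, seed = 55)
  tab <- processStack(mv$frames, smallCfg())
  acc <- tab[tab$rejected_reason == "none", ]
  expect_gte(nrow(acc), 7)  # recall >= 7/8
  # filter accounting: every fitted ROI is accepted or has a reason
  expect_true(all(tab$rejected_reason %in%
                    c("none", "max_iter", "center_distance", "chi2_range")))
  # localizations agree with the ground truth within a few precisions
  for (e in 1:2) {
    near <- acc[abs(acc$x_nm - layout$x[e]) < 200 &
                  abs(acc$y_nm - layout$y[e]) < 200, ]
    expect_gte(nrow(near), 3)
    expect_lt(abs(median(near$x_nm) - layout$x[e]), 15)
    expect_lt(abs(median(near$y_nm) - layout$y[e]), 15)
    expect_lt(min(abs(c(median(near$phi_deg) - layout$phi[e],
                        median(near$phi_deg) - layout$phi[e] + 180,
                        median(near$phi_deg) - layout$phi[e] - 180))), 10)
  }
  # empty movie
  expect_equal(nrow(processStack(list(), smallCfg())), 0)
})

fakeLoc <- function(frame, x = 0, y = 0, z = 0, phi = 90, theta = 90,
                    sx = 5, sphi = 3) {
  data.frame(frame = frame, x_nm = x, y_nm = y, z_nm = z, photons = 4000,
             background = 10, phi_deg = phi, theta_deg = theta, g2 = 0.8,
             crlb_x = sx, crlb_y = sx, crlb_z = 25, crlb_photons = 150,
             crlb_background = 0.4, crlb_phi = sphi, crlb_theta = 3,
             crlb_g2 = 0.07, chi2 = 1, n_iterations = 5, field_x_px = 0,
             field_y_px = 0, rejected_reason = "none",
             stringsAsFactors = FALSE)
}

test_that("linking obeys the 3x-uncertainty rule and merges by precision", {
  # identical localization in consecutive frames links into one track
  tab <- rbind(fakeLoc(1), fakeLoc(2))
  lk <- linkLocalizations(tab)
  expect_equal(length(lk$tracks), 1)
  expect_equal(lk$merged$nLinked, 2)
  # position difference of 4x the uncertainty: not linked
  tab2 <- rbind(fakeLoc(1), fakeLoc(2, x = 4 * 5))
  expect_equal(length(linkLocalizations(tab2)$tracks), 2)
  # orientation difference alone also breaks a link (wrap-aware)
  tab3 <- rbind(fakeLoc(1, phi = 2), fakeLoc(2, phi = 178))
  expect_equal(length(linkLocalizations(tab3)$tracks), 1)  # 4 deg on ring
  tab4 <- rbind(fakeLoc(1, phi = 2), fakeLoc(2, phi = 40))
  expect_equal(length(linkLocalizations(tab4)$tracks), 2)
  # five-frame chain with small jitter merges with ~sqrt(5) precision gain
  set.seed(3)
  chain <- do.call(rbind, lapply(1:5, function(f)
    fakeLoc(f, x = rnorm(1, 0, 2))))
  lk5 <- linkLocalizations(chain)
  expect_equal(length(lk5$tracks), 1)
  expect_equal(lk5$merged$crlb_x, 5 / sqrt(5), tolerance = 1e-6)
  wm <- sum(chain$x_nm / 25) / sum(1 / rep(25, 5))
  expect_equal(lk5$merged$x_nm, wm, tolerance = 1e-9)
})

test_that("fine drift recovers an injected common trajectory", {
  # two perpendicular strands observed over 60 frames
  set.seed(12)
  frames <- 1:60
  drift <- data.frame(frame = frames,
                      dx = 10 * sin(2 * pi * frames / 60),
                      dy = 6 * cos(2 * pi * frames / 60))
  mkres <- function(strand, normalDeg) {
    do.call(rbind, lapply(frames, function(f) {
      n <- 5
      res <- cos(normalDeg * pi / 180) * drift$dx[f] +
        sin(normalDeg * pi / 180) * drift$dy[f] + rnorm(n, 0, 3)
      data.frame(frame = f, residual = res, normalAngle = normalDeg,
                 strand = strand, weight = 1)
    }))
  }
  res <- rbind(mkres("a", 0), mkres("b", 90))
  tr <- fineDrift(res)
  expect_lt(sqrt(mean((tr$dx - drift$dx)^2)), 1.5)
  expect_lt(sqrt(mean((tr$dy - drift$dy)^2)), 1.5)
  # corrected residual spread shrinks by the injected-drift share
  raw <- res$residual
  corr <- res$residual - ifelse(res$normalAngle == 0,
                                tr$dx[match(res$frame, tr$frame)],
                                tr$dy[match(res$frame, tr$frame)])
  expect_lt(sd(corr), 0.6 * sd(raw))
  # zero residuals give a zero trajectory
  res0 <- res; res0$residual <- 0
  tr0 <- fineDrift(res0)
  expect_true(all(abs(c(tr0$dx, tr0$dy)) < 1e-9))
  # parallel strands cannot constrain both axes
  expect_warning(fineDrift(mkres("a", 0)), "strand")
})
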