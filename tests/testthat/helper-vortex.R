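# Shared fixtures: small pupil grids keep the suite fast; the acceptance
# tests use the full default configuration where the printed values demand
# it.

smallCfg <- function(charge = 1L, ...)
  opticalConfig(pupilSamples = 32L, vortexCharge = charge, ...)

# bases are cached per option set for the whole test session
.basisCache <- new.env()
cachedBasis <- function(charge = 1L, zernike = rep(0, 12), ...) {
  key <- paste(charge, paste(zernike, collapse = ","),
               paste(unlist(list(...)), collapse = ","), sep = "|")
  if (is.null(.basisCache[[key]]))
    .basisCache[[key]] <- buildPupil(smallCfg(charge, ...), zernike)
  .basisCache[[key]]
}

expect_rel <- function(value, target, tol) {
  expect_true(abs(value / target - 1) <= tol,
              label = sprintf("%.4g vs target %.4g (rel tol %.2g)",
                              value, target, tol))
}
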