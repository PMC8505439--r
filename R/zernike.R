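# Orthonormal Zernike polynomials, Noll indexing. Coefficients elsewhere in
# the package are in mlambda (1e-3 wavelength RMS), so a single mode with
# coefficient A contributes an RMS wavefront of A/1000 wavelengths.

#' Noll index to radial/azimuthal orders
#'
#' @param j Noll index (j >= 1).
#' @return integer vector `c(n, m)`; negative m denotes the sine term.
#' @examples
#' nollIndex(5)  # oblique astigmatism: n = 2, m = -2
#' @export
nollIndex <- function(j) {
  stopifnot(j >= 1)
  n <- 0L
  while (j > (n + 1L) * (n + 2L) / 2L) n <- n + 1L
  k <- j - n * (n + 1L) / 2L           # 1-based position within the row
  mAbs <- if (n %% 2L == 0L) 2L * (k %/% 2L) else 2L * ((k - 1L) %/% 2L) + 1L
  m <- if (mAbs == 0L) 0L else if (j %% 2L == 0L) mAbs else -mAbs
  c(n = n, m = as.integer(m))
}

zernikeRadial <- function(n, mAbs, rho) {
  out <- 0
  for (k in 0:((n - mAbs) / 2)) {
    out <- out + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + mAbs) / 2 - k) *
         factorial((n - mAbs) / 2 - k)) * rho^(n - 2 * k)
  }
  out
}

#' Evaluate an orthonormal Zernike mode
#'
#' Orthonormal (RMS = 1 over the unit disk) Zernike polynomial with Noll
#' indexing: even j carries the cosine term, odd j the sine term.
#'
#' @param j Noll index.
#' @param rho normalized pupil radius (<= 1 for orthonormality).
#' @param beta pupil azimuth (radians).
#' @return numeric array shaped like `rho`.
#' @export
zernikeNoll <- function(j, rho, beta) {
  nm <- nollIndex(j)
  n <- nm[1]; m <- nm[2]; mAbs <- abs(m)
  norm <- if (mAbs == 0L) sqrt(n + 1) else sqrt(2 * (n + 1))
  ang <- if (m == 0L) 1 else if (m > 0L) cos(mAbs * beta) else sin(mAbs * beta)
  norm * zernikeRadial(n, mAbs, rho) * ang
}
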