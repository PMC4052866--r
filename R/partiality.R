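# Geometric partiality model: signed radial distances to the limiting Ewald
# spheres, clamping to the reflection-sphere radius, spherical-cap volume
# fractions, Lorentz factor and analytic gradients with respect to the nine
# reciprocal basis components.
#
# Sign convention: a distance is the signed radial offset e = R - |s - c| of
# the reciprocal lattice point from a limiting sphere (centre c, radius R),
# measured along the radius from the Ewald-sphere centre. It is negative when
# the sphere surface lies closer to the Ewald centre than the point. rLow is
# the larger (max) and rHigh the smaller (min) of the nest extremes, so
# rLow >= rHigh always.

#' Signed excitation distances to the limiting Ewald spheres
#'
#' Evaluates the four extreme Ewald spheres of the nest (two top-hat
#' wavelength limits crossed with two in-plane convergence tilts, the tilt
#' taken in the plane containing the beam axis and s) and returns the extreme
#' signed radial distances, unclamped.
#'
#' @param s scattering vector, length-3 numeric (nm^-1), or an n x 3 matrix.
#' @param beam a \linkS4class{BeamModel}.
#' @return data.frame with columns \code{rHigh}, \code{rLow} (nm^-1,
#'   \code{rLow >= rHigh}).
#' @export
excitationDistances <- function(s, beam) {
  if (!is.matrix(s)) s <- matrix(s, 1, 3)
  if (any(rowSums(s^2) == 0)) stop("zero-length scattering vector")
  # reuse the basis-times-hkl machinery: put s in the a* column, hkl = (1,0,0)
  e100 <- matrix(c(1L, 0L, 0L), 1, 3)
  out <- vapply(seq_len(nrow(s)), function(i) {
    b <- cbind(s[i, ], c(0, 0, 0), c(0, 0, 0))
    ex <- cpp_excitation(b, e100, beam@wavelength / 10, beam@bandwidth,
                         beam@convergence, r = 1, kL = 1, gradients = FALSE)
    c(ex$rhigh, ex$rlow)
  }, numeric(2))
  data.frame(rHigh = out[1, ], rLow = out[2, ])
}

#' Clamp excitation distances to the reflection-sphere radius
#'
#' Each distance is replaced by min(max(value, -r), +r); flags record whether
#' clamping occurred. Clamped bounds contribute zero gradient downstream.
#'
#' @param g data.frame with columns \code{rHigh}, \code{rLow} (as returned by
#'   \code{\link{excitationDistances}}).
#' @param r reflection-sphere radius, nm^-1 (> 0).
#' @return the data.frame with clamped values plus logical columns
#'   \code{clampedHigh}, \code{clampedLow}.
#' @export
clampDistances <- function(g, r) {
  stopifnot(r > 0)
  ch <- pmin(pmax(g$rHigh, -r), r)
  cl <- pmin(pmax(g$rLow, -r), r)
  data.frame(rHigh = ch, rLow = cl,
             clampedHigh = ch != g$rHigh, clampedLow = cl != g$rLow)
}

#' Spherical-cap volume fraction
#'
#' Fraction of the volume of a sphere of radius \code{r} whose signed radial
#' coordinate is at least \code{t}: f(t) = (r - t)^2 (2r + t) / (4 r^3).
#' f(-r) = 1, f(0) = 1/2, f(r) = 0, monotone decreasing.
#'
#' @param t signed plane offset(s), must lie in [-r, r].
#' @param r sphere radius (> 0).
#' @return volume fraction(s) in [0, 1].
#' @export
capFraction <- function(t, r) {
  stopifnot(r > 0)
  if (any(t < -r - 1e-12 * r) || any(t > r + 1e-12 * r))
    stop("offset t outside [-r, r]")
  t <- pmin(pmax(t, -r), r)
  (r - t)^2 * (2 * r + t) / (4 * r^3)
}

#' Partiality from clamped excitation distances
#'
#' The volume fraction of the reflection sphere lying in the slab between the
#' two limiting planes: p = f(rHigh) - f(rLow) with f the cap fraction.
#'
#' @param rHigh,rLow clamped signed distances (rLow >= rHigh), nm^-1.
#' @param r reflection-sphere radius, nm^-1.
#' @return partiality in [0, 1].
#' @export
partialityFromDistances <- function(rHigh, rLow, r) {
  ch <- pmin(pmax(rHigh, -r), r)
  cl <- pmin(pmax(rLow, -r), r)
  pmin(pmax(capFraction(ch, r) - capFraction(cl, r), 0), 1)
}

#' Lorentz factor from unclamped distances
#'
#' L = kL / (rLow - rHigh), proportional to the inverse radial separation of
#' the limiting Ewald spheres. Computed from unclamped distances so that L is
#' independent of the partiality.
#'
#' @param rHigh,rLow unclamped signed distances, nm^-1.
#' @param kL normalization constant, nm^-1 (see
#'   \code{\link{lorentzNormalization}}).
#' @return Lorentz factor(s); \code{NA} where rLow == rHigh.
#' @export
lorentzFactor <- function(rHigh, rLow, kL) {
  T <- rLow - rHigh
  out <- ifelse(T > 0, kL / T, NA_real_)
  out
}

#' Lorentz normalization constant
#'
#' Any multiplicative constant in L is admissible (it is absorbed by the
#' overall scale factors); the package fixes k_L to the nest thickness
#' (rLow - rHigh) at a point on the nominal Ewald sphere at the detector-edge
#' resolution, so that L = 1 there.
#'
#' @param beam a \linkS4class{BeamModel}.
#' @param detector a \linkS4class{DetectorModel}.
#' @return k_L in nm^-1.
#' @export
lorentzNormalization <- function(beam, detector) {
  dEdge <- detectorResolutionLimits(detector, beam@wavelength)[["edge"]]
  lamNM <- beam@wavelength / 10
  sinTheta <- beam@wavelength / (2 * dEdge)
  twoTheta <- 2 * asin(sinTheta)
  # point on the nominal sphere at scattering angle 2theta, in the x-z plane
  s <- c(sin(twoTheta), 0, cos(twoTheta) - 1) / lamNM
  g <- excitationDistances(matrix(s, 1, 3), beam)
  g$rLow - g$rHigh
}

#' Partiality, Lorentz factor and geometry for reflections of a pattern
#'
#' One-stop evaluation of the model for a set of Miller indices under a given
#' reciprocal basis: unclamped excitation distances, clamped partiality and
#' Lorentz factor, and optionally the analytic gradient of p with respect to
#' the nine basis components.
#'
#' @param hkl n x 3 integer matrix (or length-3 vector).
#' @param basis 3x3 reciprocal basis, columns a*, b*, c*, nm^-1.
#' @param beam a \linkS4class{BeamModel}.
#' @param r reflection-sphere radius, nm^-1.
#' @param kL Lorentz normalization, nm^-1.
#' @param gradients return the n x 9 gradient matrix dp/dv? Columns are
#'   ordered (a*x, a*y, a*z, b*x, b*y, b*z, c*x, c*y, c*z).
#' @return data.frame with columns \code{rHigh}, \code{rLow} (unclamped),
#'   \code{p}, \code{L}; if \code{gradients}, the matrix is attached as
#'   attribute \code{"gradient"}.
#' @export
reflectionPartiality <- function(hkl, basis, beam, r, kL = 1,
                                 gradients = FALSE) {
  if (!is.matrix(hkl)) hkl <- matrix(as.integer(hkl), 1, 3)
  storage.mode(hkl) <- "integer"
  ex <- cpp_excitation(basis, hkl, beam@wavelength / 10, beam@bandwidth,
                       beam@convergence, r, kL, gradients)
  out <- data.frame(rHigh = ex$rhigh, rLow = ex$rlow, p = ex$p, L = ex$L)
  if (gradients) attr(out, "gradient") <- ex$grad
  out
}

#' Analytic gradient of partiality in the basis components
#'
#' Chain rule through the clamped cap fractions: a clamped bound contributes
#' exactly zero; the Miller index h multiplies the a*-component terms, k the
#' b*-components and l the c*-components. The Lorentz gradient is taken as
#' zero.
#'
#' @inheritParams reflectionPartiality
#' @return n x 9 matrix of dp/dv.
#' @export
partialityGradient <- function(hkl, basis, beam, r) {
  attr(reflectionPartiality(hkl, basis, beam, r, kL = 1, gradients = TRUE),
       "gradient")
}
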