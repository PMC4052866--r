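# Core geometry: unit cells, wavelengths, orientations, scattering vectors,
# detector resolution limits. Reciprocal space is in nm^-1, wavelengths and
# d-spacings in Angstrom at the user surface (1 nm^-1 <-> d = 10 A).

HC_KEV_A <- 12.39842  # hc, keV * Angstrom

#' Convert photon energy to wavelength
#'
#' @param energyKeV photon energy in keV (> 0).
#' @return wavelength in Angstrom, lambda = hc / E with hc = 12.39842 keV A.
#' @examples
#' energyToWavelength(8)   # 1.5498 A
#' @export
energyToWavelength <- function(energyKeV) {
  if (any(!is.finite(energyKeV)) || any(energyKeV <= 0))
    stop("photon energy must be positive")
  HC_KEV_A / energyKeV
}

#' Convert wavelength to photon energy
#' @param wavelengthA wavelength in Angstrom (> 0).
#' @return photon energy in keV.
#' @export
wavelengthToEnergy <- function(wavelengthA) {
  if (any(!is.finite(wavelengthA)) || any(wavelengthA <= 0))
    stop("wavelength must be positive")
  HC_KEV_A / wavelengthA
}

#' Construct a unit cell
#'
#' The cell is specified by its rhombohedral (primitive) parameters; the
#' hexagonal-setting equivalents a_hex = 2 a sin(alpha/2) and
#' c_hex = a sqrt(3 (1 + 2 cos alpha)) are derived on construction.
#'
#' @param a rhombohedral edge length, Angstrom.
#' @param alpha rhombohedral angle, degrees (0 < alpha < 120).
#' @param setting indexing basis used by \code{\link{reciprocalBasis}}.
#' @return a \linkS4class{UnitCell}.
#' @export
unitCell <- function(a, alpha, setting = c("rhombohedral", "hexagonal")) {
  setting <- match.arg(setting)
  ar <- alpha * pi / 180
  aHex <- 2 * a * sin(ar / 2)
  arg <- 3 * (1 + 2 * cos(ar))
  if (arg <= 0) stop("degenerate cell: alpha must be < 120 degrees")
  cHex <- a * sqrt(arg)
  new("UnitCell", aRh = a, alphaRh = alpha, aHex = aHex, cHex = cHex,
      setting = setting)
}

#' Construct a unit cell from hexagonal-setting parameters
#' @param aHex,cHex hexagonal cell edges, Angstrom.
#' @param setting indexing basis used by \code{\link{reciprocalBasis}}.
#' @return a \linkS4class{UnitCell}.
#' @export
unitCellHexagonal <- function(aHex, cHex,
                              setting = c("hexagonal", "rhombohedral")) {
  setting <- match.arg(setting)
  a <- sqrt(3 * aHex^2 + cHex^2) / 3
  alpha <- 2 * asin(1.5 * aHex / sqrt(3 * aHex^2 + cHex^2)) * 180 / pi
  unitCell(a, alpha, setting = setting)
}

#' Beam model constructor
#' @param photonEnergyKeV photon energy, keV.
#' @param bandwidth full fractional width of the top-hat spectrum.
#' @param convergence full convergence angle, radians.
#' @return a \linkS4class{BeamModel}.
#' @export
beamModel <- function(photonEnergyKeV = 8, bandwidth = 5e-4,
                      convergence = 1e-3) {
  new("BeamModel", photonEnergy = photonEnergyKeV,
      wavelength = energyToWavelength(photonEnergyKeV),
      bandwidth = bandwidth, convergence = convergence)
}

#' Detector model constructor
#' @param sideMM square edge length, mm.
#' @param distanceMM sample-to-detector distance, mm.
#' @return a \linkS4class{DetectorModel}.
#' @export
detectorModel <- function(sideMM = 76.8, distanceMM = 50) {
  new("DetectorModel", side = sideMM, distance = distanceMM)
}

# direct-space basis matrix (columns a, b, c in nm) for the indexing setting
directBasis <- function(cell) {
  if (cell@setting == "rhombohedral") {
    a <- b <- c <- cell@aRh / 10
    al <- be <- ga <- cell@alphaRh * pi / 180
  } else {
    a <- b <- cell@aHex / 10
    c <- cell@cHex / 10
    al <- be <- pi / 2
    ga <- 2 * pi / 3
  }
  ca <- cos(al); cb <- cos(be); cg <- cos(ga); sg <- sin(ga)
  cx <- cb
  cy <- (ca - cb * cg) / sg
  cz2 <- 1 - cx^2 - cy^2
  if (cz2 <= 0) stop("degenerate cell")
  cbind(c(a, 0, 0),
        c(b * cg, b * sg, 0),
        c(c * cx, c * cy, c * sqrt(cz2)))
}

#' Reference reciprocal basis of a cell, optionally rotated
#'
#' Builds the 3x3 reciprocal basis matrix (columns a*, b*, c*, Cartesian
#' components in nm^-1) of the cell's indexing setting and applies an
#' orientation: basis = R B0.
#'
#' @param cell a \linkS4class{UnitCell}.
#' @param orientation a proper 3x3 rotation matrix (default identity).
#' @return 3x3 numeric matrix, columns a*, b*, c* in nm^-1.
#' @export
reciprocalBasis <- function(cell, orientation = diag(3)) {
  stopifnot(all(dim(orientation) == c(3, 3)))
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-8 ||
      det(orientation) < 0)
    stop("orientation must be a proper rotation matrix")
  D <- directBasis(cell)
  B0 <- solve(t(D))   # columns a*,b*,c*: a_i . b*_j = delta_ij
  orientation %*% B0
}

#' Cell volume
#' @param cell a \linkS4class{UnitCell}.
#' @return volume of the indexing setting's cell in Angstrom^3.
#' @export
cellVolume <- function(cell) {
  abs(det(directBasis(cell))) * 1000
}

#' Draw random orientations uniform over the rotation group
#'
#' Haar-uniform rotations via normalized quaternions (four iid standard
#' normals). Uses R's RNG stream, so results are reproducible under
#' \code{set.seed}.
#'
#' @param n number of rotations.
#' @return a 3x3 rotation matrix, or a list of them if \code{n > 1}.
#' @export
randomOrientation <- function(n = 1) {
  one <- function() {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
             2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
             2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
           3, 3)
  }
  if (n == 1) one() else replicate(n, one(), simplify = FALSE)
}

#' Scattering vector and resolution of reflections
#'
#' @param hkl integer vector of length 3, or an n x 3 matrix.
#' @param basis 3x3 reciprocal basis (columns a*, b*, c*, nm^-1).
#' @return for a single hkl, the 3-vector s = h a* + k b* + l c* (nm^-1);
#'   for a matrix, an n x 3 matrix of scattering vectors.
#' @export
scatteringVector <- function(hkl, basis) {
  if (is.matrix(hkl)) t(basis %*% t(hkl)) else as.numeric(basis %*% hkl)
}

#' Resolution d = 1/|s| of reflections
#' @inheritParams scatteringVector
#' @return d-spacing in Angstrom; \code{NA} for (0,0,0).
#' @export
resolutionOf <- function(hkl, basis) {
  s <- scatteringVector(hkl, basis)
  sn <- if (is.matrix(s)) sqrt(rowSums(s^2)) else sqrt(sum(s^2))
  d <- 10 / sn
  d[!is.finite(d)] <- NA_real_
  d
}

#' Detector resolution limits
#'
#' For a spot at radius rho on the detector, 2\eqn{\theta} = atan(rho /
#' distance) and d = lambda / (2 sin \eqn{\theta}). The edge limit uses
#' rho = side/2, the corner limit rho = side/2 * sqrt(2).
#'
#' @param detector a \linkS4class{DetectorModel}.
#' @param wavelengthA wavelength in Angstrom.
#' @return named numeric: \code{edge} and \code{corner} d-limits, Angstrom.
#' @export
detectorResolutionLimits <- function(detector, wavelengthA) {
  stopifnot(wavelengthA > 0)
  lim <- function(rho) {
    theta <- atan(rho / detector@distance) / 2
    wavelengthA / (2 * sin(theta))
  }
  c(edge = lim(detector@side / 2),
    corner = lim(detector@side / 2 * sqrt(2)))
}
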