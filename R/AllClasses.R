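#' @import methods
NULL

#' Unit cell (rhombohedral primitive / hexagonal setting)
#'
#' Holds a rhombohedral cell (edge \code{aRh} in Angstrom, angle \code{alphaRh}
#' in degrees) together with the equivalent hexagonal-setting parameters,
#' derived on construction. \code{setting} selects which basis
#' \code{\link{reciprocalBasis}} builds: \code{"rhombohedral"} indexes on the
#' primitive cell (every hkl is a real reflection), \code{"hexagonal"} on the
#' triple hexagonal cell.
#'
#' @slot aRh rhombohedral edge length, Angstrom.
#' @slot alphaRh rhombohedral angle, degrees (0 < alpha < 120).
#' @slot aHex,cHex derived hexagonal-setting parameters, Angstrom.
#' @slot setting \code{"rhombohedral"} or \code{"hexagonal"}.
#' @exportClass UnitCell
setClass("UnitCell",
  representation(aRh = "numeric", alphaRh = "numeric",
                 aHex = "numeric", cHex = "numeric", setting = "character"))

setValidity("UnitCell", function(object) {
  if (length(object@aRh) != 1 || object@aRh <= 0)
    return("aRh must be a single positive length")
  if (length(object@alphaRh) != 1 || object@alphaRh <= 0 ||
      object@alphaRh >= 120)
    return("alphaRh must lie in (0, 120) degrees")
  if (!object@setting %in% c("rhombohedral", "hexagonal"))
    return("setting must be 'rhombohedral' or 'hexagonal'")
  TRUE
})

#' X-ray beam model
#'
#' Nominal photon energy with a top-hat spectrum of full fractional width
#' \code{bandwidth} and a full convergence angle \code{convergence}. These
#' define the nest of Ewald spheres; the beam axis is +z by convention. The
#' wavelength is derived on construction via \code{\link{energyToWavelength}}.
#'
#' @slot photonEnergy keV.
#' @slot wavelength Angstrom (derived).
#' @slot bandwidth dimensionless full fractional width (>= 0).
#' @slot convergence radians, full angle (>= 0).
#' @exportClass BeamModel
setClass("BeamModel",
  representation(photonEnergy = "numeric", wavelength = "numeric",
                 bandwidth = "numeric", convergence = "numeric"))

setValidity("BeamModel", function(object) {
  if (object@wavelength <= 0) return("wavelength must be positive")
  if (object@bandwidth < 0) return("bandwidth must be >= 0")
  if (object@convergence < 0) return("convergence must be >= 0")
  TRUE
})

#' Square detector model
#'
#' @slot side detector edge length, mm.
#' @slot distance sample-to-detector distance along the beam, mm.
#' @exportClass DetectorModel
setClass("DetectorModel",
  representation(side = "numeric", distance = "numeric"))

setValidity("DetectorModel", function(object) {
  if (object@side <= 0) return("side must be positive")
  if (object@distance <= 0) return("distance must be positive")
  TRUE
})

#' Symmetry group for merging
#'
#' An explicit ordered list of 3x3 integer matrices acting on (h,k,l).
#' Validity requires the identity, closure under composition and determinant
#' +-1 for every operator; no general space-group machinery is used.
#'
#' @slot ops list of 3x3 integer matrices.
#' @slot label human-readable label (e.g. the Laue class used for merging).
#' @exportClass SymmetryGroup
setClass("SymmetryGroup",
  representation(ops = "list", label = "character"))

setValidity("SymmetryGroup", function(object) {
  ops <- object@ops
  if (length(ops) < 1) return("group must contain at least the identity")
  for (m in ops) {
    if (!is.matrix(m) || !all(dim(m) == c(3, 3)))
      return("every operator must be a 3x3 matrix")
    if (any(m != round(m))) return("operators must be integer matrices")
    if (abs(abs(det(m)) - 1) > 1e-9)
      return("every operator must have determinant +-1")
  }
  keys <- vapply(ops, function(m) paste(as.integer(m), collapse = ","), "")
  if (anyDuplicated(keys)) return("duplicate operators")
  id <- paste(as.integer(diag(3)), collapse = ",")
  if (!id %in% keys) return("group must contain the identity")
  for (a in ops) for (b in ops) {
    if (!paste(as.integer(a %*% b), collapse = ",") %in% keys)
      return("group is not closed under composition")
  }
  TRUE
})

#' One snapshot diffraction pattern
#'
#' Observations live in a data.frame with one row per partial measurement:
#' columns \code{h,k,l} (Miller indices on the working basis), \code{key}
#' (encoded canonical hkl), \code{refIdx} (row in the dataset's reference
#' table, NA if absent), \code{d} (resolution, Angstrom), \code{iobs} and
#' \code{sigma} (partial intensity and its error), \code{p}, \code{L}
#' (partiality and Lorentz factor under the current working basis) and
#' \code{pTrue}, \code{LTrue} (generating values, simulator only).
#'
#' @slot id integer pattern id.
#' @slot basis current working reciprocal basis, 3x3, columns a*,b*,c*, nm^-1.
#' @slot trueBasis generating basis (simulator truth; may be NA).
#' @slot trueScale generating overall scale factor (simulator truth).
#' @slot obs observation data.frame as described above.
#' @exportClass SnapshotPattern
setClass("SnapshotPattern",
  representation(id = "integer", basis = "matrix", trueBasis = "matrix",
                 trueScale = "numeric", obs = "data.frame"))

setValidity("SnapshotPattern", function(object) {
  if (!all(dim(object@basis) == c(3, 3))) return("basis must be 3x3")
  if (abs(det(object@basis)) < 1e-12) return("basis is singular")
  TRUE
})

#' A simulated or loaded snapshot dataset
#'
#' @slot patterns list of \linkS4class{SnapshotPattern}.
#' @slot reference data.frame (h, k, l, key, d, I) of full intensities per
#'   canonical hkl (the simulation ground truth / merging reference).
#' @slot cell \linkS4class{UnitCell}.
#' @slot beam \linkS4class{BeamModel}.
#' @slot detector \linkS4class{DetectorModel}.
#' @slot symmetry \linkS4class{SymmetryGroup} used for merging keys.
#' @slot sphereRadius reflection-sphere radius r, nm^-1.
#' @slot lorentzNorm Lorentz normalization constant k_L, nm^-1.
#' @slot truth list of simulator truth: trueScales, sigmaNoise, seed, config.
#' @exportClass SnapshotDataset
setClass("SnapshotDataset",
  representation(patterns = "list", reference = "data.frame",
                 cell = "UnitCell", beam = "BeamModel",
                 detector = "DetectorModel", symmetry = "SymmetryGroup",
                 sphereRadius = "numeric", lorentzNorm = "numeric",
                 truth = "list"))

setValidity("SnapshotDataset", function(object) {
  if (object@sphereRadius <= 0) return("sphereRadius must be positive")
  if (!all(vapply(object@patterns, is, TRUE, class2 = "SnapshotPattern")))
    return("patterns must all be SnapshotPattern objects")
  TRUE
})

#' Result of one outer scale-merge-refine run
#'
#' @slot mergedTables list (cycle 0 .. nCycles) of merged intensity
#'   data.frames (key, h, k, l, d, I, sigma, n).
#' @slot scales list of per-cycle named scale vectors G_j.
#' @slot refinement list (one per refinement cycle) of per-pattern summary
#'   data.frames: iterations, eliminated eigenvalues, max |delta p|,
#'   reverted/skipped flags, reflections used.
#' @slot rHistory overall R-factor against the reference after each cycle
#'   (index 1 = cycle 0).
#' @slot pairCorrelations Pearson correlation of observed vs calculated
#'   partiality after each cycle (index 1 = cycle 0).
#' @slot nCycles number of refinement cycles performed.
#' @slot dataset the refined \linkS4class{SnapshotDataset}.
#' @exportClass PostRefinementRun
setClass("PostRefinementRun",
  representation(mergedTables = "list", scales = "list", refinement = "list",
                 rHistory = "numeric", pairCorrelations = "numeric",
                 nCycles = "integer", dataset = "SnapshotDataset"))

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell: rhombohedral a = %.4g A, alpha = %.4g deg (%s setting)\n",
              object@aRh, object@alphaRh, object@setting))
  cat(sprintf("  hexagonal equivalents: a = %.4g A, c = %.4g A\n",
              object@aHex, object@cHex))
})

setMethod("show", "BeamModel", function(object) {
  cat(sprintf(
    "BeamModel: %.6g keV (lambda %.6g A), bandwidth %.3g, convergence %.3g rad\n",
    object@photonEnergy, object@wavelength, object@bandwidth,
    object@convergence))
})

setMethod("show", "DetectorModel", function(object) {
  cat(sprintf("DetectorModel: %.4g mm square at %.4g mm\n",
              object@side, object@distance))
})

setMethod("show", "SymmetryGroup", function(object) {
  cat(sprintf("SymmetryGroup '%s': %d operators\n",
              object@label, length(object@ops)))
})

setMethod("show", "SnapshotPattern", function(object) {
  cat(sprintf("SnapshotPattern %d: %d observations\n",
              object@id, nrow(object@obs)))
})

setMethod("show", "SnapshotDataset", function(object) {
  nobs <- sum(vapply(object@patterns, function(p) nrow(p@obs), 0L))
  cat(sprintf("SnapshotDataset: %d patterns, %d observations, %d reference hkl\n",
              length(object@patterns), nobs, nrow(object@reference)))
  cat(sprintf("  symmetry %s, r = %.3g nm^-1\n",
              object@symmetry@label, object@sphereRadius))
})

setMethod("show", "PostRefinementRun", function(object) {
  cat(sprintf("PostRefinementRun: %d cycle(s)\n", object@nCycles))
  cat("  overall R after cycles", paste(seq_along(object@rHistory) - 1,
      collapse = ", "), ":", paste(sprintf("%.4f", object@rHistory),
      collapse = ", "), "\n")
})
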