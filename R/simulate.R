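# Snapshot dataset simulator: synthetic Wilson-distributed reference
# intensities, random orientations, reflection prediction on a square
# detector, partial intensities with per-pattern scale factors and constant
# Gaussian noise, and perturbed starting geometries.

#' Simulation configuration
#'
#' Defaults are the package's reference study conditions: 1000 patterns of a
#' rhombohedral a = 144.2 A, alpha = 113.78 deg crystal (Laue class -3m on
#' primitive axes), an 8 keV beam with 0.05% top-hat bandwidth and 1 mrad
#' convergence, a 76.8 mm square detector at 50 mm, reflection-sphere radius
#' 5e-3 nm^-1, reciprocal-basis perturbations uniform within +-0.1% per
#' component, overall scales ~ N(1, 0.3) and constant Gaussian noise with
#' standard deviation equal to the mean reference intensity in the highest
#' resolution shell (of \code{noiseShells} equal-count shells).
#'
#' @param nPatterns number of patterns.
#' @param cell a \linkS4class{UnitCell}.
#' @param symmetry a \linkS4class{SymmetryGroup} for merging keys.
#' @param beam a \linkS4class{BeamModel}.
#' @param detector a \linkS4class{DetectorModel}.
#' @param sphereRadius reflection-sphere radius r, nm^-1.
#' @param basisErrorMax maximum fractional perturbation per basis component
#'   (flat-top distribution).
#' @param scaleMean,scaleSD distribution of the per-pattern overall scales.
#' @param wilsonB isotropic B-factor (A^2) of the synthetic Wilson intensity
#'   fall-off; 0 gives resolution-independent means.
#' @param meanIntensity mean full intensity at zero scattering angle
#'   (arbitrary units).
#' @param noiseSD explicit noise standard deviation, or NULL to use the
#'   highest-resolution-shell rule.
#' @param noiseShells number of equal-count shells for the noise rule.
#' @param dMin reference-table resolution cutoff (A); NULL = detector corner.
#' @param seed RNG seed.
#' @return a list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nPatterns = 1000,
                             cell = unitCell(144.2, 113.78),
                             symmetry = laueGroup("-3m_R"),
                             beam = beamModel(8, 5e-4, 1e-3),
                             detector = detectorModel(76.8, 50),
                             sphereRadius = 5e-3,
                             basisErrorMax = 0.001,
                             scaleMean = 1, scaleSD = 0.3,
                             wilsonB = 25, meanIntensity = 1000,
                             noiseSD = NULL, noiseShells = 20,
                             dMin = NULL, seed = 1) {
  stopifnot(nPatterns >= 0, sphereRadius > 0,
            basisErrorMax >= 0, basisErrorMax < 1)
  cfg <- list(nPatterns = as.integer(nPatterns), cell = cell,
              symmetry = symmetry, beam = beam, detector = detector,
              sphereRadius = sphereRadius, basisErrorMax = basisErrorMax,
              scaleMean = scaleMean, scaleSD = scaleSD, wilsonB = wilsonB,
              meanIntensity = meanIntensity, noiseSD = noiseSD,
              noiseShells = as.integer(noiseShells), dMin = dMin,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

# candidate Miller indices with d >= dMin for the cell's indexing basis
candidateIndices <- function(cell, dMin) {
  B0 <- reciprocalBasis(cell)
  smax <- 10 / dMin
  D <- directBasis(cell)
  lens <- sqrt(colSums(D^2))
  bounds <- as.integer(floor(lens * smax))
  cpp_candidate_hkl(crossprod(B0), bounds[1], bounds[2], bounds[3], smax)
}

#' Generate a synthetic reference intensity table
#'
#' All symmetry-unique reflections with d >= dMin receive intensities drawn
#' from an exponential (Wilson, acentric) distribution whose mean falls off
#' with resolution as exp(-B / (2 d^2)).
#'
#' @param cell a \linkS4class{UnitCell}.
#' @param symmetry a \linkS4class{SymmetryGroup}.
#' @param dMin resolution cutoff, Angstrom.
#' @param wilsonB isotropic B-factor, A^2.
#' @param meanIntensity mean intensity at zero angle.
#' @return data.frame (h, k, l, key, d, I), one row per canonical hkl.
#' @export
generateReferenceIntensities <- function(cell, symmetry, dMin,
                                         wilsonB = 25, meanIntensity = 1000) {
  cand <- candidateIndices(cell, dMin)
  can <- canonicalReflections(cand, symmetry)
  key <- hklKey(can[, 1], can[, 2], can[, 3])
  keep <- !duplicated(key)
  hkl <- can[keep, , drop = FALSE]
  key <- key[keep]
  d <- resolutionOf(hkl, reciprocalBasis(cell))
  mean_d <- meanIntensity * exp(-wilsonB / (2 * d^2))
  I <- stats::rexp(length(d), rate = 1 / mean_d)
  data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
             key = key, d = d, I = I)
}

#' Perturb a reciprocal basis component-wise
#'
#' Each of the nine components v is replaced by v (1 + u) with u drawn
#' independently and uniformly from [-maxFrac, +maxFrac] (flat-top errors).
#'
#' @param basis 3x3 reciprocal basis.
#' @param maxFrac maximum fractional error (>= 0).
#' @return perturbed 3x3 basis.
#' @export
perturbBasis <- function(basis, maxFrac) {
  stopifnot(maxFrac >= 0)
  basis * (1 + matrix(stats::runif(9, -maxFrac, maxFrac), 3, 3))
}

#' Predict observable reflections for one orientation
#'
#' Returns every reflection whose reflection sphere intersects the excitation
#' slab (unclamped rHigh < +r and rLow > -r) and whose diffracted beam, at the
#' nominal wavelength, falls within the detector square; (0,0,0) is excluded.
#'
#' @param basis 3x3 reciprocal basis (nm^-1).
#' @param beam a \linkS4class{BeamModel}.
#' @param detector a \linkS4class{DetectorModel}.
#' @param r reflection-sphere radius, nm^-1.
#' @param kL Lorentz normalization (default: computed from beam + detector).
#' @param candidates optional precomputed candidate index matrix (as from the
#'   internal enumeration); when NULL it is enumerated to the detector-corner
#'   resolution using the cell implied by \code{cellForCandidates}.
#' @param cellForCandidates \linkS4class{UnitCell} used to enumerate
#'   candidates when \code{candidates} is NULL.
#' @return data.frame (h, k, l, rHigh, rLow, p, L, x, y, d): unclamped
#'   distances, clamped partiality, Lorentz factor, detector position (mm)
#'   and resolution (A).
#' @export
predictReflections <- function(basis, beam, detector, r,
                               kL = lorentzNormalization(beam, detector),
                               candidates = NULL, cellForCandidates = NULL) {
  if (is.null(candidates)) {
    if (is.null(cellForCandidates))
      stop("supply either candidates or cellForCandidates")
    dCorner <- detectorResolutionLimits(detector, beam@wavelength)[["corner"]]
    candidates <- candidateIndices(cellForCandidates, dCorner)
  }
  pr <- cpp_predict(basis, candidates, beam@wavelength / 10, beam@bandwidth,
                    beam@convergence, r, kL, detector@side, detector@distance)
  data.frame(h = pr$h, k = pr$k, l = pr$l, rHigh = pr$rhigh, rLow = pr$rlow,
             p = pr$p, L = pr$L, x = pr$x, y = pr$y, d = pr$d)
}

# noise SD: mean reference intensity in the highest-resolution of
# `shells` equal-count shells
noiseFromReference <- function(reference, shells) {
  ord <- order(reference$d)               # ascending d = highest res first
  n <- nrow(reference)
  take <- ord[seq_len(max(1L, n %/% shells))]
  mean(reference$I[take])
}

#' Simulate a full snapshot dataset
#'
#' For each pattern: a Haar-random orientation, an overall scale
#' G ~ N(scaleMean, scaleSD) (redrawn if non-positive), predicted reflections
#' under the true basis, partial intensities
#' I = G p L I_full + N(0, sigma_noise), and a perturbed working basis whose
#' partialities and Lorentz factors are stored as the current model values.
#' Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \linkS4class{SnapshotDataset}.
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  beam <- config$beam; det <- config$detector; cell <- config$cell
  r <- config$sphereRadius
  kL <- lorentzNormalization(beam, det)
  dCorner <- detectorResolutionLimits(det, beam@wavelength)[["corner"]]
  dMin <- if (is.null(config$dMin)) dCorner else config$dMin
  reference <- generateReferenceIntensities(cell, config$symmetry, dMin,
                                            config$wilsonB,
                                            config$meanIntensity)
  sigmaNoise <- if (is.null(config$noiseSD))
    noiseFromReference(reference, config$noiseShells) else config$noiseSD
  cand <- candidateIndices(cell, dMin)
  B0 <- reciprocalBasis(cell)
  lamNM <- beam@wavelength / 10

  patterns <- vector("list", config$nPatterns)
  for (j in seq_len(config$nPatterns)) {
    rot <- randomOrientation()
    trueB <- rot %*% B0
    G <- stats::rnorm(1, config$scaleMean, config$scaleSD)
    while (G <= 0) G <- stats::rnorm(1, config$scaleMean, config$scaleSD)
    pred <- predictReflections(trueB, beam, det, r, kL, candidates = cand)
    hklm <- as.matrix(pred[, c("h", "k", "l")])
    storage.mode(hklm) <- "integer"
    key <- canonicalKeys(hklm, config$symmetry)
    refIdx <- match(key, reference$key)
    Ifull <- reference$I[refIdx]
    n <- nrow(pred)
    iobs <- G * pred$p * pred$L * Ifull +
      if (sigmaNoise > 0) stats::rnorm(n, 0, sigmaNoise) else 0
    workB <- perturbBasis(trueB, config$basisErrorMax)
    cur <- cpp_excitation(workB, hklm, lamNM, beam@bandwidth,
                          beam@convergence, r, kL, FALSE)
    obs <- data.frame(h = pred$h, k = pred$k, l = pred$l, key = key,
                      refIdx = refIdx, d = pred$d, iobs = iobs,
                      sigma = rep(max(sigmaNoise, .Machine$double.eps), n),
                      p = cur$p, L = cur$L,
                      pTrue = pred$p, LTrue = pred$L)
    patterns[[j]] <- new("SnapshotPattern", id = j, basis = workB,
                         trueBasis = trueB, trueScale = G, obs = obs)
  }
  trueScales <- vapply(patterns, function(p) p@trueScale, 0)
  new("SnapshotDataset", patterns = patterns, reference = reference,
      cell = cell, beam = beam, detector = det, symmetry = config$symmetry,
      sphereRadius = r, lorentzNorm = kL,
      truth = list(trueScales = trueScales, sigmaNoise = sigmaNoise,
                   seed = config$seed, config = config))
}

#' Re-perturb the working bases of a simulated dataset
#'
#' Produces a companion dataset with identical observations but working
#' bases re-drawn from the true bases at a different maximum fractional
#' error; the stored model partialities/Lorentz factors are recomputed.
#'
#' @param dataset a simulated \linkS4class{SnapshotDataset}.
#' @param maxFrac new maximum fractional basis error.
#' @param seed RNG seed for the new perturbations.
#' @return the re-perturbed \linkS4class{SnapshotDataset}.
#' @export
reperturbDataset <- function(dataset, maxFrac, seed = 1) {
  set.seed(seed)
  beam <- dataset@beam
  lamNM <- beam@wavelength / 10
  dataset@patterns <- lapply(dataset@patterns, function(pat) {
    workB <- perturbBasis(pat@trueBasis, maxFrac)
    hklm <- as.matrix(pat@obs[, c("h", "k", "l")])
    storage.mode(hklm) <- "integer"
    cur <- cpp_excitation(workB, hklm, lamNM, beam@bandwidth,
                          beam@convergence, dataset@sphereRadius,
                          dataset@lorentzNorm, FALSE)
    pat@basis <- workB
    pat@obs$p <- cur$p
    pat@obs$L <- cur$L
    pat
  })
  dataset
}

#' Partiality summary of a simulated dataset
#'
#' Mean and maximum generating (model-truth) partiality over all simulated
#' observations, before any rejection.
#'
#' @param dataset a simulated \linkS4class{SnapshotDataset}.
#' @param patterns optional subset of pattern indices.
#' @return named numeric: \code{mean}, \code{max}, \code{n} observations.
#' @export
partialityStatistics <- function(dataset, patterns = NULL) {
  pats <- dataset@patterns
  if (!is.null(patterns)) pats <- pats[patterns]
  p <- unlist(lapply(pats, function(x) x@obs$pTrue), use.names = FALSE)
  c(mean = mean(p), max = max(p), n = length(p))
}
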