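# Per-pattern nonlinear least-squares refinement of the nine reciprocal-basis
# components against current full-intensity estimates, and the outer
# scale-merge-refine driver.

#' Intensity residual of partial observations
#'
#' Delta I = I_partial / (G L) - p I_full: the difference between the
#' Lorentz- and scale-corrected observed intensity and the partiality-scaled
#' full-intensity estimate. The refined objective is the sum of squared
#' residuals over the selected reflections of a pattern.
#'
#' @param iobs partial intensities.
#' @param p partialities (current model values).
#' @param L Lorentz factors.
#' @param G overall pattern scale.
#' @param Ifull current full-intensity estimates.
#' @return residual vector.
#' @export
residualIntensity <- function(iobs, p, L, G, Ifull) {
  iobs / (G * L) - p * Ifull
}

#' Dataset-wide multiplicity of scalable measurements
#'
#' Counts, per canonical hkl, the measurements with p >= pMin across all
#' patterns (whether in the same pattern or not); used by the "at least one
#' other scalable measurement" rejection rule.
#'
#' @param patterns list of \linkS4class{SnapshotPattern} or a
#'   \linkS4class{SnapshotDataset}.
#' @param pMin partiality threshold.
#' @return data.frame (key, count).
#' @export
multiplicityIndex <- function(patterns, pMin = 0.1) {
  if (is(patterns, "SnapshotDataset")) patterns <- patterns@patterns
  keys <- unlist(lapply(patterns, function(p)
    p@obs$key[is.finite(p@obs$p) & p@obs$p >= pMin]), use.names = FALSE)
  uk <- sort(unique(keys))
  data.frame(key = uk, count = tabulate(match(keys, uk), length(uk)))
}

#' Select the refinable observations of a pattern
#'
#' Keeps observations with I >= snr * sigma, partiality >= pMin, a current
#' merged-intensity estimate, and dataset multiplicity of the canonical hkl
#' of at least 2. An empty selection means the caller skips refinement for
#' the pattern.
#'
#' @param pattern a \linkS4class{SnapshotPattern}.
#' @param merged current merged intensity table.
#' @param multiplicity data.frame from \code{\link{multiplicityIndex}}.
#' @param pMin partiality threshold.
#' @param snr signal-to-noise threshold (I >= snr * sigma).
#' @return integer indices into the pattern's observation rows.
#' @export
selectRefinable <- function(pattern, merged, multiplicity, pMin = 0.1,
                            snr = 3) {
  obs <- pattern@obs
  Iref <- merged$I[match(obs$key, merged$key)]
  count <- multiplicity$count[match(obs$key, multiplicity$key)]
  count[is.na(count)] <- 0L
  which(is.finite(obs$iobs) & obs$iobs >= snr * obs$sigma &
          is.finite(obs$p) & obs$p >= pMin &
          is.finite(obs$L) & obs$L > 0 &
          is.finite(Iref) & count >= 2)
}

#' Gauss-Newton normal equations for one pattern
#'
#' Jacobian entries are -I_full dp/dv (the Lorentz gradient is taken as
#' zero); the normal matrix is J^T J and the right-hand side -J^T Delta I.
#'
#' @param pattern a \linkS4class{SnapshotPattern}.
#' @param sel observation indices (from \code{\link{selectRefinable}}).
#' @param merged current merged intensity table.
#' @param G pattern scale factor.
#' @param beam a \linkS4class{BeamModel}.
#' @param r reflection-sphere radius, nm^-1.
#' @param kL Lorentz normalization, nm^-1.
#' @return list with \code{A} (9x9), \code{b} (length 9), \code{residuals}
#'   and \code{J} (n x 9).
#' @export
buildNormalEquations <- function(pattern, sel, merged, G, beam, r, kL) {
  obs <- pattern@obs[sel, , drop = FALSE]
  hklm <- as.matrix(obs[, c("h", "k", "l")])
  storage.mode(hklm) <- "integer"
  ex <- cpp_excitation(pattern@basis, hklm, beam@wavelength / 10,
                       beam@bandwidth, beam@convergence, r, kL, TRUE)
  Iref <- merged$I[match(obs$key, merged$key)]
  dI <- residualIntensity(obs$iobs, ex$p, ex$L, G, Iref)
  J <- ex$grad * (-Iref)
  list(A = crossprod(J), b = -crossprod(J, dI)[, 1], residuals = dI, J = J)
}

#' Solve rescaled normal equations by filtered SVD
#'
#' Applies Bricogne diagonal rescaling D = diag(1/sqrt(A_ii)) so all diagonal
#' elements become 1 (parameters with zero diagonal are frozen), takes the
#' SVD of the rescaled matrix, zeroes singular values below
#' \code{eigFrac} times the largest, and back-transforms the pseudo-inverse
#' solution.
#'
#' @param A 9x9 symmetric normal matrix.
#' @param b right-hand side, length 9.
#' @param eigFrac elimination threshold relative to the largest singular
#'   value (default 1e-6).
#' @return list with \code{step} (length 9), \code{eliminated} (count of
#'   zeroed singular values among non-frozen parameters) and \code{frozen}
#'   (count of zero-diagonal parameters).
#' @export
solveRescaledSVD <- function(A, b, eigFrac = 1e-6) {
  dg <- diag(A)
  frozen <- !(is.finite(dg) & dg > 0)
  if (all(frozen))
    return(list(step = numeric(length(b)), eliminated = length(b),
                frozen = length(b)))
  Dm <- ifelse(frozen, 0, 1 / sqrt(dg))
  Ap <- A * outer(Dm, Dm)
  bp <- b * Dm
  sv <- svd(Ap)
  smax <- max(sv$d)
  keep <- sv$d >= eigFrac * smax & sv$d > 0
  eliminated <- max(0L, sum(!keep) - sum(frozen))
  inv <- ifelse(keep, 1 / sv$d, 0)
  step <- Dm * (sv$v %*% (inv * (t(sv$u) %*% bp)))[, 1]
  list(step = step, eliminated = eliminated, frozen = sum(frozen))
}

#' Refine the reciprocal basis of one pattern
#'
#' Iterates select / build / solve / apply. After each step all selected
#' partialities are recomputed; iteration stops when the largest partiality
#' change is below \code{dpTol} (default 0.01) or after \code{maxIter}
#' (default 10) iterations. If a step assigns zero partiality to more than a
#' third of the selected reflections, the basis is restored and iteration
#' stops with the \code{reverted} flag. After refinement the pattern's stored
#' p and L are recomputed for all its observations.
#'
#' @param pattern a \linkS4class{SnapshotPattern}.
#' @param merged current merged intensity table.
#' @param G the pattern's scale factor (held fixed during refinement).
#' @param beam a \linkS4class{BeamModel}.
#' @param r reflection-sphere radius, nm^-1.
#' @param kL Lorentz normalization, nm^-1.
#' @param multiplicity data.frame from \code{\link{multiplicityIndex}}.
#' @param pMin,snr selection thresholds.
#' @param eigFrac SVD elimination threshold.
#' @param maxIter,dpTol termination controls.
#' @return list with \code{pattern} (updated) and \code{result}, a one-row
#'   data.frame: id, nUsed, iterations, maxDeltaP (last iteration),
#'   objective, nSolves, nSolvesElim1, meanEliminated, reverted, reason.
#' @export
refinePattern <- function(pattern, merged, G, beam, r, kL, multiplicity,
                          pMin = 0.1, snr = 3, eigFrac = 1e-6,
                          maxIter = 10L, dpTol = 0.01) {
  sel <- selectRefinable(pattern, merged, multiplicity, pMin, snr)
  mkrow <- function(nUsed, iters, maxdp, obj, elim, reverted, reason) {
    data.frame(id = pattern@id, nUsed = nUsed, iterations = iters,
               maxDeltaP = maxdp, objective = obj,
               nSolves = length(elim),
               nSolvesElim1 = sum(elim == 1L),
               meanEliminated = if (length(elim)) mean(elim) else NA_real_,
               reverted = reverted, reason = reason)
  }
  if (length(sel) == 0)
    return(list(pattern = pattern,
                result = mkrow(0L, 0L, NA_real_, NA_real_, integer(0),
                               FALSE, "skipped")))
  obs <- pattern@obs[sel, , drop = FALSE]
  hklS <- as.matrix(obs[, c("h", "k", "l")])
  storage.mode(hklS) <- "integer"
  Iref <- merged$I[match(obs$key, merged$key)]
  lam <- beam@wavelength / 10
  B <- pattern@basis
  ex <- cpp_excitation(B, hklS, lam, beam@bandwidth, beam@convergence,
                       r, kL, TRUE)
  elim <- integer(0)
  maxdp <- NA_real_
  reverted <- FALSE
  reason <- "max_iterations"
  iters <- 0L
  for (it in seq_len(maxIter)) {
    dI <- residualIntensity(obs$iobs, ex$p, ex$L, G, Iref)
    J <- ex$grad * (-Iref)
    sol <- solveRescaledSVD(crossprod(J), -crossprod(J, dI)[, 1], eigFrac)
    elim <- c(elim, sol$eliminated)
    iters <- it
    Bnew <- B + matrix(sol$step, 3, 3)
    exNew <- cpp_excitation(Bnew, hklS, lam, beam@bandwidth,
                            beam@convergence, r, kL, TRUE)
    maxdp <- max(abs(exNew$p - ex$p))
    if (mean(exNew$p == 0) > 1 / 3) {
      reverted <- TRUE
      reason <- "reverted"
      break
    }
    B <- Bnew
    ex <- exNew
    if (maxdp < dpTol) {
      reason <- "converged"
      break
    }
  }
  objective <- sum(residualIntensity(obs$iobs, ex$p, ex$L, G, Iref)^2)
  pattern@basis <- B
  hklAll <- as.matrix(pattern@obs[, c("h", "k", "l")])
  storage.mode(hklAll) <- "integer"
  cur <- cpp_excitation(B, hklAll, lam, beam@bandwidth, beam@convergence,
                        r, kL, FALSE)
  pattern@obs$p <- cur$p
  pattern@obs$L <- cur$L
  list(pattern = pattern,
       result = mkrow(length(sel), iters, maxdp, objective, elim,
                      reverted, reason))
}

#' Baseline merges for comparison
#'
#' \code{"punit"} forces all partialities to 1 (Lorentz correction only) and
#' runs the usual iterative scaling; \code{"noscale"} merges with all scales
#' fixed at 1 using the current partiality model (no scaling step).
#'
#' @param dataset a \linkS4class{SnapshotDataset}.
#' @param type baseline type.
#' @param rounds scaling rounds for the \code{"punit"} baseline.
#' @param pMin partiality rejection threshold.
#' @param weighted sigma-weighted merging.
#' @return a merged intensity table.
#' @export
mergeBaseline <- function(dataset, type = c("punit", "noscale"), rounds = 3,
                          pMin = 0.1, weighted = FALSE) {
  type <- match.arg(type)
  if (type == "noscale")
    return(mergeIntensities(dataset, scales = 1, pMin = pMin,
                            weighted = weighted))
  patterns <- lapply(dataset@patterns, function(p) {
    p@obs$p <- rep(1, nrow(p@obs))
    p
  })
  kabschScaleMerge(patterns, rounds = rounds, pMin = pMin,
                   weighted = weighted)$merged
}

#' Run the full scale-merge-refine procedure
#'
#' Cycle structure: an initial scaling-and-merging step, then
#' \code{nCycles} repetitions of (refine every pattern against the current
#' merged estimates, then re-scale and re-merge with the refined geometry).
#' \code{nCycles = 0} reproduces the no-refinement baseline (initial scaling
#' and merging alone). Scales are held fixed during the inner refinement
#' iterations and re-fitted at the next scaling step.
#'
#' @param dataset a \linkS4class{SnapshotDataset}.
#' @param nCycles number of refinement cycles (>= 0).
#' @param pMin partiality rejection threshold.
#' @param snr signal-to-noise selection threshold.
#' @param eigFrac SVD elimination threshold.
#' @param scaleRounds rounds of iterative scaling per merge step.
#' @param maxIter,dpTol inner refinement termination controls.
#' @param weighted sigma-weighted merging.
#' @return a \linkS4class{PostRefinementRun}; the refined dataset is in the
#'   \code{dataset} slot.
#' @export
runCycles <- function(dataset, nCycles = 3, pMin = 0.1, snr = 3,
                      eigFrac = 1e-6, scaleRounds = 3, maxIter = 10L,
                      dpTol = 0.01, weighted = FALSE) {
  stopifnot(nCycles >= 0)
  beam <- dataset@beam
  r <- dataset@sphereRadius
  kL <- dataset@lorentzNorm
  sm <- kabschScaleMerge(dataset@patterns, scaleRounds, pMin, weighted)
  mergedTables <- list(sm$merged)
  scalesList <- list(sm$scales)
  rHistory <- overallRFactor(sm$merged, dataset@reference)
  pairCor <- partialityPairs(dataset@patterns, sm$scales, sm$merged,
                             subsampleTarget = 0)$correlation
  refinement <- list()
  for (cy in seq_len(nCycles)) {
    mult <- multiplicityIndex(dataset@patterns, pMin)
    rows <- vector("list", length(dataset@patterns))
    for (j in seq_along(dataset@patterns)) {
      pat <- dataset@patterns[[j]]
      rp <- refinePattern(pat, sm$merged, sm$scales[[as.character(pat@id)]],
                          beam, r, kL, mult, pMin, snr, eigFrac, maxIter,
                          dpTol)
      dataset@patterns[[j]] <- rp$pattern
      rows[[j]] <- rp$result
    }
    refinement[[cy]] <- do.call(rbind, rows)
    sm <- kabschScaleMerge(dataset@patterns, scaleRounds, pMin, weighted)
    mergedTables[[cy + 1]] <- sm$merged
    scalesList[[cy + 1]] <- sm$scales
    rHistory <- c(rHistory, overallRFactor(sm$merged, dataset@reference))
    pairCor <- c(pairCor,
                 partialityPairs(dataset@patterns, sm$scales, sm$merged,
                                 subsampleTarget = 0)$correlation)
  }
  new("PostRefinementRun", mergedTables = mergedTables, scales = scalesList,
      refinement = refinement, rHistory = rHistory,
      nCycles = as.integer(nCycles), pairCorrelations = pairCor,
      dataset = dataset)
}
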