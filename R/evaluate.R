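# Evaluation: R-factor in resolution shells against reference intensities,
# observed-vs-calculated partiality diagnostics, and shell statistics over
# the raw simulated observations.

#' R-factor between a merged table and a reference, in resolution shells
#'
#' R = sum |I_merged - k I_ref| / sum (k I_ref) over the common reflections,
#' with k the single least-squares overall scale between the two sets
#' (gauge-invariant). Shells use equal-count binning by d.
#'
#' @param merged merged intensity table (key, d, I, ...).
#' @param reference reference table (key, d, I).
#' @param nShells number of equal-count shells (default 10).
#' @return data.frame with one row per shell (dMax, dMin, n, R) plus the
#'   overall R and scale as attributes \code{"overallR"}, \code{"scale"}.
#' @export
rFactorShells <- function(merged, reference, nShells = 10) {
  idx <- match(merged$key, reference$key)
  ok <- !is.na(idx)
  if (!any(ok)) stop("no common reflections between merged and reference")
  Im <- merged$I[ok]
  Ir <- reference$I[idx[ok]]
  d <- reference$d[idx[ok]]
  k <- sum(Im * Ir) / sum(Ir^2)
  n <- length(Im)
  nShells <- max(1L, min(nShells, n))
  ord <- order(d, decreasing = TRUE)              # low resolution first
  shell <- integer(n)
  shell[ord] <- ceiling(seq_len(n) / (n / nShells))
  shell[shell > nShells] <- nShells
  rows <- lapply(seq_len(nShells), function(s) {
    i <- shell == s
    data.frame(dMax = max(d[i]), dMin = min(d[i]), n = sum(i),
               R = sum(abs(Im[i] - k * Ir[i])) / sum(k * Ir[i]))
  })
  out <- do.call(rbind, rows)
  attr(out, "overallR") <- sum(abs(Im - k * Ir)) / sum(k * Ir)
  attr(out, "scale") <- k
  out
}

#' Overall R-factor (scalar convenience wrapper)
#' @inheritParams rFactorShells
#' @return the overall R-factor.
#' @export
overallRFactor <- function(merged, reference) {
  attr(rFactorShells(merged, reference, nShells = 1), "overallR")
}

#' Observed versus calculated partiality
#'
#' The observed partiality of a measurement is the ratio of its intensity,
#' corrected for the overall scale and Lorentz factor but not partiality, to
#' the current full-intensity estimate: p_obs = I / (G L I_full). Calculated
#' partiality is the geometric model value. Pairs with I_full <= 0 or
#' unusable L are skipped. The Pearson correlation is computed over all
#' pairs; a seeded uniform subsample of about \code{subsampleTarget} points
#' is returned for plotting (0 = no subsample, return all).
#'
#' @param patterns list of \linkS4class{SnapshotPattern} or a
#'   \linkS4class{SnapshotDataset}.
#' @param scales named per-pattern scale factors.
#' @param merged current merged intensity table.
#' @param subsampleTarget approximate number of returned pairs; default is
#'   the mean number of observations per pattern.
#' @return list with \code{pairs} (data.frame pid, key, pCalc, pObs) and
#'   \code{correlation}.
#' @export
partialityPairs <- function(patterns, scales, merged,
                            subsampleTarget = NULL) {
  if (is(patterns, "SnapshotDataset")) patterns <- patterns@patterns
  pool <- poolObservations(patterns)
  G <- scaleForPID(pool$pid, scales)
  Ifull <- merged$I[match(pool$key, merged$key)]
  ok <- is.finite(Ifull) & Ifull > 0 & is.finite(pool$L) & pool$L > 0 &
    is.finite(pool$p)
  pObs <- pool$iobs[ok] / (G[ok] * pool$L[ok] * Ifull[ok])
  pCalc <- pool$p[ok]
  corr <- stats::cor(pObs, pCalc)
  pairs <- data.frame(pid = pool$pid[ok], key = pool$key[ok],
                      pCalc = pCalc, pObs = pObs)
  if (is.null(subsampleTarget))
    subsampleTarget <- ceiling(nrow(pool) / max(1, length(patterns)))
  if (subsampleTarget > 0 && nrow(pairs) > subsampleTarget)
    pairs <- pairs[sample.int(nrow(pairs), subsampleTarget), ]
  list(pairs = pairs, correlation = corr)
}

#' Shell statistics of the raw simulated observations
#'
#' Number of reflections, mean partiality and maximum partiality in shells
#' of equal width in 1/d, computed over all observations before any
#' rejection. Uses the generating partialities when present (simulated
#' data), else the current model values.
#'
#' @param patterns list of \linkS4class{SnapshotPattern} or a
#'   \linkS4class{SnapshotDataset}.
#' @param nShells number of equal-1/d-width shells.
#' @return data.frame (dMax, dMin, n, meanP, maxP) per shell.
#' @export
shellStatistics <- function(patterns, nShells = 10) {
  if (is(patterns, "SnapshotDataset")) patterns <- patterns@patterns
  obs <- do.call(rbind, lapply(patterns, function(p) {
    pcol <- if ("pTrue" %in% names(p@obs)) p@obs$pTrue else p@obs$p
    data.frame(d = p@obs$d, p = pcol)
  }))
  if (nrow(obs) == 0) stop("no observations")
  invd <- 1 / obs$d
  br <- seq(min(invd), max(invd), length.out = nShells + 1)
  br[1] <- br[1] - 1e-9
  br[nShells + 1] <- br[nShells + 1] + 1e-9
  shell <- cut(invd, br, labels = FALSE)
  rows <- lapply(seq_len(nShells), function(s) {
    i <- which(shell == s)
    if (length(i) == 0)
      return(data.frame(dMax = 1 / br[s], dMin = 1 / br[s + 1], n = 0L,
                        meanP = NA_real_, maxP = NA_real_))
    data.frame(dMax = 1 / br[s], dMin = 1 / br[s + 1], n = length(i),
               meanP = mean(obs$p[i]), maxP = max(obs$p[i]))
  })
  do.call(rbind, rows)
}
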