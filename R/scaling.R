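# The method of scaled partials: convert partial intensities to
# full-intensity estimates, determine per-pattern scale factors by the
# linear-cost iterative merge-and-rescale scheme, and merge with symmetry
# folding and low-partiality rejection.

keyToHKL <- function(key) {
  two <- 2 * KEY_OFF
  l <- key %% two - KEY_OFF
  k <- (key %/% two) %% two - KEY_OFF
  h <- key %/% (two * two) - KEY_OFF
  cbind(h = as.integer(h), k = as.integer(k), l = as.integer(l))
}

# one flat table of all observations, used by merging/scaling/diagnostics
poolObservations <- function(patterns) {
  n <- vapply(patterns, function(p) nrow(p@obs), 0L)
  pid <- rep.int(vapply(patterns, function(p) p@id, 0L), n)
  obs <- do.call(rbind, lapply(patterns, function(p)
    p@obs[, c("key", "d", "iobs", "sigma", "p", "L")]))
  obs$pid <- pid
  obs
}

#' Scale a partial observation up to a full-intensity estimate
#'
#' I_full = I_partial / (p L). Observations with non-positive p or L cannot
#' be scaled and return NA (callers treat them as flagged/excluded).
#'
#' @param iobs partial intensity (vector).
#' @param p partiality (vector).
#' @param L Lorentz factor (vector).
#' @return per-observation full-intensity estimates.
#' @export
scaleUp <- function(iobs, p, L) {
  ifelse(is.finite(p) & is.finite(L) & p > 0 & L > 0, iobs / (p * L),
         NA_real_)
}

#' Merge scaled-up observations into a full-intensity table
#'
#' For each canonical hkl the estimate is the plain mean over all usable
#' measurements of I_partial / (p L G_j); observations with p < pMin are not
#' included. With \code{weighted = TRUE} an inverse-variance weighted mean is
#' used instead.
#'
#' @param patterns list of \linkS4class{SnapshotPattern} (or a
#'   \linkS4class{SnapshotDataset}).
#' @param scales named numeric of per-pattern scales G_j (names = pattern
#'   ids), or a single value recycled.
#' @param pMin partiality rejection threshold (default 0.1).
#' @param weighted use 1/sigma^2 weights in the mean.
#' @return data.frame (key, h, k, l, d, I, sigma, n) with one row per
#'   canonical hkl that received at least one contribution.
#' @export
mergeIntensities <- function(patterns, scales = 1, pMin = 0.1,
                             weighted = FALSE) {
  if (is(patterns, "SnapshotDataset")) patterns <- patterns@patterns
  pool <- poolObservations(patterns)
  mergePool(pool, scales, pMin, weighted)
}

mergePool <- function(pool, scales = 1, pMin = 0.1, weighted = FALSE) {
  G <- scaleForPID(pool$pid, scales)
  full <- scaleUp(pool$iobs, pool$p, pool$L) / G
  use <- is.finite(full) & pool$p >= pMin
  if (!any(use)) stop("no usable observations to merge")
  key <- pool$key[use]
  uk <- sort(unique(key))
  idx <- match(key, uk)
  sigFull <- pool$sigma[use] / (pool$p[use] * pool$L[use] * G[use])
  if (weighted) {
    w <- 1 / sigFull^2
    sw <- rowsum(w, idx)[, 1]
    I <- rowsum(full[use] * w, idx)[, 1] / sw
    sig <- sqrt(1 / sw)
  } else {
    n <- tabulate(idx, length(uk))
    I <- rowsum(full[use], idx)[, 1] / n
    sig <- sqrt(rowsum(sigFull^2, idx)[, 1]) / n
  }
  n <- tabulate(idx, length(uk))
  d <- rowsum(pool$d[use], idx)[, 1] / n
  hkl <- keyToHKL(uk)
  data.frame(key = uk, h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
             d = d, I = I, sigma = sig, n = n)
}

scaleForPID <- function(pid, scales) {
  if (length(scales) == 1 && is.null(names(scales)))
    return(rep.int(scales, length(pid)))
  G <- scales[match(as.character(pid), names(scales))]
  if (anyNA(G)) stop("missing scale factor for some pattern ids")
  unname(G)
}

#' Fit the overall scale of one pattern against a reference table
#'
#' Least-squares ratio G = sum(I_full,e * Iref) / sum(Iref^2) over the
#' pattern's usable observations (p >= pMin, scalable, reference entry
#' present). With no usable observation, G = 1 is returned with attribute
#' \code{unscaled = TRUE}.
#'
#' @param pattern a \linkS4class{SnapshotPattern}.
#' @param merged a merged table (as from \code{\link{mergeIntensities}}).
#' @param pMin partiality threshold.
#' @return the fitted scale factor G.
#' @export
fitScale <- function(pattern, merged, pMin = 0.1) {
  obs <- pattern@obs
  full <- scaleUp(obs$iobs, obs$p, obs$L)
  ref <- merged$I[match(obs$key, merged$key)]
  use <- is.finite(full) & obs$p >= pMin & is.finite(ref)
  if (!any(use) || sum(ref[use]^2) == 0) {
    G <- 1
    attr(G, "unscaled") <- TRUE
    return(G)
  }
  sum(full[use] * ref[use]) / sum(ref[use]^2)
}

#' Iterative scaling and merging (Kabsch-style, linear cost)
#'
#' Round 0 merges all patterns with equal scales; each subsequent round fits
#' every pattern's scale against the current merged table, renormalizes the
#' mean scale to 1 (gauge fixing) and re-merges. Cost is linear in the number
#' of patterns.
#'
#' @param patterns list of \linkS4class{SnapshotPattern} or a
#'   \linkS4class{SnapshotDataset}.
#' @param rounds number of fit-and-remerge rounds (>= 1).
#' @param pMin partiality rejection threshold.
#' @param weighted sigma-weighted merging.
#' @return list with \code{scales} (named numeric, one per pattern),
#'   \code{merged} (final merged table), \code{history} (mean |delta G| per
#'   round) and \code{unscaled} (ids of patterns that could not be scaled).
#' @export
kabschScaleMerge <- function(patterns, rounds = 3, pMin = 0.1,
                             weighted = FALSE) {
  if (is(patterns, "SnapshotDataset")) patterns <- patterns@patterns
  stopifnot(rounds >= 1)
  pool <- poolObservations(patterns)
  ids <- vapply(patterns, function(p) p@id, 0L)
  G <- stats::setNames(rep(1, length(patterns)), ids)
  merged <- mergePool(pool, G, pMin, weighted)

  full <- scaleUp(pool$iobs, pool$p, pool$L)
  usable <- is.finite(full) & pool$p >= pMin
  history <- numeric(0)
  unscaled <- integer(0)
  pidIdx <- match(pool$pid, ids)
  for (round in seq_len(rounds)) {
    ref <- merged$I[match(pool$key, merged$key)]
    use <- usable & is.finite(ref)
    num <- rowsum(ifelse(use, full * ref, 0), pidIdx,
                  reorder = TRUE)[, 1]
    den <- rowsum(ifelse(use, ref^2, 0), pidIdx, reorder = TRUE)[, 1]
    # rowsum drops empty groups; realign to all patterns
    got <- sort(unique(pidIdx))
    numAll <- denAll <- numeric(length(ids))
    numAll[got] <- num; denAll[got] <- den
    Gnew <- ifelse(denAll > 0, numAll / denAll, NA_real_)
    unscaled <- ids[!is.finite(Gnew) | Gnew <= 0]
    Gnew[!is.finite(Gnew) | Gnew <= 0] <- 1
    Gnew <- Gnew / mean(Gnew)
    history <- c(history, mean(abs(Gnew - G)))
    G <- stats::setNames(Gnew, ids)
    merged <- mergePool(pool, G, pMin, weighted)
  }
  list(scales = G, merged = merged, history = history, unscaled = unscaled)
}
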