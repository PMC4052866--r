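# Symmetry folding for merging. Groups are explicit operator lists (no
# space-group engine); canonical asymmetric-unit representatives are the
# lexicographically greatest orbit member under (h, k, l) ordering.

#' Construct a symmetry group from explicit operators
#'
#' @param ops list of 3x3 integer matrices acting on (h,k,l); must contain
#'   the identity and be closed under composition.
#' @param label descriptive label.
#' @return a \linkS4class{SymmetryGroup}.
#' @export
symmetryGroup <- function(ops, label = "custom") {
  ops <- lapply(ops, function(m) {
    storage.mode(m) <- "integer"
    m
  })
  new("SymmetryGroup", ops = ops, label = label)
}

#' Built-in Laue groups
#'
#' \code{"1"} is the identity-only group, \code{"-1"} adds Friedel inversion.
#' \code{"-3m_R"} is the Laue class of point group 32 on rhombohedral
#' (primitive) axes: cyclic permutations of (h,k,l), the three diad images
#' -(l,k,h), -(k,h,l), -(h,l,k), and their Friedel mates (order 12).
#' \code{"-3m1_H"} is the same Laue class on hexagonal axes (order 12).
#' With \code{friedel = FALSE} the inversion-free halves are returned
#' (anomalous pairs kept separate).
#'
#' @param label one of "1", "-1", "-3m_R", "-3m1_H".
#' @param friedel merge Friedel mates (include the inversion)? Default TRUE.
#' @return a \linkS4class{SymmetryGroup}.
#' @export
laueGroup <- function(label = c("-3m_R", "-3m1_H", "-1", "1"),
                      friedel = TRUE) {
  label <- match.arg(label)
  id <- diag(3)
  base <- switch(label,
    "1" = list(id),
    "-1" = list(id),
    "-3m_R" = {
      perm <- function(i, j, k, s = 1L) {
        m <- matrix(0L, 3, 3)
        m[1, i] <- s; m[2, j] <- s; m[3, k] <- s
        m
      }
      list(id,
           perm(3, 1, 2),        # (h,k,l) -> (l,h,k)
           perm(2, 3, 1),        # (h,k,l) -> (k,l,h)
           perm(3, 2, 1, -1L),   # -> (-l,-k,-h)
           perm(2, 1, 3, -1L),   # -> (-k,-h,-l)
           perm(1, 3, 2, -1L))   # -> (-h,-l,-k)
    },
    "-3m1_H" = {
      m3 <- matrix(c(0, -1, 0, 1, -1, 0, 0, 0, 1), 3, 3)   # (k, -h-k, l)
      m2 <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), 3, 3)    # (k, h, -l)
      list(id, m3, m3 %*% m3, m2, m3 %*% m2, m3 %*% m3 %*% m2)
    })
  ops <- base
  withInv <- (friedel && label != "1") || label == "-1"
  if (withInv)
    ops <- c(ops, lapply(base, function(m) -m))
  keys <- vapply(ops, function(m) paste(as.integer(m), collapse = ","), "")
  ops <- ops[!duplicated(keys)]
  symmetryGroup(ops, label = if (withInv || label == "1") label
                             else paste0(label, " (no Friedel)"))
}

opsStack <- function(group) {
  do.call(rbind, lapply(group@ops, function(m) {
    storage.mode(m) <- "integer"
    m
  }))
}

#' Orbit of a reflection under a symmetry group
#'
#' @param hkl integer vector of length 3.
#' @param group a \linkS4class{SymmetryGroup}.
#' @return integer matrix of the distinct equivalent reflections (one row
#'   each), ordered decreasingly; the first row is the canonical
#'   representative.
#' @export
equivalentReflections <- function(hkl, group) {
  stopifnot(length(hkl) == 3)
  imgs <- t(vapply(group@ops, function(m) as.integer(m %*% hkl),
                   integer(3)))
  imgs <- unique(imgs)
  ord <- order(imgs[, 1], imgs[, 2], imgs[, 3], decreasing = TRUE)
  imgs[ord, , drop = FALSE]
}

#' Canonical asymmetric-unit representatives
#'
#' Maps each reflection to the lexicographically greatest member of its orbit
#' (a fixed total ordering on (h,k,l)), so canonical(canonical(x)) ==
#' canonical(x).
#'
#' @param hkl n x 3 integer matrix (or length-3 vector).
#' @param group a \linkS4class{SymmetryGroup}.
#' @return matrix (or vector) of the same shape with canonical indices.
#' @export
canonicalReflections <- function(hkl, group) {
  vec <- !is.matrix(hkl)
  if (vec) hkl <- matrix(as.integer(hkl), 1, 3)
  storage.mode(hkl) <- "integer"
  out <- cpp_canonical(hkl, opsStack(group))
  if (vec) out[1, ] else out
}

# encode hkl rows as a single integer key for grouping/joins
KEY_OFF <- 512L
hklKey <- function(h, k, l) {
  (as.double(h) + KEY_OFF) * (2 * KEY_OFF)^2 +
    (as.double(k) + KEY_OFF) * (2 * KEY_OFF) + (as.double(l) + KEY_OFF)
}

canonicalKeys <- function(hkl, group) {
  can <- canonicalReflections(hkl, group)
  hklKey(can[, 1], can[, 2], can[, 3])
}
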