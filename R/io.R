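# Text formats: HKL intensity tables and a stream-like per-pattern format
# (header with the nine basis components and the scale factor, one line per
# reflection), plus a YAML geometry/config reader.

#' Write an intensity table as whitespace-separated HKL text
#'
#' Columns h k l I [sigma nmeas], intensities printed as \code{%.4e}, with a
#' one-line header. Works for reference tables (h k l I) and merged tables
#' (h k l I sigma nmeas).
#'
#' @param table data.frame with columns h, k, l, I and optionally sigma, n.
#' @param path output file path.
#' @export
writeHKL <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (all(c("sigma", "n") %in% names(table))) {
    writeLines("  h   k   l            I        sigma  nmeas", con)
    writeLines(sprintf("%4d %4d %4d %12.4e %12.4e %6d",
                       table$h, table$k, table$l, table$I, table$sigma,
                       table$n), con)
  } else {
    writeLines("  h   k   l            I", con)
    writeLines(sprintf("%4d %4d %4d %12.4e", table$h, table$k, table$l,
                       table$I), con)
  }
  invisible(path)
}

parseNumTokens <- function(tokens, lineNo, what) {
  v <- suppressWarnings(as.numeric(tokens))
  if (anyNA(v))
    stop(sprintf("malformed %s on line %d: '%s'", what, lineNo,
                 paste(tokens, collapse = " ")))
  v
}

#' Read an HKL intensity table
#'
#' @param path file written by \code{\link{writeHKL}}.
#' @return data.frame with columns h, k, l, I and, if present in the file,
#'   sigma and n.
#' @export
readHKL <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty HKL file")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(seq_along(body), function(i) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    v <- parseNumTokens(tok, i + 1, "HKL record")
    if (any(v[1:3] != round(v[1:3])))
      stop(sprintf("non-integer Miller index on line %d", i + 1))
    v
  })
  m <- do.call(rbind, rows)
  out <- data.frame(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                    l = as.integer(m[, 3]), I = m[, 4])
  if (ncol(m) >= 6) {
    out$sigma <- m[, 5]
    out$n <- as.integer(m[, 6])
  }
  out
}

#' Write patterns in a stream-like text format
#'
#' Each pattern is a block delimited by begin/end markers, with the nine
#' Cartesian reciprocal-basis components (nm^-1, \code{%.8e}) and the scale
#' factor in the header, then one line per reflection:
#' \code{h k l I sigma p L} (intensities \code{%.4e}).
#'
#' @param patterns list of \linkS4class{SnapshotPattern} or a
#'   \linkS4class{SnapshotDataset}.
#' @param path output file path.
#' @param scales optional named scale factors to write as G (default: the
#'   pattern's generating scale, or 1).
#' @export
writePatternStream <- function(patterns, path, scales = NULL) {
  if (is(patterns, "SnapshotDataset")) patterns <- patterns@patterns
  con <- file(path, "w")
  on.exit(close(con))
  for (pat in patterns) {
    G <- if (!is.null(scales)) scales[[as.character(pat@id)]]
         else if (length(pat@trueScale) && is.finite(pat@trueScale))
           pat@trueScale else 1
    writeLines(sprintf("----- begin pattern %d", pat@id), con)
    writeLines(paste("basis", paste(sprintf("%.8e", as.vector(pat@basis)),
                                    collapse = " ")), con)
    writeLines(sprintf("scale %.6e", G), con)
    o <- pat@obs
    writeLines(sprintf("%4d %4d %4d %12.4e %12.4e %.6e %.6e",
                       o$h, o$k, o$l, o$iobs, o$sigma, o$p, o$L), con)
    writeLines("----- end pattern", con)
  }
  invisible(path)
}

#' Read a stream-like pattern file
#'
#' @param path file written by \code{\link{writePatternStream}}.
#' @param symmetry optional \linkS4class{SymmetryGroup} used to recompute
#'   canonical merging keys (default: identity-only keys).
#' @return list of \linkS4class{SnapshotPattern}; the scale read from each
#'   header is stored in \code{trueScale}.
#' @export
readPatternStream <- function(path, symmetry = NULL) {
  lines <- readLines(path)
  patterns <- list()
  i <- 1
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (!nzchar(line)) { i <- i + 1; next }
    m <- regmatches(line, regexec("^-+ begin pattern (\\d+)$", line))[[1]]
    if (length(m) == 0)
      stop(sprintf("expected 'begin pattern' marker on line %d", i))
    id <- as.integer(m[2])
    i <- i + 1
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (tok[1] != "basis" || length(tok) != 10)
      stop(sprintf("expected 'basis' header on line %d", i))
    basis <- matrix(parseNumTokens(tok[-1], i, "basis"), 3, 3)
    i <- i + 1
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (tok[1] != "scale" || length(tok) != 2)
      stop(sprintf("expected 'scale' header on line %d", i))
    G <- parseNumTokens(tok[2], i, "scale")
    i <- i + 1
    rows <- list()
    while (i <= n && !grepl("^-+ end pattern$", trimws(lines[i]))) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      v <- parseNumTokens(tok, i, "reflection record")
      if (length(v) != 7)
        stop(sprintf("expected 7 fields on line %d", i))
      if (any(v[1:3] != round(v[1:3])))
        stop(sprintf("non-integer Miller index on line %d", i))
      rows[[length(rows) + 1]] <- v
      i <- i + 1
    }
    if (i > n) stop("missing 'end pattern' marker at end of file")
    i <- i + 1
    m <- if (length(rows)) do.call(rbind, rows) else
      matrix(numeric(0), 0, 7)
    hkl <- matrix(as.integer(m[, 1:3]), ncol = 3)
    key <- if (!is.null(symmetry) && nrow(hkl))
      canonicalKeys(hkl, symmetry) else hklKey(hkl[, 1], hkl[, 2], hkl[, 3])
    obs <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                      key = if (nrow(hkl)) key else numeric(0),
                      refIdx = rep(NA_integer_, nrow(hkl)),
                      d = resolutionOf(hkl, basis),
                      iobs = m[, 4], sigma = m[, 5], p = m[, 6], L = m[, 7])
    patterns[[length(patterns) + 1]] <-
      new("SnapshotPattern", id = id, basis = basis,
          trueBasis = matrix(NA_real_, 3, 3), trueScale = G, obs = obs)
  }
  patterns
}

#' Read a geometry/model configuration from YAML
#'
#' Recognized keys: \code{cell_a_rh}, \code{cell_alpha_rh},
#' \code{cell_setting}, \code{symmetry} (a \code{\link{laueGroup}} label or a
#' list of 3x3 operator rows), \code{photon_energy_keV},
#' \code{bandwidth_frac}, \code{convergence_rad}, \code{detector_side_mm},
#' \code{detector_distance_mm}, \code{sphere_radius_nm1} and the simulator
#' fields of \code{\link{simulationConfig}} (\code{n_patterns},
#' \code{basis_error_max_frac}, \code{scale_mean}, \code{scale_sd},
#' \code{wilson_B}, \code{mean_intensity}, \code{noise_sd}, \code{seed}).
#'
#' @param path YAML file path.
#' @return a \code{\link{simulationConfig}}.
#' @export
readGeometryConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(key, default) if (!is.null(y[[key]])) y[[key]] else default
  cell <- unitCell(pick("cell_a_rh", 144.2), pick("cell_alpha_rh", 113.78),
                   setting = pick("cell_setting", "rhombohedral"))
  sym <- y[["symmetry"]]
  symmetry <- if (is.null(sym)) laueGroup("-3m_R")
    else if (is.character(sym)) laueGroup(sym)
    else symmetryGroup(lapply(sym, function(m)
      matrix(as.integer(unlist(m)), 3, 3, byrow = TRUE)))
  simulationConfig(
    nPatterns = pick("n_patterns", 1000),
    cell = cell, symmetry = symmetry,
    beam = beamModel(pick("photon_energy_keV", 8),
                     pick("bandwidth_frac", 5e-4),
                     pick("convergence_rad", 1e-3)),
    detector = detectorModel(pick("detector_side_mm", 76.8),
                             pick("detector_distance_mm", 50)),
    sphereRadius = pick("sphere_radius_nm1", 5e-3),
    basisErrorMax = pick("basis_error_max_frac", 0.001),
    scaleMean = pick("scale_mean", 1), scaleSD = pick("scale_sd", 0.3),
    wilsonB = pick("wilson_B", 25),
    meanIntensity = pick("mean_intensity", 1000),
    noiseSD = y[["noise_sd"]],
    seed = pick("seed", 1))
}
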