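test_that("reference table enumerates exactly the unique hkl above d_min", {
  cell <- toyCell()
  group <- laueGroup("-3m_R")
  dMin <- 4   # few reflections
  set.seed(31)
  ref <- generateReferenceIntensities(cell, group, dMin)
  # exhaustive index-enumeration oracle
  B0 <- reciprocalBasis(cell)
  grid <- as.matrix(expand.grid(h = -4:4, k = -4:4, l = -4:4))
  grid <- grid[rowSums(abs(grid)) > 0, ]
  d <- resolutionOf(grid, B0)
  inRange <- grid[d >= dMin, , drop = FALSE]
  can <- unique(canonicalReflections(inRange, group))
  expect_equal(nrow(ref), nrow(can))
  expect_true(all(ref$I >= 0))
  # determinism under seed
  set.seed(31)
  ref2 <- generateReferenceIntensities(cell, group, dMin)
  expect_identical(ref, ref2)
})

test_that("zero Wilson B gives resolution-independent mean intensities", {
  set.seed(32)
  ref <- generateReferenceIntensities(toyCell(), laueGroup("-3m_R"), 2,
                                      wilsonB = 0, meanIntensity = 100)
  lowRes <- ref$I[ref$d >= stats::median(ref$d)]
  highRes <- ref$I[ref$d < stats::median(ref$d)]
  # exponential means agree within sampling error (se ~ mean/sqrt(n))
  se <- 100 * sqrt(1 / length(lowRes) + 1 / length(highRes))
  expect_lt(abs(mean(lowRes) - mean(highRes)), 4 * se)
})

test_that("basis perturbation is bounded, flat and seed-stable", {
  B <- reciprocalBasis(unitCell(144.2, 113.78))
  set.seed(33)
  expect_identical(perturbBasis(B, 0), B)
  mf <- 0.001
  nz <- B != 0   # zero components stay zero; the bound is per nonzero one
  draws <- replicate(200, ((perturbBasis(B, mf) - B) / B)[nz])
  expect_true(all(abs(draws) <= mf * (1 + 1e-9)))   # roundoff headroom
  # flat-top distribution: Kolmogorov-Smirnov against the uniform
  u <- as.vector(replicate(200, ((perturbBasis(B, mf) - B) / B)[nz]))
  ks <- suppressWarnings(stats::ks.test(u, "punif", -mf, mf))
  expect_gt(ks$p.value, 0.01)
})

test_that("reflection prediction matches an exhaustive brute-force scan", {
  cell <- toyCell()
  beam <- beamModel(8, 0.02, 2e-3)
  det <- detectorModel(76.8, 50)
  r <- 5e-3
  set.seed(34)
  B <- randomOrientation() %*% reciprocalBasis(cell)
  pred <- predictReflections(B, beam, det, r, cellForCandidates = cell)
  expect_false(any(pred$h == 0 & pred$k == 0 & pred$l == 0))

  # independent scan over all indices to the corner resolution
  dCorner <- detectorResolutionLimits(det, beam@wavelength)[["corner"]]
  grid <- as.matrix(expand.grid(h = -6:6, k = -6:6, l = -6:6))
  grid <- grid[rowSums(abs(grid)) > 0, ]
  d <- resolutionOf(grid, reciprocalBasis(cell))
  grid <- grid[d >= dCorner, , drop = FALSE]
  keep <- logical(nrow(grid))
  lamNM <- beam@wavelength / 10
  for (i in seq_len(nrow(grid))) {
    s <- as.numeric(B %*% grid[i, ])
    ex <- sweepExtremes(s, beam, nGrid = 2)   # corners of the nest
    if (!(ex[1] < r && ex[2] > -r)) next
    koz <- s[3] + 1 / lamNM
    if (koz <= 0) next
    px <- det@distance * s[1] / koz
    py <- det@distance * s[2] / koz
    keep[i] <- abs(px) <= det@side / 2 && abs(py) <= det@side / 2
  }
  oracle <- grid[keep, , drop = FALSE]
  ours <- as.matrix(pred[, c("h", "k", "l")])
  okey <- snapref:::hklKey(oracle[, 1], oracle[, 2], oracle[, 3])
  pkey <- snapref:::hklKey(ours[, 1], ours[, 2], ours[, 3])
  expect_setequal(pkey, okey)

  # degenerate detector predicts nothing; wider bandwidth predicts a superset
  tiny <- predictReflections(B, beam, detectorModel(1e-9, 50), r,
                             cellForCandidates = cell)
  expect_equal(nrow(tiny), 0)
  narrow <- predictReflections(B, beamModel(8, 0.005, 2e-3), det, r,
                               cellForCandidates = cell)
  nkey <- snapref:::hklKey(narrow$h, narrow$k, narrow$l)
  expect_true(all(nkey %in% pkey))
})

test_that("noiseless patterns reproduce the generating intensity chain", {
  cfg <- toyConfig(nPatterns = 5, noiseSD = 0, basisErrorMax = 0)
  ds <- simulateDataset(cfg)
  for (pat in patterns(ds)) {
    obs <- observations(pat)
    Ifull <- referenceIntensities(ds)$I[obs$refIdx]
    ratio <- obs$iobs / (obs$pTrue * obs$LTrue * Ifull)
    ok <- is.finite(ratio) & obs$pTrue > 0
    # scale recovery: I/(p L I_full) = G for every reflection
    expect_equal(ratio[ok], rep(pat@trueScale, sum(ok)), tolerance = 1e-12)
    # unperturbed working basis: stored model p equals generating p
    expect_equal(obs$p, obs$pTrue, tolerance = 1e-12)
  }
})

test_that("datasets are deterministic under seed and stable across seeds", {
  cfg <- toyConfig(nPatterns = 8, noiseSD = 1, basisErrorMax = 0.001,
                   seed = 35)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(observations(d1), observations(d2))
  expect_identical(referenceIntensities(d1), referenceIntensities(d2))
  # empty dataset is valid and retains a truth record
  d0 <- simulateDataset(toyConfig(nPatterns = 0))
  expect_length(patterns(d0), 0)
  expect_true(is.numeric(d0@truth$sigmaNoise))
  # dataset mean partiality is stable across seeds
  means <- vapply(36:38, function(s)
    partialityStatistics(simulateDataset(referenceConfig(40, seed = s)))[["mean"]],
    0)
  expect_lt(stats::sd(means), 0.01)
})

test_that("reference-condition shell profile peaks at the detector edge", {
  ds <- sharedDataset01()
  st <- shellStatistics(ds, 10)
  peak <- which.max(st$n)
  dEdge <- detectorResolutionLimits(ds@detector, ds@beam@wavelength)[["edge"]]
  # the most populated shell ends essentially at the edge resolution,
  # and counts fall steeply into the corner region
  expect_lt(abs(st$dMin[peak] - dEdge), 0.05)
  expect_lt(st$n[10], st$n[peak] / 2)
  # mean partiality rises with resolution
  expect_true(all(diff(st$meanP) > 0))
})

test_that("re-perturbing a dataset keeps observations but moves the model", {
  ds <- sharedDataset01()
  ds10 <- sharedDataset10()
  o1 <- observations(patterns(ds)[[1]])
  o2 <- observations(patterns(ds10)[[1]])
  expect_identical(o1$iobs, o2$iobs)
  expect_identical(o1$pTrue, o2$pTrue)
  expect_false(identical(o1$p, o2$p))
  relerr <- abs(patterns(ds10)[[1]]@basis / patterns(ds10)[[1]]@trueBasis - 1)
  expect_true(all(relerr <= 0.01 + 1e-12))
})
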