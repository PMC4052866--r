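test_that("cap fraction matches closed values and volume oracles", {
  r <- 5e-3
  expect_equal(capFraction(-r, r), 1)
  expect_equal(capFraction(0, r), 0.5)
  expect_equal(capFraction(r, r), 0)
  expect_error(capFraction(1.5 * r, r), "outside")
  # monotone decreasing
  ts <- seq(-r, r, length.out = 41)
  expect_true(all(diff(capFraction(ts, r)) < 0))
  # quadrature oracle at random offsets
  set.seed(21)
  for (t in runif(20, -r, r))
    expect_equal(capFraction(t, r), slabFractionQuad(t, r, r),
                 tolerance = 1e-8)
  # Monte-Carlo volume oracle at t = r/2
  set.seed(22)
  n <- 4e5
  pts <- matrix(runif(3 * n, -r, r), ncol = 3)
  inside <- rowSums(pts^2) <= r^2
  frac <- sum(inside & pts[, 1] >= r / 2) / sum(inside)
  tol <- 3 * sqrt(frac * (1 - frac) / sum(inside))
  expect_lt(abs(capFraction(r / 2, r) - frac), tol)
})

test_that("excitation distances have the documented signs and extremes", {
  beam0 <- beamModel(8, 0, 0)          # monochromatic, collimated
  lamNM <- beam0@wavelength / 10
  onSphere <- function(twoTheta)
    c(sin(twoTheta), 0, cos(twoTheta) - 1) / lamNM
  g <- excitationDistances(onSphere(0.5), beam0)
  expect_equal(g$rHigh, 0, tolerance = 1e-12)
  expect_equal(g$rLow, 0, tolerance = 1e-12)

  beam <- beamModel(8, 5e-4, 0)        # bandwidth only: slab straddles
  g <- excitationDistances(onSphere(0.5), beam)
  expect_lt(g$rHigh, 0)
  expect_gt(g$rLow, 0)
  expect_error(excitationDistances(c(0, 0, 0), beam), "zero-length")

  # dense (lambda, tilt) sweep oracle: extremes within 1% of the thickness
  beam <- beamModel(8, 5e-4, 1e-3)
  set.seed(23)
  for (i in 1:10) {
    tt <- runif(1, 0.1, 0.8)
    s <- onSphere(tt) + rnorm(3, 0, 1e-3)
    ours <- excitationDistances(s, beam)
    oracle <- sweepExtremes(s, beam)
    thick <- oracle[2] - oracle[1]
    expect_lt(abs(ours$rHigh - oracle[1]), 0.01 * thick)
    expect_lt(abs(ours$rLow - oracle[2]), 0.01 * thick)
  }
})

test_that("clamping bounds distances and flags replacements", {
  r <- 5e-3
  g <- data.frame(rHigh = c(-2 * r, -0.2 * r, -2 * r),
                  rLow = c(-1.5 * r, 0.3 * r, 2 * r))
  cl <- clampDistances(g, r)
  expect_equal(cl$rHigh, c(-r, -0.2 * r, -r))
  expect_equal(cl$rLow, c(-r, 0.3 * r, r))
  expect_equal(cl$clampedHigh, c(TRUE, FALSE, TRUE))
  expect_equal(cl$clampedLow, c(TRUE, FALSE, TRUE))
  # slab containing the whole sphere: fully recorded
  expect_equal(partialityFromDistances(-2 * r, 2 * r, r), 1)
  # zero-thickness slab
  expect_equal(partialityFromDistances(0.2 * r, 0.2 * r, r), 0)
})

test_that("partiality equals the slab-volume fraction of the sphere", {
  r <- 5e-3
  set.seed(24)
  # 1000 random geometries against the quadrature volume oracle
  rh <- runif(1000, -2 * r, 2 * r)
  rl <- rh + runif(1000, 0, 2 * r)
  p <- partialityFromDistances(rh, rl, r)
  expect_true(all(p >= 0 & p <= 1))
  for (i in seq_len(1000))
    expect_lt(abs(p[i] - slabFractionQuad(rh[i], rl[i], r)), 1e-3)
  # Monte-Carlo slab-volume cross-check on a subset
  set.seed(25)
  pts <- matrix(runif(3 * 4e5, -r, r), ncol = 3)
  pts <- pts[rowSums(pts^2) <= r^2, ]
  for (i in sample.int(1000, 20)) {
    mc <- mean(pts[, 1] >= rh[i] & pts[, 1] <= rl[i])
    tol <- max(1e-3, 3 * sqrt(mc * (1 - mc) / nrow(pts)))
    expect_lt(abs(p[i] - mc), tol)
  }
})

test_that("partiality is continuous across the clamping boundary", {
  r <- 5e-3
  rl <- 0.7 * r
  eps <- 1e-10 * r
  below <- partialityFromDistances(-r - eps, rl, r)
  above <- partialityFromDistances(-r + eps, rl, r)
  expect_lt(abs(below - above), 1e-6)
})

test_that("Lorentz factor is inverse-proportional to slab thickness", {
  kL <- 4.6e-3
  expect_equal(lorentzFactor(-1e-3, 1e-3, kL),
               2 * lorentzFactor(-2e-3, 2e-3, kL))
  # equal thickness, different partiality: same L
  expect_equal(lorentzFactor(-4e-3, -2e-3, kL), lorentzFactor(0, 2e-3, kL))
  expect_true(is.na(lorentzFactor(1e-3, 1e-3, kL)))
  # normalization: L = 1 at the detector-edge nest thickness
  beam <- beamModel(); det <- detectorModel()
  kL <- lorentzNormalization(beam, det)
  dEdge <- detectorResolutionLimits(det, beam@wavelength)[["edge"]]
  lamNM <- beam@wavelength / 10
  tt <- 2 * asin(beam@wavelength / (2 * dEdge))
  s <- c(sin(tt), 0, cos(tt) - 1) / lamNM
  oracle <- sweepExtremes(s, beam)
  expect_equal(kL, oracle[2] - oracle[1], tolerance = 1e-4)
  g <- excitationDistances(s, beam)
  expect_equal(lorentzFactor(g$rHigh, g$rLow, kL), 1, tolerance = 1e-12)
})

test_that("thin central slabs give thickness-independent partial intensity", {
  # the p*L compensation: for slabs through the sphere centre,
  # p(t) * L(t) = (3 kL / 4r) (1 - t^2/(12 r^2)) -> constant as t -> 0
  r <- 5e-3
  kL <- 1
  pl <- function(t) partialityFromDistances(-t / 2, t / 2, r) *
    lorentzFactor(-t / 2, t / 2, kL)
  expect_equal(pl(1e-4 * r), pl(2e-5 * r), tolerance = 1e-9)
  expect_equal(pl(1e-5 * r), 3 * kL / (4 * r), tolerance = 1e-9)
  # a fully recorded reflection (slab just containing the sphere) appears
  # with comparable intensity: ratio 3T/(4r) = 3/2 at T = 2r
  plFull <- 1 * (kL / (2 * r))
  expect_equal(pl(1e-5 * r) / plFull, 1.5, tolerance = 1e-6)
})

test_that("analytic gradients match central finite differences", {
  cell <- unitCell(144.2, 113.78)
  beam <- beamModel()
  det <- detectorModel()
  r <- 5e-3
  set.seed(26)
  B <- randomOrientation() %*% reciprocalBasis(cell)
  pred <- predictReflections(B, beam, det, r, cellForCandidates = cell)
  # central differences are only meaningful away from clamp boundaries and
  # nest-corner switches, where the model is genuinely one-sided
  safe <- fdSafeRows(pred, B, beam, r)
  sub <- pred[safe, ][sample(length(safe), 100), ]
  hkl <- as.matrix(sub[, c("h", "k", "l")])
  storage.mode(hkl) <- "integer"
  gA <- partialityGradient(hkl, B, beam, r)
  worst <- 0
  for (i in seq_len(nrow(hkl)))
    for (q in 1:9)
      worst <- max(worst, fdRelError(hkl[i, , drop = FALSE], B, beam, r, q,
                                     gA[i, q]))
  expect_lt(worst, 1e-5)
})

test_that("clamped and index-zero gradient components vanish exactly", {
  # wide-bandwidth beam, tiny sphere: reflection fully recorded with margin
  beam <- beamModel(8, 0.05, 0)
  lamNM <- beam@wavelength / 10
  tt <- 0.6
  s <- c(sin(tt), 0, cos(tt) - 1) / lamNM
  B <- cbind(s, c(0, 1, 0), c(0, 0, 1))
  r <- 1e-5
  res <- reflectionPartiality(c(1, 0, 0), B, beam, r, gradients = TRUE)
  expect_equal(res$p, 1)
  expect_lt(res$rHigh, -r)
  expect_gt(res$rLow, r)
  expect_equal(as.vector(attr(res, "gradient")), rep(0, 9))

  # h = 0: all three a*-component gradients are exactly zero
  cell <- unitCell(144.2, 113.78)
  beamRef <- beamModel()
  set.seed(27)
  Brand <- randomOrientation() %*% reciprocalBasis(cell)
  pred <- predictReflections(Brand, beamRef, detectorModel(), 5e-3,
                             cellForCandidates = cell)
  zh <- pred[pred$h == 0, ][1, ]
  g <- partialityGradient(as.matrix(zh[, c("h", "k", "l")]), Brand,
                          beamRef, 5e-3)
  expect_equal(as.vector(g[1, 1:3]), c(0, 0, 0))
})
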