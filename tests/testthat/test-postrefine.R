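test_that("intensity residuals vanish at the generating model", {
  cfg <- toyConfig(nPatterns = 3, noiseSD = 0, basisErrorMax = 0)
  ds <- simulateDataset(cfg)
  pat <- patterns(ds)[[1]]
  obs <- observations(pat)
  Ifull <- referenceIntensities(ds)$I[obs$refIdx]
  dI <- residualIntensity(obs$iobs, obs$p, obs$L, pat@trueScale, Ifull)
  expect_equal(dI, rep(0, length(dI)), tolerance = 1e-9)
  # p = 0: the residual is the scaled observed intensity
  expect_equal(residualIntensity(6, 0, 2, 3, 100), 1)
})

test_that("the refinable selection applies each rejection rule", {
  g <- laueGroup("1")
  # five observations crossing each rule exactly once
  pat <- makePattern(1, h = 1:5, k = 0, l = 0,
                     iobs = c(10, 2, 10, 10, 10),   # obs 2 fails I >= 3 sigma
                     p = c(0.5, 0.5, 0.05, 0.5, 0.5),  # obs 3 fails p >= 0.1
                     L = 1, sigma = 1, group = g)
  merged <- data.frame(key = snapref:::hklKey(c(1, 2, 3, 5), 0, 0),
                       I = c(10, 10, 10, 10))       # obs 4 has no estimate
  # multiplicity: hkl 5 is seen only once in the whole dataset
  mult <- data.frame(key = snapref:::hklKey(1:5, 0, 0),
                     count = c(2L, 2L, 2L, 2L, 1L))
  sel <- selectRefinable(pat, merged, mult, pMin = 0.1, snr = 3)
  expect_equal(sel, 1L)
})

test_that("normal equations have outer-product structure and FD-exact terms", {
  ds <- sharedDataset01()
  pat <- patterns(ds)[[1]]
  merged <- referenceIntensities(ds)
  mult <- multiplicityIndex(ds)
  sel <- selectRefinable(pat, merged, mult)
  # single observation: rank-1 outer product of its gradient row
  ne1 <- buildNormalEquations(pat, sel[1], merged, 1, ds@beam,
                              ds@sphereRadius, ds@lorentzNorm)
  expect_equal(ne1$A, crossprod(ne1$J), tolerance = 1e-12)
  expect_equal(qr(ne1$A)$rank, 1)

  # J^T J from ~20 observations matches a numerically differentiated J
  sub <- sel[1:20]
  ne <- buildNormalEquations(pat, sub, merged, 1, ds@beam,
                             ds@sphereRadius, ds@lorentzNorm)
  obs <- observations(pat)[sub, ]
  Iref <- merged$I[match(obs$key, merged$key)]
  hkl <- as.matrix(obs[, c("h", "k", "l")])
  storage.mode(hkl) <- "integer"
  Jnum <- matrix(0, nrow(hkl), 9)
  for (i in seq_len(nrow(hkl)))
    for (q in 1:9)
      Jnum[i, q] <- -Iref[i] *
        fdPartialityGradient(hkl[i, , drop = FALSE], pat@basis, ds@beam,
                             ds@sphereRadius, q)
  Anum <- crossprod(Jnum)
  scale <- max(abs(Anum))
  expect_lt(max(abs(ne$A - Anum)) / scale, 1e-5)
})

test_that("rescaled SVD solves match direct solvers and handle rank loss", {
  # identity system
  sol <- solveRescaledSVD(diag(9), c(1, rep(0, 8)))
  expect_equal(sol$step, c(1, rep(0, 8)))
  expect_equal(sol$eliminated, 0)
  # random SPD system: matches solve()
  set.seed(51)
  M <- matrix(rnorm(81), 9, 9)
  A <- crossprod(M) + diag(9)
  b <- rnorm(9)
  sol <- solveRescaledSVD(A, b)
  expect_equal(sol$step, solve(A, b), tolerance = 1e-8)
  # all-zero matrix: zero step, everything eliminated
  sol0 <- solveRescaledSVD(matrix(0, 9, 9), rep(1, 9))
  expect_equal(sol0$step, rep(0, 9))
  expect_equal(sol0$eliminated, 9)
  # known null space: no step component along it in the rescaled
  # coordinates where the SVD elimination is defined
  v <- rep(1, 9) / 3
  P <- diag(9) - outer(v, v)
  Adef <- P %*% A %*% P
  sdef <- solveRescaledSVD(Adef, as.vector(P %*% b))
  Dm <- 1 / sqrt(diag(Adef))
  null_rescaled <- (v / Dm) / sqrt(sum((v / Dm)^2))
  step_rescaled <- sdef$step / Dm
  expect_lt(abs(sum(step_rescaled * null_rescaled)),
            1e-10 * sqrt(sum(step_rescaled^2)))
  expect_gte(sdef$eliminated, 1)
})

test_that("refinement converges immediately at the true geometry", {
  cfg <- toyConfig(nPatterns = 8, noiseSD = 0, basisErrorMax = 0,
                   seed = 52)
  ds <- simulateDataset(cfg)
  merged <- referenceIntensities(ds)
  mult <- multiplicityIndex(ds)
  pat <- patterns(ds)[[2]]
  rp <- refinePattern(pat, merged, pat@trueScale, ds@beam,
                      ds@sphereRadius, ds@lorentzNorm, mult)
  if (rp$result$reason != "skipped") {
    expect_equal(rp$result$iterations, 1)
    expect_lt(rp$result$maxDeltaP, 0.01)
    expect_equal(rp$pattern@basis, pat@basis, tolerance = 1e-6)
  }
  expect_true(rp$result$reason %in% c("converged", "skipped"))
})

test_that("a step that extinguishes most reflections is reverted", {
  ds <- sharedDataset01()
  pat <- patterns(ds)[[3]]
  mult <- multiplicityIndex(ds)
  # grossly inflated reference intensities make the observed partialities
  # near zero, so the first Gauss-Newton step drives p towards zero
  merged <- referenceIntensities(ds)
  merged$I <- merged$I * 1e6
  rp <- refinePattern(pat, merged, 1, ds@beam, ds@sphereRadius,
                      ds@lorentzNorm, mult)
  expect_true(rp$result$reverted)
  expect_identical(rp$result$reason, "reverted")
  # the fatal step was undone: the stored basis does not extinguish more
  # than a third of the selected reflections
  sel <- selectRefinable(pat, merged, mult)
  cur <- reflectionPartiality(
    as.matrix(observations(pat)[sel, c("h", "k", "l")]),
    rp$pattern@basis, ds@beam, ds@sphereRadius, ds@lorentzNorm)
  expect_lte(mean(cur$p == 0), 1 / 3)
  # if the very first step was fatal, the basis is untouched
  if (rp$result$iterations == 1)
    expect_equal(rp$pattern@basis, pat@basis)
})

test_that("the objective is larger away from the generating geometry", {
  ds <- sharedDataset01()
  ref <- referenceIntensities(ds)
  better <- 0
  pats <- patterns(ds)[1:50]
  for (pat in pats) {
    obs <- observations(pat)
    Iref <- ref$I[obs$refIdx]
    ok <- is.finite(Iref) & is.finite(obs$L) & obs$L > 0
    atWork <- sum(residualIntensity(obs$iobs[ok], obs$p[ok], obs$L[ok],
                                    pat@trueScale, Iref[ok])^2)
    exTrue <- reflectionPartiality(
      as.matrix(obs[ok, c("h", "k", "l")]), pat@trueBasis, ds@beam,
      ds@sphereRadius, ds@lorentzNorm)
    atTrue <- sum(residualIntensity(obs$iobs[ok], exTrue$p, exTrue$L,
                                    pat@trueScale, Iref[ok])^2)
    if (atWork > atTrue) better <- better + 1
  }
  expect_gte(better / length(pats), 0.95)
})

test_that("refinement improves the partiality estimates of most patterns", {
  # the refined geometry is judged by what it is used for: the partiality
  # assignments (the objective constrains reflection offsets along the
  # excitation slab, not every parameter-space direction)
  run <- sharedRun01()
  ds0 <- sharedDataset01()
  refined <- run@dataset
  perr <- function(p) mean(abs(observations(p)$p - observations(p)$pTrue))
  before <- vapply(patterns(ds0), perr, 0)
  after <- vapply(patterns(refined), perr, 0)
  expect_lt(mean(after), mean(before))
  expect_gt(mean(after < before), 0.5)
  rs <- refinementSummary(run, 1)
  expect_gt(mean(rs$reason %in% c("converged", "max_iterations")), 0.8)
})

test_that("zero cycles reproduce the plain scaling-and-merging result", {
  ds <- sharedDataset01()
  run0 <- runCycles(ds, nCycles = 0)
  sm <- kabschScaleMerge(ds, rounds = 3)
  expect_equal(mergedTable(run0, 0), sm$merged)
  expect_equal(scaleFactors(run0, 0), sm$scales)
  expect_length(run0@rHistory, 1)
})
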