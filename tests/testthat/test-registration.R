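regFixture <- function() fixture("regFixture", function() {
  ref <- generateHead(1, phantomParams(scale = 0.5), spacing = 0.5)
  list(ref = ref, pts = cranialPoints(ref))
})

test_that("identity configurations fit with zero registration error", {
  fx <- regFixture()
  fit <- affineFit(fx$pts, fx$pts)
  expect_lt(fit$report$RE, 1e-18)
  expect_equal(fit$transform, cbind(diag(3), 0), tolerance = 1e-9)
  expect_identical(fit$report$RE,
                   fit$report$SRE + 0.45 * fit$report$LRE1 +
                     0.55 * fit$report$LRE2)
})

test_that("a known affine transform is recovered exactly", {
  fx <- regFixture()
  A <- matrix(c(1.05, 0.02, 0, -0.03, 0.97, 0.01, 0, 0.02, 1.1), 3,
              byrow = TRUE)
  Tm <- cbind(A, c(2, -1, 3))
  subj <- new("CranialPointSet",
              surface = applyTransform(surfacePoints(fx$pts), Tm),
              landmarks = applyTransform(landmarkPoints(fx$pts), Tm))
  rownames(subj@landmarks) <- rownames(landmarkPoints(fx$pts))
  fit <- affineFit(subj, fx$pts)
  err <- max(abs(applyTransform(allPoints(subj), fit$transform) -
                   allPoints(fx$pts)))
  expect_lt(err, 1e-9)
  expect_lt(fit$report$RE, 1e-12) # mm^2
  # RE after the fit never exceeds the Nz-matched identity configuration
  expect_lte(fit$report$RE, fit$report$RE0)
  # reflections are rejected
  refl <- cbind(diag(c(-1, 1, 1)), 0)
  subjR <- new("CranialPointSet",
               surface = applyTransform(surfacePoints(fx$pts), refl),
               landmarks = applyTransform(landmarkPoints(fx$pts), refl))
  rownames(subjR@landmarks) <- rownames(landmarkPoints(fx$pts))
  expect_error(affineFit(subjR, fx$pts), "orientation")
})

test_that("raising gamma1 tightens the Iz/Nz landmarks in a conflicted fit", {
  fx <- regFixture()
  # conflict: displace Iz so the surface term and the landmark term pull
  # in different directions
  subj <- fx$pts
  lm <- landmarkPoints(subj)
  lm["Iz", ] <- lm["Iz", ] + c(0, -4, 2)
  subj@landmarks <- lm
  f1 <- affineFit(subj, fx$pts, gamma1 = 0.45, gamma2 = 0.55)
  f2 <- affineFit(subj, fx$pts, gamma1 = 0.9, gamma2 = 0.55)
  expect_lt(f2$report$LRE1, f1$report$LRE1)
})

test_that("probe-region scaling recovers synthetic anisotropic stretch", {
  fx <- regFixture()
  pts <- surfacePoints(fx$pts)
  stretched <- sweep(pts, 2, c(1.1, 0.9, 1.0), `*`)
  sc <- probeRegionScaling(stretched, pts, probeCentre = c(-20, 0, 10),
                           radius = 30, centre = c(0, 0, 0))
  expect_equal(sc$scales, c(1 / 1.1, 1 / 0.9, 1), tolerance = 0.02)
  expect_lte(sc$rmseAfter, sc$rmseBefore)
  expect_error(probeRegionScaling(stretched, pts, c(1e5, 0, 0), 1,
                                  c(0, 0, 0)), "probe region")
  # already coincident surfaces give unit scales
  sc0 <- probeRegionScaling(pts, pts, c(-20, 0, 10), 30, c(0, 0, 0))
  expect_equal(sc0$scales, c(1, 1, 1), tolerance = 1e-9)
})

test_that("shell filling is the identity for a perfectly matched subject", {
  fx <- regFixture()
  lay <- placeProbe(fx$ref, probeTemplate("desk", pitch = 8),
                    direction = c(-1, 0, 0.4))
  pm <- probeRegionMask(fx$ref, lay, radius = 25)
  fill <- fillReferenceShell(fx$ref, fx$ref, shellThickness = 1.5,
                             probeMask = pm, csfTolerance = 10)
  expect_true(fill$accepted)
  expect_identical(fill$failedRule, 0L)
  expect_identical(headLabels(fill$head), headLabels(fx$ref))
  expect_true(all(fill$voxelsChanged == 0))
})

test_that("WM protruding into the probe region triggers rule (2)", {
  fx <- regFixture()
  lay <- placeProbe(fx$ref, probeTemplate("desk", pitch = 8),
                    direction = c(-1, 0, 0.4))
  pm <- probeRegionMask(fx$ref, lay, radius = 25)
  warped <- fx$ref
  lab <- headLabels(warped)
  # plant WM voxels just outside the reference head inside the probe region
  outside <- which(lab == 0L & pm, arr.ind = TRUE)
  stopifnot(nrow(outside) > 0)
  lab[outside[1:10, ]] <- 5L
  warped@labels <- lab
  fill <- fillReferenceShell(fx$ref, warped, shellThickness = 1.5,
                             probeMask = pm, csfTolerance = 1e9)
  expect_false(fill$accepted)
  expect_identical(fill$failedRule, 2L)
})

test_that("CSF-1 mismatch beyond the tolerance triggers rule (1)", {
  fx <- regFixture()
  lay <- placeProbe(fx$ref, probeTemplate("desk", pitch = 8),
                    direction = c(-1, 0, 0.4))
  pm <- probeRegionMask(fx$ref, lay, radius = 25)
  warped <- fx$ref
  lab <- headLabels(warped)
  outside <- which(lab == 0L & pm, arr.ind = TRUE)
  lab[outside[1:200, ]] <- 2L # 200 voxels of (0.5 mm)^3 = 25 mm^3 CSF-1
  warped@labels <- lab
  fill <- fillReferenceShell(fx$ref, warped, shellThickness = 1.5,
                             probeMask = pm, csfTolerance = 10)
  expect_false(fill$accepted)
  expect_identical(fill$failedRule, 1L)
  # a generous tolerance lets the same mismatch through
  fill2 <- fillReferenceShell(fx$ref, warped, shellThickness = 1.5,
                              probeMask = pm, csfTolerance = 100)
  expect_true(fill2$accepted)
})

test_that("resampling through an affine keeps the label set", {
  fx <- regFixture()
  Tm <- cbind(diag(c(1.02, 0.98, 1.01)), c(0.4, -0.3, 0.2))
  warped <- resampleHead(fx$ref, Tm, fx$ref)
  expect_true(all(unique(as.vector(headLabels(warped))) %in%
                    c(0L, unique(as.vector(headLabels(fx$ref))))))
  expect_identical(dim(headLabels(warped)), dim(headLabels(fx$ref)))
})

test_that("accepted registered subjects share the reference exterior", {
  fx <- regFixture()
  lay <- placeProbe(fx$ref, probeTemplate("desk", pitch = 8),
                    direction = c(-1, 0, 0.4))
  pop <- generatePopulation(2, seed = 33, params = phantomParams(scale = 0.5),
                            spacing = 0.5)
  for (i in 1:2) {
    reg <- registerSubject(pop$heads[[i]], pop$points[[i]], fx$ref, fx$pts,
                           lay, probeRadius = 25, shellThickness = 1.5)
    if (reg$accepted)
      expect_identical(headLabels(reg$head) > 0, headLabels(fx$ref) > 0)
    expect_lte(reg$scaling$rmseAfter, reg$scaling$rmseBefore + 1e-12)
  }
})

test_that("majority downsampling keeps a single connected head", {
  hd <- generateHead(2, phantomParams(scale = 0.5), spacing = 0.5)
  ds <- downsampleHead(hd, 3L)
  expect_equal(voxelSpacing(ds), 1.5)
  lab <- headLabels(ds)
  # volume approximately conserved
  expect_equal(sum(lab > 0) * 1.5^3, sum(headLabels(hd) > 0) * 0.5^3,
               tolerance = 0.05)
  # the labelled region is 6-connected (single component)
  d <- dim(lab)
  idx <- which(lab > 0)
  comp <- integer(prod(d))
  comp[idx[1]] <- 1L
  frontier <- idx[1]
  lin <- function(ijk) (ijk[, 3] - 1) * d[1] * d[2] + (ijk[, 2] - 1) * d[1] +
    ijk[, 1]
  while (length(frontier)) {
    ijk <- arrayInd(frontier, d)
    nb <- NULL
    for (a in 1:3) for (s in c(-1, 1)) {
      jj <- ijk; jj[, a] <- jj[, a] + s
      ok <- jj[, a] >= 1 & jj[, a] <= d[a]
      nb <- c(nb, lin(jj[ok, , drop = FALSE]))
    }
    nb <- unique(nb)
    nb <- nb[lab[nb] > 0 & comp[nb] == 0L]
    comp[nb] <- 1L
    frontier <- nb
  }
  expect_equal(sum(comp), length(idx))
})
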