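test_that("head generation is deterministic and validates layer ordering", {
  p <- phantomParams(scale = 0.5)
  h1 <- generateHead(5, p, spacing = 0.5)
  h2 <- generateHead(5, p, spacing = 0.5)
  expect_identical(headLabels(h1), headLabels(h2))
  expect_error(generateHead(1, phantomParams(scale = 0.5, grooveDepth = 10),
                            spacing = 0.5), "grey-matter")
  expect_error(generateHead(1, phantomParams(scale = 0.5,
                                             shellThickness = 0.4),
                            spacing = 0.5), "two voxels")
})

test_that("degenerate phantom volumes match analytic ellipsoid shells", {
  # no sulci, no CSF layer: four concentric compartments
  p <- phantomParams(scale = 0.5, nSulci = 0, csfThickness = 0,
                     ventricleAxes = c(0, 0, 0))
  hd <- generateHead(1, p, spacing = 0.5)
  lab <- headLabels(hd)
  vol <- function(ax) 4 / 3 * pi * prod(ax)
  vvol <- 0.5^3
  ax <- p$semiAxes
  analytic <- c(SS = vol(ax) - vol(ax - p$shellThickness),
                GM = vol(ax - p$shellThickness) -
                     vol(ax - p$shellThickness - p$gmThickness),
                WM = vol(ax - p$shellThickness - p$gmThickness))
  got <- c(SS = sum(lab == 1L), GM = sum(lab == 4L),
           WM = sum(lab == 5L)) * vvol
  # agreement within roughly one voxel layer over each interface area
  for (tn in names(analytic)) {
    surfArea <- 4 * pi * prod(ax[1:2])^(1 / 2) * 1.2 # loose bound
    expect_lt(abs(got[[tn]] - analytic[[tn]]), surfArea * 0.5)
  }
  expect_equal(sum(lab == 2L) + sum(lab == 3L), 0L)
})

test_that("groove depth monotonically adds CSF", {
  v <- vapply(c(1.5, 2.5, 3.4), function(dep)
    sum(headLabels(generateHead(1, phantomParams(scale = 0.5,
                                                 grooveDepth = dep),
                                spacing = 0.5)) == 2L), numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("population variation scales the head circumference as requested", {
  p <- phantomParams(scale = 0.4)
  pop <- generatePopulation(24, seed = 9, params = p,
                            spread = list(size = 0.06, shell = 0,
                                          csf = 0, groove = 0, sulci = 0),
                            spacing = 0.5, points = FALSE)
  circ <- vapply(pop$heads, headCircumference, numeric(1))
  relSd <- sd(circ) / mean(circ)
  expect_equal(relSd, 0.06, tolerance = 0.35)
  # zero spread reproduces identical heads
  pop0 <- generatePopulation(3, seed = 2, params = p,
                             spread = list(size = 0, shell = 0, csf = 0,
                                           groove = 0, sulci = 0),
                             spacing = 0.5, points = FALSE)
  expect_identical(headLabels(pop0$heads[[1]]), headLabels(pop0$heads[[2]]))
  expect_identical(headLabels(pop0$heads[[2]]), headLabels(pop0$heads[[3]]))
})

test_that("cranial point sets carry 249 + 5 named on-surface points", {
  hd <- generateHead(3, phantomParams(scale = 0.5), spacing = 0.5)
  cp <- cranialPoints(hd)
  expect_equal(nrow(surfacePoints(cp)), 249L)
  expect_equal(rownames(landmarkPoints(cp)),
               c("Iz", "Nz", "LPA", "RPA", "Cz"))
  expect_equal(nrow(allPoints(cp)), 254L)
  # all points on the voxel surface within half a voxel: stepping half a
  # voxel outward leaves the head, half a voxel inward stays inside
  ctr <- fdot:::.headCentroid(hd)
  lab <- headLabels(hd)
  d <- dim(lab)
  onSurface <- apply(allPoints(cp), 1, function(pt) {
    u <- (pt - ctr) / sqrt(sum((pt - ctr)^2))
    labAt <- function(q) {
      ijk <- floor((q - headOrigin(hd)) / voxelSpacing(hd)) + 1
      if (any(ijk < 1) || any(ijk > d)) return(0L)
      lab[ijk[1], ijk[2], ijk[3]]
    }
    labAt(pt - 0.5 * u) > 0 && labAt(pt + 0.75 * u) == 0
  })
  expect_true(all(onSurface))
})

test_that("landmarks sit at the axis poles on a sphere phantom", {
  hd <- sphereHead(15, h = 0.5, label = 1L)
  cp <- cranialPoints(hd)
  lm <- landmarkPoints(cp)
  ctr <- fdot:::.headCentroid(hd)
  expect_equal(lm["Cz", 1:2], ctr[1:2], tolerance = 0.5, ignore_attr = TRUE)
  expect_gt(lm["Cz", 3], ctr[3] + 14)
  # Nz and Iz antipodal on the y axis within a voxel
  expect_equal(lm["Nz", ] + lm["Iz", ], 2 * ctr, tolerance = 0.7,
               ignore_attr = TRUE)
})

test_that("probe placement on a sphere recovers template geodesics", {
  hd <- sphereHead(25, h = 0.5, label = 1L)
  tmpl <- probeTemplate("desk", pitch = 8)
  lay <- placeProbe(hd, tmpl, direction = c(0, 0, 1), sweeps = 50)
  ctr <- fdot:::.headCentroid(hd)
  pos <- rbind(sourcePositions(lay), detectorPositions(lay))
  tmo <- rbind(tmpl[tmpl$role == "source", ], tmpl[tmpl$role == "detector", ])
  td <- as.matrix(dist(cbind(tmo$u, tmo$v)))
  # geodesic separations on the sphere: R * angle
  U <- sweep(pos, 2, ctr)
  r <- sqrt(rowSums(U^2))
  Un <- U / r
  geo <- mean(r) * acos(pmin(1, pmax(-1, tcrossprod(Un))))
  sel <- upper.tri(td) & td > 0
  expect_lt(max(abs(geo[sel] - td[sel]) / td[sel]), 0.02)
  # the fitted launch target reproduces the sphere centre
  expect_equal(launchTarget(lay), ctr, tolerance = 1)
  expect_lt(lay@fitResidual, 1)
  # re-running the relaxation from its output is a fixed point
  lay2 <- placeProbe(hd, tmpl, direction = c(0, 0, 1), sweeps = 50)
  expect_equal(sourcePositions(lay2), sourcePositions(lay),
               tolerance = 1e-9)
})

test_that("full probe template ships 15 sources and 15 detectors", {
  tm <- probeTemplate("full")
  expect_equal(sum(tm$role == "source"), 15L)
  expect_equal(sum(tm$role == "detector"), 15L)
})
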