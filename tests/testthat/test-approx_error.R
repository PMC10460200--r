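test_that("two-sample statistics reproduce the hand evaluation exactly", {
  st <- errorStatistics(c(0, 0), list(c(1, 0), c(0, 1)), "toy")
  expect_equal(errorMean(st), c(-0.5, -0.5))
  expect_equal(errorCov(st), matrix(c(0.5, -0.5, -0.5, 0.5), 2),
               tolerance = 1e-12)
  expect_equal(errorEigenvalues(st), c(1, 0), tolerance = 1e-12)
  expect_equal(errorStd(st), 1, tolerance = 1e-12)
  # the sole eigenvector is proportional to (1, -1); the mean is
  # orthogonal to it, so the projected-mean ratio vanishes
  v1 <- errorEigenvectors(st)[, 1]
  expect_equal(abs(v1), c(1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(projectionRatioMean(st), 0, tolerance = 1e-12)
})

test_that("degenerate ensembles give exactly zero statistics", {
  y <- c(1.3, -2.2, 0.5)
  st <- errorStatistics(y, list(y, y, y), "zero")
  expect_equal(errorMean(st), rep(0, 3))
  expect_equal(errorStd(st), 0)
  expect_true(all(errorCov(st) == 0))
})

test_that("covariance rank is N - 1 for independent samples", {
  set.seed(11)
  m <- 12; N <- 6
  ys <- lapply(seq_len(N), function(i) rnorm(m))
  st <- errorStatistics(rnorm(m), ys, "rank")
  v <- errorEigenvalues(st)
  expect_equal(sum(v > 1e-10 * v[1]), N - 1)
  # trace equals the eigenvalue sum
  expect_equal(sum(diag(errorCov(st))), sum(v), tolerance = 1e-10)
  # eigenvectors orthonormal
  V <- errorEigenvectors(st)
  expect_equal(crossprod(V), diag(ncol(V)), tolerance = 1e-10)
})

test_that("visibility ratios behave on aligned and scaled signals", {
  set.seed(3)
  ys <- lapply(1:5, function(i) rnorm(8))
  yref <- rnorm(8)
  st <- errorStatistics(yref, ys, "vis")
  expect_equal(signalVisibility(rep(0, 8), st)$ratio, 0)
  # a signal along the first eigenvector with norm sqrt(lambda1) has
  # ratio sqrt(lambda1 / sum(lambda))
  v1 <- errorEigenvectors(st)[, 1]
  l <- errorEigenvalues(st)
  sv <- signalVisibility(v1 * sqrt(l[1]), st)
  expect_equal(sv$ratio, sqrt(l[1] / sum(l)), tolerance = 1e-10)
  expect_equal(sv$projections[1], sqrt(l[1]), tolerance = 1e-10)
  # global rescaling of all inputs leaves every ratio unchanged
  sc <- 7.3
  st2 <- errorStatistics(sc * yref, lapply(ys, `*`, sc), "vis")
  dy <- rnorm(8)
  expect_equal(signalVisibility(sc * dy, st2)$ratio,
               signalVisibility(dy, st)$ratio, tolerance = 1e-10)
  expect_equal(projectionRatioMean(st2), projectionRatioMean(st),
               tolerance = 1e-10)
})

test_that("difference-error statistics follow the Jacobian mismatch", {
  Jref <- matrix(c(1, 0, 0, 1), 2)
  J1 <- matrix(c(1, 0, 0, 0), 2)
  J2 <- matrix(c(0, 0, 0, 1), 2)
  dx <- c(1, 1)
  st <- differenceErrorStats(Jref, list(J1, J2), dx, "toy-diff")
  # e_1 = (Jref - J1) dx = (0, 1); e_2 = (1, 0)
  expect_equal(errorMean(st), c(0.5, 0.5))
  expect_equal(errorCov(st), matrix(c(0.5, -0.5, -0.5, 0.5), 2),
               tolerance = 1e-12)
  vr <- visibilityRatios(as.numeric(Jref %*% dx), st)
  expect_equal(unname(vr["meanRatio"]), sqrt(2) / sqrt(0.5),
               tolerance = 1e-12)
  # identical Jacobians: zero statistics
  st0 <- differenceErrorStats(Jref, list(Jref, Jref), dx)
  expect_equal(errorStd(st0), 0)
})

test_that("MC reweighting equals a fresh transport with the same seed", {
  run <- mcSlabRun()
  mv <- mcMeasurementVector(run$head, run$optics, run$layout,
                            nPhotons = 20000, seed = 7, f = 0.1,
                            keepRecords = TRUE)
  opt2 <- run$optics
  opt2$mu_a <- opt2$mu_a * 1.6 # +60% everywhere
  mua2 <- absorptionVolume(run$head, opt2)
  mvRw <- mcReweight(mv, mua2)
  mvFresh <- mcMeasurementVector(run$head, opt2, run$layout,
                                 nPhotons = 20000, seed = 7, f = 0.1)
  # trajectories are absorption-independent, so the two agree exactly
  expect_equal(measurementData(mvRw)$logamp,
               measurementData(mvFresh)$logamp, tolerance = 1e-12)
  expect_equal(measurementData(mvRw)$phase,
               measurementData(mvFresh)$phase, tolerance = 1e-12)
})

test_that("tissue sweep is zero at zero change and monotone in |change|", {
  run <- mcSlabRun()
  mv <- mcMeasurementVector(run$head, run$optics, run$layout,
                            nPhotons = 20000, seed = 7, f = 0.1,
                            keepRecords = TRUE)
  # toy population: reweightings under global absorption jitter
  set.seed(5)
  ys <- lapply(1:4, function(i) {
    opt <- run$optics
    opt$mu_a <- opt$mu_a * (1 + rnorm(1, 0, 0.05))
    mvp <- mcReweight(mv, absorptionVolume(run$head, opt))
    measurementQuantity(mvp, "logamp")
  })
  stL <- errorStatistics(measurementQuantity(mv, "logamp"), ys, "sweepL")
  ysP <- lapply(1:4, function(i) measurementQuantity(mv, "phase") + 0)
  stP <- errorStatistics(measurementQuantity(mv, "phase"),
                         lapply(1:4, function(i)
                           measurementQuantity(mv, "phase") + rnorm(
                             length(ysP[[1]]), 0, 1e-3)), "sweepP")
  sw <- tissueSweep(mv, run$head, run$optics, "GM",
                    grid = c(0, 0.2, 0.4, 0.6), statsLogamp = stL,
                    statsPhase = stP)
  expect_equal(sw$logamp[1], 0)
  expect_true(all(diff(sw$logamp) > 0))
})

test_that("cylinder slices partition the full-cylinder perturbation", {
  run <- mcSlabRun()
  mv <- mcMeasurementVector(run$head, run$optics, run$layout,
                            nPhotons = 20000, seed = 7, f = 0.1,
                            keepRecords = TRUE)
  jac <- mcJacobian(mv, run$head, run$optics)
  start <- c(15, 15, 15) # top surface between the optodes
  prof <- cylinderSensitivity(jac, run$head, row = 1, start = start,
                              direction = c(0, 0, -1), radius = 2.5,
                              depth = 10, slice = 1)
  # partition additivity: summed slice responses equal the full cylinder
  ctrs <- elementCentres(jac, run$head)
  rel <- sweep(ctrs, 2, start)
  ax <- rel[, 3] * -1
  rad2 <- rowSums(rel^2) - ax^2
  full <- as.numeric(rad2 <= 2.5^2 & ax >= 0 & ax < 10)
  expect_equal(sum(prof$logamp),
               sum(jacobianLogamp(jac)[1, ] * full), tolerance = 1e-10)
  # CW sign: lnA sensitivities are nonpositive at every depth
  jac0 <- mcJacobian(mcMeasurementVector(run$head, run$optics, run$layout,
                                         nPhotons = 20000, seed = 7, f = 0,
                                         keepRecords = TRUE),
                     run$head, run$optics)
  prof0 <- cylinderSensitivity(jac0, run$head, row = 1, start = start,
                               direction = c(0, 0, -1), radius = 2.5,
                               depth = 10, slice = 1)
  expect_true(all(prof0$logamp <= 0))
  # slices beyond any detected-photon support are exactly zero
  deep <- cylinderSensitivity(jac0, run$head, row = 1,
                              start = c(1, 1, 15),
                              direction = c(0, 0, -1), radius = 1,
                              depth = 14, slice = 2)
  expect_true(any(deep$logamp == 0))
})
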