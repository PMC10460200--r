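# End-to-end study driver: synthetic population -> probe placement ->
# (optional) CSF split -> registration to the reference exterior ->
# forward solves + absorption Jacobians per anatomy -> approximation-error
# statistics and detectability ratios.

#' Study configuration
#'
#' All knobs of the end-to-end synthetic study, fully serializable
#' (\code{\link{writeStudyConfig}}); a run is reproducible from the
#' configuration and its seeds alone. The defaults define the desk-scale
#' study: a half-size neonatal phantom population (N = 20) generated at
#' 0.5 mm, simulated with the diffusion-approximation solver on a 1.5 mm
#' grid, an 8-optode probe (4 sources + 4 detectors), 100 MHz modulation,
#' and the local ball perturbation (radius 5 mm, delta mu_a =
#' 0.005 mm^-1) probing difference-mode detectability.
#'
#' @param ... overrides of the default entries.
#' @return a list of class \code{"studyConfig"}.
#' @export
studyConfig <- function(...) {
  cfg <- list(
    N = 20L,
    seed = 1L,
    scale = 0.5,
    genSpacing = 0.5,
    simFactor = 3L,          # simulation grid = genSpacing * simFactor
    spread = list(size = 0.063, shell = 0.15, csf = 0.15, groove = 0.15),
    solver = "da",           # "da" or "mc"
    nPhotons = 1e5,          # per source, MC solver only
    f = 0.1,                 # GHz (100 MHz)
    sdsMax = 55,             # mm
    probePitch = 8,          # mm, desk template
    probeDirection = c(-1, 0, 0.4),
    patchRadius = 2.5,       # mm
    probeRegionRadius = 30,  # mm, registration QC region
    shellThickness = 1.5,    # mm, reference S&S mask (half-scale)
    gamma1 = 0.45,
    gamma2 = 0.55,
    csfTolerance = 10,       # mm^3, QC rule (1)
    csfSplit = FALSE,        # two-compartment CSF (MC models)
    csfTheta = 0.6,
    ballRadius = 5,          # mm
    ballDelta = 0.005,       # mm^-1
    ballDepth = 7,           # mm below the probe-centre surface point
    tMax = 5,                # ns, MC time cutoff
    outputDir = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "studyConfig"
  cfg
}

#' Serialize / parse a study configuration (YAML)
#'
#' Round-trips exactly: \code{readStudyConfig(writeStudyConfig(cfg, f))}
#' equals \code{cfg}.
#'
#' @param config a \code{studyConfig}.
#' @param path file path.
#' @return \code{readStudyConfig} returns the configuration.
#' @export
writeStudyConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeStudyConfig
#' @export
readStudyConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- studyConfig()
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (is.null(v)) { cfg[nm] <- list(NULL); next }
    if (is.list(v) && !is.list(cfg[[nm]])) v <- unlist(v)
    if (is.integer(cfg[[nm]])) v <- as.integer(v)
    else if (is.numeric(cfg[[nm]])) v <- as.numeric(v)
    cfg[[nm]] <- v
  }
  cfg
}

.studyForward <- function(head, layout, cfg, optics = NULL, refMesh = NULL) {
  if (cfg$solver == "da") {
    if (is.null(optics)) optics <- tissueTable("da")
    mesh <- voxelToMesh(head)
    mesh <- tagPatches(mesh, layout)
    mv <- daMeasurementVector(mesh, optics, layout, f = cfg$f,
                              sdsMax = cfg$sdsMax, keepSolver = TRUE)
    jac <- daJacobian(mv)
    list(mv = mv, jac = jac, mesh = mesh)
  } else {
    if (is.null(optics)) optics <- tissueTable("mc")
    mv <- mcMeasurementVector(head, optics, layout,
                              nPhotons = cfg$nPhotons, seed = cfg$seed,
                              f = cfg$f, sdsMax = cfg$sdsMax,
                              tMax = cfg$tMax, keepRecords = TRUE)
    jac <- mcJacobian(mv, head, optics)
    list(mv = mv, jac = jac, mesh = NULL)
  }
}

#' Run the end-to-end synthetic study
#'
#' Pipeline: generate the reference head and a population with
#' inter-individual variation; place the probe on the reference; register
#' every subject to the reference exterior (affine + probe-region scaling
#' + shell filling with QC; rejected subjects are counted and excluded);
#' downsample all accepted models to the simulation grid (identical
#' exterior by construction, so Jacobian columns align element-by-element);
#' run the forward solver and absorption Jacobians for the reference and
#' every subject; estimate the absolute-measurement approximation-error
#' statistics and the Jacobian-mismatch difference-error statistics for
#' the local ball perturbation; report visibility ratios for both modes.
#'
#' @param config a \code{\link{studyConfig}}.
#' @param verbose print stage timings.
#' @return a list with elements \code{config}, \code{nAccepted},
#'   \code{nRejected}, \code{rejectedRules}, \code{registration}
#'   (per-subject RMSE summaries), \code{statsAbs} (list logamp/phase
#'   \code{ErrorStatistics}), \code{statsDiff} (same for difference mode),
#'   \code{ball} (centre/radius/delta), \code{visibility} (data.frame of
#'   ratios), \code{reference} (head, layout, measurement), and
#'   \code{eigen} (spectra summaries).
#' @export
runStudy <- function(config = studyConfig(), verbose = TRUE) {
  cfg <- config
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() Sys.time()
  t0 <- tic()

  params <- phantomParams(scale = cfg$scale)
  if (!is.null(cfg$spread$sulci) && cfg$spread$sulci == 0)
    params$groovePhase <- 0 # fixed sulci everywhere, reference included
  ref <- generateHead(cfg$seed, params, spacing = cfg$genSpacing)
  refPts <- cranialPoints(ref)
  layout <- placeProbe(ref, probeTemplate("desk", pitch = cfg$probePitch),
                       direction = cfg$probeDirection,
                       patchRadius = cfg$patchRadius)
  say("reference + probe: %.1f s", as.numeric(tic()) - as.numeric(t0))

  pop <- generatePopulation(cfg$N, seed = cfg$seed + 1000L, params = params,
                            spread = cfg$spread, spacing = cfg$genSpacing)

  regs <- vector("list", cfg$N)
  accepted <- logical(cfg$N)
  rules <- integer(cfg$N)
  for (i in seq_len(cfg$N)) {
    r <- registerSubject(pop$heads[[i]], pop$points[[i]], ref, refPts,
                         layout, probeRadius = cfg$probeRegionRadius,
                         shellThickness = cfg$shellThickness,
                         gamma1 = cfg$gamma1, gamma2 = cfg$gamma2,
                         csfTolerance = cfg$csfTolerance)
    regs[[i]] <- r
    accepted[i] <- r$accepted
    rules[i] <- r$failedRule
  }
  say("registration: %d/%d accepted", sum(accepted), cfg$N)

  if (isTRUE(cfg$csfSplit)) {
    ref <- csfSplit(ref, theta = cfg$csfTheta)
    for (i in which(accepted))
      regs[[i]]$head <- csfSplit(regs[[i]]$head, theta = cfg$csfTheta)
    say("CSF split applied")
  }

  refSim <- downsampleHead(ref, cfg$simFactor)
  subsSim <- lapply(which(accepted), function(i)
    downsampleHead(regs[[i]]$head, cfg$simFactor))
  # identical exterior masks guarantee identical meshes / voxel grids
  exts <- vapply(subsSim, function(h)
    identical(headLabels(h) > 0, headLabels(refSim) > 0), logical(1))
  if (!all(exts))
    stop("registered models do not share the reference exterior")

  t1 <- tic()
  fwRef <- .studyForward(refSim, layout, cfg)

  # ball perturbation under the probe centre, on the shared element grid
  probeCtr <- colMeans(rbind(sourcePositions(layout),
                             detectorPositions(layout)))
  ctr0 <- .headCentroid(refSim)
  surfPt <- .surfaceCast(refSim, ctr0,
                         matrix(probeCtr - ctr0, 1))[1, ]
  inward <- (ctr0 - surfPt) / sqrt(sum((ctr0 - surfPt)^2))
  ballCtr <- surfPt + cfg$ballDepth * inward
  geomRef <- if (cfg$solver == "da") fwRef$mesh else refSim
  dx <- ballPerturbation(fwRef$jac, geomRef, ballCtr,
                         radius = cfg$ballRadius, deltaMuA = cfg$ballDelta)

  # stream the subjects: keep only the measurement vectors and the
  # Jacobian-perturbation products (the dense Jacobians and factorized
  # operators of 20 anatomies would not fit in memory together)
  zRefL <- as.numeric(jacobianLogamp(fwRef$jac) %*% dx)
  zRefP <- as.numeric(jacobianPhase(fwRef$jac) %*% dx)
  ysL <- ysP <- zsL <- zsP <- vector("list", length(subsSim))
  for (i in seq_along(subsSim)) {
    fw <- .studyForward(subsSim[[i]], layout, cfg)
    ysL[[i]] <- measurementQuantity(fw$mv, "logamp")
    ysP[[i]] <- measurementQuantity(fw$mv, "phase")
    zsL[[i]] <- as.numeric(jacobianLogamp(fw$jac) %*% dx)
    zsP[[i]] <- as.numeric(jacobianPhase(fw$jac) %*% dx)
    rm(fw)
  }
  say("forward + Jacobians (%d models): %.1f s", length(subsSim) + 1,
      as.numeric(tic()) - as.numeric(t1))

  yRefL <- measurementQuantity(fwRef$mv, "logamp")
  yRefP <- measurementQuantity(fwRef$mv, "phase")
  statsAbs <- list(
    logamp = errorStatistics(yRefL, ysL, "logamp:absolute"),
    phase = errorStatistics(yRefP, ysP, "phase:absolute"))

  # e_i = (J_ref - J_i) dx = z_ref - z_i
  statsDiff <- list(
    logamp = errorStatistics(zRefL, zsL, "logamp:difference"),
    phase = errorStatistics(zRefP, zsP, "phase:difference"))

  # reference difference signal from a perturbed forward solve
  if (cfg$solver == "da") {
    der <- derivedCoefficients(tissueTable("da"))
    muaBase <- .tissueValue(der, "mu_a")[meshLabels(fwRef$mesh)]
    muaPert <- muaBase
    muaPert[dx > 0] <- muaPert[dx > 0] + cfg$ballDelta
    mvPert <- daMeasurementVector(fwRef$mesh, tissueTable("da"), layout,
                                  f = cfg$f, sdsMax = cfg$sdsMax,
                                  muaElement = muaPert)
  } else {
    muaVol <- absorptionVolume(refSim, tissueTable("mc"))
    muaVol[fwRef$jac@elements[dx > 0]] <-
      muaVol[fwRef$jac@elements[dx > 0]] + cfg$ballDelta
    mvPert <- mcReweight(fwRef$mv, muaVol)
  }
  dYL <- measurementQuantity(mvPert, "logamp") - yRefL
  dYP <- measurementQuantity(mvPert, "phase") - yRefP

  visAbsL <- signalVisibility(dYL, statsAbs$logamp)$ratio
  visAbsP <- signalVisibility(dYP, statsAbs$phase)$ratio
  vrL <- visibilityRatios(dYL, statsDiff$logamp)
  vrP <- visibilityRatios(dYP, statsDiff$phase)

  visibility <- data.frame(
    quantity = c("logamp", "phase"),
    absoluteRatio = c(visAbsL, visAbsP),
    diffStdRatio = c(vrL["stdRatio"], vrP["stdRatio"]),
    diffMeanRatio = c(vrL["meanRatio"], vrP["meanRatio"]),
    meanProjRatio = c(
      if (errorStd(statsAbs$logamp) > 0)
        projectionRatioMean(statsAbs$logamp) else NA_real_,
      if (errorStd(statsAbs$phase) > 0)
        projectionRatioMean(statsAbs$phase) else NA_real_))

  eigenSummary <- function(st) {
    v <- errorEigenvalues(st)
    pos <- v[v > 1e-10 * max(v, 0)]
    cum <- cumsum(pos) / sum(pos)
    data.frame(quantity = st@quantity, rank = length(pos),
               n95 = which(cum >= 0.95)[1],
               lambda1 = pos[1])
  }
  eig <- do.call(rbind, lapply(c(statsAbs, statsDiff), eigenSummary))

  res <- list(config = cfg, nAccepted = sum(accepted),
              nRejected = sum(!accepted),
              rejectedRules = rules[!accepted],
              registration = data.frame(
                subject = seq_len(cfg$N), accepted = accepted,
                rmseBefore = vapply(regs, function(r)
                  r$affine$rmseBefore, numeric(1)),
                rmseAfter = vapply(regs, function(r)
                  r$affine$rmseAfter, numeric(1)),
                probeRmseBefore = vapply(regs, function(r)
                  r$scaling$rmseBefore, numeric(1)),
                probeRmseAfter = vapply(regs, function(r)
                  r$scaling$rmseAfter, numeric(1)),
                gmLost = vapply(regs, function(r) r$gmLost, numeric(1))),
              statsAbs = statsAbs, statsDiff = statsDiff,
              ball = list(centre = ballCtr, radius = cfg$ballRadius,
                          delta = cfg$ballDelta),
              visibility = visibility, eigen = eig,
              reference = list(head = refSim, layout = layout,
                               measurement = fwRef$mv, jacobian = fwRef$jac,
                               mesh = fwRef$mesh))

  if (!is.null(cfg$outputDir)) {
    dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(res$visibility,
              file.path(cfg$outputDir, "visibility.csv"), row.names = FALSE)
    write.csv(res$registration,
              file.path(cfg$outputDir, "registration.csv"),
              row.names = FALSE)
    write.csv(res$eigen, file.path(cfg$outputDir, "eigen.csv"),
              row.names = FALSE)
    writeMeasurementVector(fwRef$mv,
                           file.path(cfg$outputDir, "reference_mv.csv"))
    spectra <- data.frame(
      index = seq_along(errorEigenvalues(statsAbs$logamp)),
      abs_logamp = errorEigenvalues(statsAbs$logamp),
      abs_phase = errorEigenvalues(statsAbs$phase),
      diff_logamp = errorEigenvalues(statsDiff$logamp),
      diff_phase = errorEigenvalues(statsDiff$phase))
    write.csv(spectra, file.path(cfg$outputDir, "eigen_spectra.csv"),
              row.names = FALSE)
    writeStudyConfig(cfg, file.path(cfg$outputDir, "config.yaml"))
    manifest <- list(package = "fdot",
                     version = as.character(utils::packageVersion("fdot")),
                     seed = cfg$seed, nAccepted = res$nAccepted,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    yaml::write_yaml(manifest, file.path(cfg$outputDir, "manifest.yaml"))
  }
  res
}
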