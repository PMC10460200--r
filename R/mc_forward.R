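#' Per-voxel absorption field from a head model and a tissue table
#'
#' Maps the per-tissue absorption coefficients onto the voxel grid;
#' background voxels get 0.
#'
#' @param head a \code{VoxelHeadModel}.
#' @param optics tissue table (see \code{\link{tissueTable}}).
#' @return numeric vector of length \code{prod(dim(labels))}, mm^-1.
#' @export
absorptionVolume <- function(head, optics = tissueTable("mc")) {
  mua <- .tissueValue(optics, "mu_a")
  v <- c(0, mua)[as.vector(head@labels) + 1L]
  v[is.na(v)] <- 0
  v
}

.opticsVectors <- function(optics) {
  list(mus = c(0, .tissueValue(optics, "mu_s")),
       g = c(0, .tissueValue(optics, "g")),
       n = c(1, .tissueValue(optics, "n")))
}

#' Monte Carlo photon transport for one source
#'
#' Launches photon packets from a collimated disk source of radius
#' \code{patchRadius(layout)} toward the probe's centre of curvature
#' (\code{launchTarget}), propagates them through the labelled voxel grid
#' with free paths sampled from the local scattering coefficient and
#' Henyey-Greenstein deflection with the local anisotropy, using exact
#' axis-aligned voxel ray traversal. Changes of the scattering coefficient
#' mid-step rescale the remaining free path by the ratio of the old to the
#' new coefficient (implemented via a dimensionless pathlength budget).
#' At the exterior boundary a photon either exits or is reflected back
#' (binary decision by the unpolarized Fresnel reflectance). A photon
#' exiting within a detector patch is detected and its sparse per-voxel
#' partial pathlengths and time of flight are recorded. Absorption is not
#' applied during transport (microscopic Beer-Lambert law), so trajectories
#' are independent of mu_a and weights can be recomputed afterwards.
#'
#' Each photon draws from an independent counter-based RNG stream seeded by
#' (seed, launch index); re-running any subset of launch indices reproduces
#' their trajectories bit-exactly (strict replay).
#'
#' @param head \code{VoxelHeadModel}.
#' @param optics tissue table (scattering, anisotropy, refractive index).
#' @param layout \code{OptodeLayout}.
#' @param sourceId which source to fire (row of
#'   \code{sourcePositions(layout)}).
#' @param nPhotons number of photon packets to launch.
#' @param seed integer seed of the run.
#' @param tMax time-of-flight cutoff, ns (default 5).
#' @param nExterior exterior refractive index (default 1).
#' @param photonIndices optional vector of launch indices (1-based) to
#'   simulate instead of \code{1:nPhotons}; used for strict replay.
#' @return a \code{PhotonRecordSet}.
#' @export
mcTransport <- function(head, optics, layout, sourceId, nPhotons, seed,
                        tMax = 5, nExterior = 1.0, photonIndices = NULL) {
  stopifnot(is(head, "VoxelHeadModel"), is(layout, "OptodeLayout"))
  if (is.null(photonIndices)) {
    if (nPhotons < 1) stop("nPhotons must be >= 1")
    photonIndices <- seq_len(nPhotons)
  }
  ov <- .opticsVectors(optics)
  src <- sourcePositions(layout)[sourceId, ]
  res <- .mc_transport_cpp(
    as.integer(head@labels), dim(head@labels), head@spacing, head@origin,
    ov$mus, ov$g, ov$n, nExterior, as.numeric(src),
    as.numeric(launchTarget(layout)), patchRadius(layout),
    detectorPositions(layout), patchRadius(layout),
    as.numeric(photonIndices), as.numeric(seed), tMax)
  out <- new("PhotonRecordSet",
             detector = res$detector, tof = res$tof, ptr = res$ptr,
             voxel = res$voxel, pathlen = res$pathlen,
             nLaunched = as.numeric(length(photonIndices)),
             nTerminated = res$nTerminated,
             dims = dim(head@labels), spacing = head@spacing,
             sourceId = as.integer(sourceId), seed = as.numeric(seed))
  attr(out, "launchIndex") <- res$launchIndex
  attr(out, "nEscaped") <- res$nEscaped
  attr(out, "nMissed") <- res$nMissed
  out
}

#' Detected-photon weights under the microscopic Beer-Lambert law
#'
#' w_p = exp(-sum_j mu_a,j l_p,j) for every detected photon, recomputable
#' for any absorption field.
#'
#' @param records a \code{PhotonRecordSet}.
#' @param mu_a per-voxel absorption field (vector over the full grid,
#'   mm^-1), e.g. from \code{\link{absorptionVolume}}.
#' @return numeric vector of weights, one per detected photon.
#' @export
detectedWeight <- function(records, mu_a) {
  if (any(mu_a < 0, na.rm = TRUE)) stop("mu_a must be >= 0")
  if (length(mu_a) != prod(records@dims))
    stop("mu_a must cover the full voxel grid of the records")
  .mc_weights_cpp(records@ptr, records@voxel, records@pathlen,
                  as.numeric(mu_a))
}

#' Frequency-domain measurement from detected photons
#'
#' X = sum_p w_p cos(2 pi f t_p), Y = sum_p w_p sin(2 pi f t_p), both
#' divided by the number of launched photons (unit source strength), with
#' ln A = ln sqrt(X^2 + Y^2) and phase = atan2(Y, X). At f = 0 the
#' measurement is purely real (Y = 0, phase = 0).
#'
#' @param records \code{PhotonRecordSet}.
#' @param mu_a per-voxel absorption field, mm^-1.
#' @param f modulation frequency, GHz (0.1 = 100 MHz).
#' @param detectorId optional single detector to evaluate; default all.
#' @return data.frame with one row per detector: \code{detector, X, Y,
#'   logamp, phase, nDetected, valid}; a detector without detected photons
#'   is flagged invalid rather than returning -Inf log-amplitudes.
#' @export
fdMeasurement <- function(records, mu_a, f, detectorId = NULL) {
  if (f < 0) stop("f must be >= 0")
  w <- detectedWeight(records, mu_a)
  arg <- 2 * pi * f * records@tof
  dets <- if (is.null(detectorId)) seq_len(max(records@detector, 1L))
          else detectorId
  out <- data.frame(detector = dets, X = 0, Y = 0, logamp = NA_real_,
                    phase = NA_real_, nDetected = 0L, valid = FALSE)
  for (i in seq_along(dets)) {
    sel <- records@detector == dets[i]
    n <- sum(sel)
    out$nDetected[i] <- n
    if (n == 0) next
    X <- sum(w[sel] * cos(arg[sel])) / records@nLaunched
    Y <- sum(w[sel] * sin(arg[sel])) / records@nLaunched
    out$X[i] <- X
    out$Y[i] <- Y
    out$logamp[i] <- log(sqrt(X^2 + Y^2))
    out$phase[i] <- atan2(Y, X)
    out$valid[i] <- TRUE
  }
  out
}

#' Assemble the Monte Carlo measurement vector over all sources
#'
#' Fires each source in turn, records the detected photons, and evaluates
#' the FD measurement at every detector. Pairs with source-detector
#' separation (SDS) of \code{sdsMax} or more are masked out, consistently
#' with the Jacobians.
#'
#' @inheritParams mcTransport
#' @param f modulation frequency, GHz (default 0.1 = 100 MHz).
#' @param sdsMax SDS inclusion cutoff, mm (default 55).
#' @param optics tissue table; absorption taken from its \code{mu_a}.
#' @param keepRecords if TRUE, attach the per-source
#'   \code{PhotonRecordSet}s as attribute \code{"records"} (needed for
#'   replay-based re-weighting and Jacobians).
#' @return a \code{MeasurementVector} (solver "mc").
#' @export
mcMeasurementVector <- function(head, optics, layout, nPhotons, seed,
                                f = 0.1, sdsMax = 55, tMax = 5,
                                nExterior = 1.0, keepRecords = FALSE) {
  mu_a <- absorptionVolume(head, optics)
  src <- sourcePositions(layout)
  det <- detectorPositions(layout)
  rows <- list()
  recs <- list()
  for (k in seq_len(nrow(src))) {
    rec <- mcTransport(head, optics, layout, k, nPhotons,
                       seed = seed + k - 1, tMax = tMax,
                       nExterior = nExterior)
    m <- fdMeasurement(rec, mu_a, f, detectorId = seq_len(nrow(det)))
    sds <- sqrt(rowSums((det - matrix(src[k, ], nrow(det), 3,
                                      byrow = TRUE))^2))
    rows[[k]] <- data.frame(source = k, detector = m$detector, sds = sds,
                            X = m$X, Y = m$Y, logamp = m$logamp,
                            phase = m$phase,
                            valid = m$valid & sds < sdsMax)
    if (keepRecords) recs[[k]] <- rec
  }
  mv <- new("MeasurementVector", data = do.call(rbind, rows), f = f,
            solver = "mc", sdsMax = sdsMax)
  if (keepRecords) attr(mv, "records") <- recs
  mv
}
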