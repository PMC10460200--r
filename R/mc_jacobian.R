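#' Exact replay derivatives of X and Y with respect to voxel absorption
#'
#' For the photons recorded during one transport run,
#' dX/dmu_a,j = -sum_p l_p,j w_p cos(2 pi f t_p) and
#' dY/dmu_a,j = -sum_p l_p,j w_p sin(2 pi f t_p), summed per detector and
#' normalized per launched photon. Voxels no detected photon traversed get
#' exact zeros.
#'
#' @param records \code{PhotonRecordSet}.
#' @param mu_a per-voxel absorption field, mm^-1.
#' @param f modulation frequency, GHz.
#' @param nDetectors number of detectors (defaults to the largest detector
#'   index seen).
#' @return list with \code{X}, \code{Y} (per detector) and \code{dX},
#'   \code{dY} (voxel x detector matrices).
#' @export
replayXYDerivatives <- function(records, mu_a, f,
                                nDetectors = max(records@detector, 1L)) {
  if (length(mu_a) != prod(records@dims))
    stop("mu_a must cover the full voxel grid of the records")
  .mc_replay_cpp(records@ptr, records@voxel, records@pathlen,
                 records@detector, records@tof, as.numeric(mu_a), f,
                 as.integer(nDetectors), records@nLaunched)
}

#' Log-amplitude and phase derivative rows from complex derivatives
#'
#' Converts derivatives of the real and imaginary measurement components
#' into derivatives of ln A and phase:
#' d lnA = (X dX + Y dY) / A^2 and d phase = (X dY - Y dX) / A^2 with
#' A^2 = X^2 + Y^2. Shared by the Monte Carlo replay and the
#' diffusion-approximation adjoint paths.
#'
#' @param X,Y real and imaginary measurement components (scalars).
#' @param dX,dY derivative vectors (same length).
#' @return list with \code{logamp} and \code{phase} derivative vectors.
#' @export
logampPhaseJacobian <- function(X, Y, dX, dY) {
  A2 <- X^2 + Y^2
  if (A2 <= 0) stop("zero measurement amplitude: no detected signal")
  list(logamp = (X * dX + Y * dY) / A2,
       phase = (X * dY - Y * dX) / A2)
}

#' FD 'replay' absorption Jacobian for the Monte Carlo solver
#'
#' Builds the full Jacobian of ln A and phase with respect to per-voxel
#' absorption for all unmasked source-detector pairs of a Monte Carlo
#' measurement vector, from the stored detected-photon records (no
#' re-transport). Columns cover the labelled voxels of \code{head}; row
#' order matches the valid rows of \code{measurement}.
#'
#' @param measurement a \code{MeasurementVector} produced by
#'   \code{\link{mcMeasurementVector}} with \code{keepRecords = TRUE}.
#' @param head the \code{VoxelHeadModel} that was simulated.
#' @param optics tissue table used for the absorption re-weighting.
#' @return a \code{JacobianMatrix} (solver "mc"). Values are derivatives
#'   per mm^-1 absorption change in the whole voxel; use
#'   \code{\link{normalizePerVolume}} for the per-1-mm^3 scale.
#' @export
mcJacobian <- function(measurement, head, optics = tissueTable("mc")) {
  recs <- attr(measurement, "records")
  if (is.null(recs))
    stop("measurement must carry photon records (keepRecords = TRUE)")
  mu_a <- absorptionVolume(head, optics)
  f <- measurement@f
  elements <- which(as.vector(head@labels) > 0L)
  dat <- measurement@data
  keep <- dat$valid
  ndet <- max(dat$detector)
  logamp <- NULL; phase <- NULL
  for (k in sort(unique(dat$source[keep]))) {
    rep_k <- replayXYDerivatives(recs[[k]], mu_a, f, nDetectors = ndet)
    for (j in dat$detector[keep & dat$source == k]) {
      lp <- logampPhaseJacobian(rep_k$X[j], rep_k$Y[j],
                                rep_k$dX[elements, j], rep_k$dY[elements, j])
      logamp <- rbind(logamp, lp$logamp)
      phase <- rbind(phase, lp$phase)
    }
  }
  rows <- dat[keep, c("source", "detector", "sds")]
  # rows were appended source-major, detector-minor: same order as dat
  new("JacobianMatrix", logamp = unname(logamp), phase = unname(phase),
      rows = rows, elements = as.integer(elements),
      elementVolume = rep(head@spacing^3, length(elements)),
      f = f, solver = "mc")
}

#' Rescale a Jacobian to derivatives per 1 mm^3 of tissue
#'
#' Divides every column by its element volume, giving the derivative per
#' absorption change in 1 mm^3.
#'
#' @param jac a \code{JacobianMatrix}.
#' @return the rescaled \code{JacobianMatrix}.
#' @export
normalizePerVolume <- function(jac) {
  s <- rep(1 / jac@elementVolume, each = nrow(jac@logamp))
  jac@logamp <- jac@logamp * s
  jac@phase <- jac@phase * s
  jac
}

#' Difference-quotient absorption Jacobian estimates (validation path)
#'
#' Central differences of the FD measurement under mu_a +/- delta applied
#' to one voxel at a time. Under the microscopic Beer-Lambert law this is
#' pure re-weighting of the stored photons; no re-transport is performed.
#' Used to validate the exact replay derivatives.
#'
#' @param records \code{PhotonRecordSet}.
#' @param mu_a per-voxel absorption field, mm^-1.
#' @param f modulation frequency, GHz.
#' @param delta perturbation step, mm^-1 (default 1e-4).
#' @param nDetectors number of detectors.
#' @return list of voxel x detector matrices \code{dX}, \code{dY},
#'   \code{logamp}, \code{phase}, plus per-detector \code{X}, \code{Y}.
#' @export
differenceQuotientJacobian <- function(records, mu_a, f, delta = 1e-4,
                                       nDetectors = max(records@detector, 1L)) {
  if (length(mu_a) != prod(records@dims))
    stop("mu_a must cover the full voxel grid of the records")
  r <- .mc_diffq_cpp(records@ptr, records@voxel, records@pathlen,
                     records@detector, records@tof, as.numeric(mu_a), f,
                     as.integer(nDetectors), records@nLaunched, delta)
  dX <- (r$Xp - r$Xm) / (2 * delta)
  dY <- (r$Yp - r$Ym) / (2 * delta)
  lnAp <- 0.5 * log(r$Xp^2 + r$Yp^2)
  lnAm <- 0.5 * log(r$Xm^2 + r$Ym^2)
  php <- atan2(r$Yp, r$Xp)
  phm <- atan2(r$Ym, r$Xm)
  list(X = r$X, Y = r$Y, dX = dX, dY = dY,
       logamp = (lnAp - lnAm) / (2 * delta),
       phase = (php - phm) / (2 * delta))
}
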