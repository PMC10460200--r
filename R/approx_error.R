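# Approximation-error statistics over a population of anatomies.
#
# The anatomical modelling error is treated as additive noise: from the
# reference measurement vector y_ref and the population vectors y_i the
# sample mean mu_e = (1/N) sum (y_ref - y_i) and the unbiased sample
# covariance Gamma_e are estimated, eigen-decomposed (through the N x N
# Gram matrix of the centred differences, which carries the same nonzero
# spectrum as the m x m covariance), and summarized by
# STD = sqrt(trace(Gamma_e)) and by projection/visibility ratios of
# signals of interest onto the eigenvector span.

#' Extract a quantity vector from a measurement vector
#'
#' Returns the masked (valid) entries of ln A or phase in row order.
#'
#' @param mv a \code{MeasurementVector}.
#' @param quantity "logamp" or "phase".
#' @return numeric vector of length m.
#' @export
measurementQuantity <- function(mv, quantity = c("logamp", "phase")) {
  quantity <- match.arg(quantity)
  d <- mv@data
  d[[quantity]][d$valid]
}

.eigenFromDifferences <- function(D) {
  # D: m x N matrix of centred differences; Gamma = D D^T / (N - 1)
  N <- ncol(D)
  G <- crossprod(D) / (N - 1) # N x N
  eg <- eigen(G, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * 1e-12
  vals <- pmax(eg$values, 0)
  vecs <- NULL
  if (any(pos)) {
    vecs <- D %*% eg$vectors[, pos, drop = FALSE]
    vecs <- sweep(vecs, 2, sqrt(colSums(vecs^2)), `/`)
  } else {
    vecs <- matrix(0, nrow(D), 0)
  }
  list(values = vals, vectors = vecs)
}

#' Approximation-error statistics of absolute measurements
#'
#' Mean and unbiased covariance of the differences y_ref - y_i over a
#' population, with descending eigendecomposition and
#' STD = sqrt(trace). With N samples at most N - 1 eigenvalues are
#' positive.
#'
#' @param yRef reference vector (length m).
#' @param ys list (or m x N matrix) of population vectors.
#' @param quantity label stored with the statistics.
#' @return an \code{ErrorStatistics} object.
#' @export
errorStatistics <- function(yRef, ys, quantity = "logamp:absolute") {
  Y <- if (is.list(ys)) do.call(cbind, ys) else as.matrix(ys)
  if (nrow(Y) != length(yRef)) stop("population vectors do not match y_ref")
  N <- ncol(Y)
  if (N < 2) stop("need at least two population samples")
  E <- yRef - Y # m x N error realizations
  mu <- rowMeans(E)
  D <- E - mu
  covm <- tcrossprod(D) / (N - 1)
  eg <- .eigenFromDifferences(D)
  m <- length(yRef)
  vals <- numeric(m)
  vals[seq_len(min(m, length(eg$values)))] <-
    sort(eg$values, decreasing = TRUE)[seq_len(min(m, length(eg$values)))]
  new("ErrorStatistics", mean = mu, cov = covm, values = vals,
      vectors = eg$vectors, std = sqrt(sum(diag(covm))), n = N,
      quantity = quantity)
}

#' Difference-error statistics from Jacobian mismatch
#'
#' For a fixed perturbation delta_x, the error in the linearized
#' difference measurement caused by using an atlas Jacobian is
#' e_i = (J_ref - J_i) delta_x; its sample statistics are computed exactly
#' as for absolute measurements.
#'
#' @param Jref reference Jacobian block (m x n_e matrix).
#' @param Js list of population Jacobian blocks on the same element grid.
#' @param deltaX per-element perturbation vector (length n_e), mm^-1.
#' @param quantity label.
#' @return an \code{ErrorStatistics} object.
#' @export
differenceErrorStats <- function(Jref, Js, deltaX,
                                 quantity = "logamp:difference") {
  if (ncol(Jref) != length(deltaX))
    stop("deltaX does not match the Jacobian element grid")
  yRef <- as.numeric(Jref %*% deltaX)
  ys <- lapply(Js, function(J) {
    if (!all(dim(J) == dim(Jref))) stop("incompatible Jacobian dimensions")
    as.numeric(J %*% deltaX)
  })
  # e_i = (J_ref - J_i) dx = yRef - y_i with y_i = J_i dx
  errorStatistics(yRef, ys, quantity = quantity)
}

#' Projected-mean ratio
#'
#' ||P_v mu_e|| / STD: the norm of the error mean projected onto the span
#' of the positive-eigenvalue eigenvectors, relative to the total
#' standard deviation. Measures how representative the reference anatomy
#' is of the population mean.
#'
#' @param stats \code{ErrorStatistics}.
#' @return dimensionless ratio.
#' @export
projectionRatioMean <- function(stats) {
  if (stats@std <= 0) stop("degenerate statistics: STD = 0")
  proj <- crossprod(stats@vectors, stats@mean)
  sqrt(sum(proj^2)) / stats@std
}

#' Visibility of a signal over the approximation error
#'
#' ||P_v delta_y|| / STD plus the per-eigenvector projection magnitudes
#' |delta_y . v_i|. A ratio above one means the signal of interest
#' exceeds the anatomy-induced variation.
#'
#' @param deltaY signal vector (length m), e.g. y_pert - y_ref.
#' @param stats \code{ErrorStatistics}.
#' @return list with \code{ratio} and \code{projections}.
#' @export
signalVisibility <- function(deltaY, stats) {
  if (length(deltaY) != length(stats@mean))
    stop("signal length does not match the statistics")
  proj <- as.numeric(crossprod(stats@vectors, deltaY))
  list(ratio = if (stats@std > 0) sqrt(sum(proj^2)) / stats@std else 0,
       projections = abs(proj))
}

#' Difference-mode ratios
#'
#' The two ratios used to judge detectability in difference imaging:
#' ||delta_y_ref|| / ||mu_e|| (signal vs expected shift) and
#' ||P_w delta_y_ref|| / STD (signal vs spread).
#'
#' @param deltaY reference difference signal, length m.
#' @param stats difference-error \code{ErrorStatistics}.
#' @return named numeric vector \code{c(meanRatio, stdRatio)}.
#' @export
visibilityRatios <- function(deltaY, stats) {
  mu <- stats@mean
  proj <- as.numeric(crossprod(stats@vectors, deltaY))
  c(meanRatio = sqrt(sum(deltaY^2)) / sqrt(sum(mu^2)),
    stdRatio = if (stats@std > 0) sqrt(sum(proj^2)) / stats@std else 0)
}

#' Re-measure a Monte Carlo measurement vector under perturbed absorption
#'
#' Under the microscopic Beer-Lambert law the stored photon records are
#' re-weighted with the perturbed per-voxel absorption; no re-transport.
#'
#' @param mv \code{MeasurementVector} with records attached.
#' @param mu_a perturbed per-voxel absorption field.
#' @return a new \code{MeasurementVector} (records carried over).
#' @export
mcReweight <- function(mv, mu_a) {
  recs <- attr(mv, "records")
  if (is.null(recs)) stop("measurement must carry photon records")
  d <- mv@data
  out <- d
  for (k in sort(unique(d$source))) {
    rows <- which(d$source == k)
    m <- fdMeasurement(recs[[k]], mu_a, mv@f,
                       detectorId = d$detector[rows])
    out$X[rows] <- m$X
    out$Y[rows] <- m$Y
    out$logamp[rows] <- m$logamp
    out$phase[rows] <- m$phase
    out$valid[rows] <- m$valid & d$sds[rows] < mv@sdsMax
  }
  mv2 <- new("MeasurementVector", data = out, f = mv@f, solver = "mc",
             sdsMax = mv@sdsMax)
  attr(mv2, "records") <- recs
  mv2
}

#' Perturbed absorption field for a tissue-wide relative change
#'
#' @param head \code{VoxelHeadModel}.
#' @param optics tissue table.
#' @param tissue tissue name ("SS", "CSF1", "CSF2", "GM", "WM").
#' @param relChange relative change, e.g. -0.6 or +0.6.
#' @return per-voxel absorption vector.
#' @export
perturbTissue <- function(head, optics, tissue, relChange) {
  optics$mu_a[optics$tissue == tissue] <-
    optics$mu_a[optics$tissue == tissue] * (1 + relChange)
  absorptionVolume(head, optics)
}

#' Ball absorption perturbation on the element grid of a Jacobian
#'
#' Per-element vector with \code{deltaMuA} inside a ball, matching the
#' Jacobian's column order.
#'
#' @param jac \code{JacobianMatrix}.
#' @param head \code{VoxelHeadModel} (MC grids) or \code{TetMeshModel}
#'   (DA meshes) behind the Jacobian columns.
#' @param centre ball centre, mm.
#' @param radius ball radius, mm (default 5).
#' @param deltaMuA absorption increase, mm^-1 (default 0.005).
#' @return numeric vector over Jacobian columns.
#' @export
ballPerturbation <- function(jac, head, centre, radius = 5,
                             deltaMuA = 0.005) {
  ctrs <- elementCentres(jac, head)
  dx <- numeric(ncol(jac@logamp))
  sel <- rowSums(sweep(ctrs, 2, centre)^2) <= radius^2
  dx[sel] <- deltaMuA
  dx
}

#' Element centroids behind the columns of a Jacobian
#'
#' @param jac \code{JacobianMatrix}.
#' @param geometry the owning \code{VoxelHeadModel} (MC) or
#'   \code{TetMeshModel} (DA).
#' @return matrix n_e x 3, mm.
#' @export
elementCentres <- function(jac, geometry) {
  if (is(geometry, "VoxelHeadModel")) {
    ijk <- arrayInd(jac@elements, dim(geometry@labels))
    sweep(sweep(ijk - 0.5, 2, rep(geometry@spacing, 3), `*`), 2,
          geometry@origin, `+`)
  } else if (is(geometry, "TetMeshModel")) {
    tt <- geometry@tets[jac@elements, , drop = FALSE]
    (geometry@nodes[tt[, 1], , drop = FALSE] +
     geometry@nodes[tt[, 2], , drop = FALSE] +
     geometry@nodes[tt[, 3], , drop = FALSE] +
     geometry@nodes[tt[, 4], , drop = FALSE]) / 4
  } else stop("unsupported geometry")
}

#' Tissue-wise absorption sweep of visibility ratios
#'
#' For a grid of relative absorption changes in one tissue, recomputes the
#' reference measurement under the change (Monte Carlo re-weighting; no
#' re-transport) and evaluates the visibility ratio against fixed
#' approximation-error statistics, separately for ln A and phase.
#'
#' @param mv reference \code{MeasurementVector} with records.
#' @param head reference \code{VoxelHeadModel}.
#' @param optics tissue table.
#' @param tissue tissue name.
#' @param grid relative changes (default +/- 20\% to 90\% in 5\% steps).
#' @param statsLogamp,statsPhase \code{ErrorStatistics} for the two
#'   quantities.
#' @return data.frame with columns \code{change, logamp, phase}.
#' @export
tissueSweep <- function(mv, head, optics, tissue,
                        grid = c(-rev(seq(0.2, 0.9, by = 0.05)),
                                 seq(0.2, 0.9, by = 0.05)),
                        statsLogamp, statsPhase) {
  y0l <- measurementQuantity(mv, "logamp")
  y0p <- measurementQuantity(mv, "phase")
  out <- data.frame(change = grid, logamp = NA_real_, phase = NA_real_)
  for (i in seq_along(grid)) {
    mua <- perturbTissue(head, optics, tissue, grid[i])
    mvp <- mcReweight(mv, mua)
    out$logamp[i] <- signalVisibility(measurementQuantity(mvp, "logamp") - y0l,
                                      statsLogamp)$ratio
    out$phase[i] <- signalVisibility(measurementQuantity(mvp, "phase") - y0p,
                                     statsPhase)$ratio
  }
  out
}

#' Depth-sensitivity profile along a cylinder
#'
#' For one source-detector pair, drills a narrow cylinder from the surface
#' midpoint between the optodes along the inward normal and evaluates the
#' Jacobian row against a unit absorption perturbation (1 mm^-1) of each
#' cylinder slice in turn.
#'
#' @param jac \code{JacobianMatrix}.
#' @param geometry \code{VoxelHeadModel} or \code{TetMeshModel} behind the
#'   columns.
#' @param row which Jacobian row (source-detector pair) to profile.
#' @param start surface point where the cylinder enters, mm.
#' @param direction inward axis (normalized internally).
#' @param radius cylinder radius, mm (default 2.5).
#' @param depth total depth, mm (default 20).
#' @param slice slice thickness, mm (default 1).
#' @return data.frame with \code{depth} (slice midpoints), \code{logamp},
#'   \code{phase}, \code{nElements}.
#' @export
cylinderSensitivity <- function(jac, geometry, row, start, direction,
                                radius = 2.5, depth = 20, slice = 1) {
  u <- direction / sqrt(sum(direction^2))
  ctrs <- elementCentres(jac, geometry)
  rel <- sweep(ctrs, 2, start)
  ax <- as.numeric(rel %*% u)
  rad2 <- rowSums(rel^2) - ax^2
  edges <- seq(0, depth, by = slice)
  mids <- edges[-1] - slice / 2
  la <- jac@logamp[row, ]
  ph <- jac@phase[row, ]
  inCyl <- rad2 <= radius^2
  out <- data.frame(depth = mids, logamp = NA_real_, phase = NA_real_,
                    nElements = 0L)
  for (i in seq_along(mids)) {
    sel <- inCyl & ax >= edges[i] & ax < edges[i + 1]
    out$logamp[i] <- sum(la[sel])
    out$phase[i] <- sum(ph[sel])
    out$nElements[i] <- sum(sel)
  }
  out
}
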