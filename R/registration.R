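# Linear registration of atlas heads to a reference exterior.
#
# Two-step linear registration: (1) a 3x4 affine minimizing the weighted
# registration error RE = SRE + gamma1*LRE1 + gamma2*LRE2 over the cranial
# points (surface term + two landmark terms, solved as a weighted linear
# least-squares problem about the nasion), (2) additional per-axis
# anisotropic scaling fitted to closest-point pairs in the probe region.
# The warped subject is then resampled onto the reference grid and the
# reference scalp-and-skull shell is filled with the warped interior,
# subject to the quality-control rules.

#' Weighted affine registration of cranial point sets
#'
#' Solves the 12-parameter affine transform (about the nasion: subject Nz
#' is first matched to reference Nz) minimizing
#' RE = SRE + gamma1 LRE1 + gamma2 LRE2, where SRE is the mean squared
#' distance over all 254 cranial points, LRE1 over {Iz, Nz}, and LRE2 over
#' {LPA, RPA}. The stacked least-squares system weights each block by
#' 1/sqrt(number of observations) times sqrt(gamma); the landmark rows are
#' re-stacked in addition to their appearance in the surface block.
#'
#' @param subject,reference \code{CranialPointSet}s with matching point
#'   ordering.
#' @param gamma1 weight of the Iz/Nz landmark term (default 0.45).
#' @param gamma2 weight of the LPA/RPA landmark term (default 0.55).
#' @param restackLandmarks if TRUE (default) the landmark rows appear both
#'   in the surface block and in their own blocks (254 + 4 stacked
#'   points); FALSE uses the pure 254-point system with reweighted
#'   landmark rows.
#' @return list with \code{transform} (3 x 4 matrix mapping homogeneous
#'   subject coordinates to reference coordinates, absolute frame) and
#'   \code{report} (list: \code{RE, SRE, LRE1, LRE2} after, \code{RE0}
#'   before, \code{gamma1, gamma2}, \code{rmseBefore, rmseAfter}).
#' @export
affineFit <- function(subject, reference, gamma1 = 0.45, gamma2 = 0.55,
                      restackLandmarks = TRUE) {
  if (gamma1 < 0 || gamma2 < 0) stop("gamma weights must be >= 0")
  ps <- allPoints(subject)
  pr <- allPoints(reference)
  if (nrow(ps) != nrow(pr)) stop("point sets differ in size")
  nzS <- landmarkPoints(subject)["Nz", ]
  nzR <- landmarkPoints(reference)["Nz", ]
  X <- sweep(ps, 2, nzS)
  Yr <- sweep(pr, 2, nzR)
  nS <- nrow(X)
  lmIdx <- nrow(surfacePoints(subject)) + 1:5
  names(lmIdx) <- rownames(landmarkPoints(subject))

  wS <- rep(sqrt(1 / nS), nS)
  if (restackLandmarks) {
    i1 <- lmIdx[c("Iz", "Nz")]
    i2 <- lmIdx[c("LPA", "RPA")]
    rows <- c(seq_len(nS), i1, i2)
    w <- c(wS, rep(sqrt(gamma1 / 2), 2), rep(sqrt(gamma2 / 2), 2))
  } else {
    rows <- seq_len(nS)
    w <- wS
    w[lmIdx[c("Iz", "Nz")]] <- sqrt(1 / nS + gamma1 / 2)
    w[lmIdx[c("LPA", "RPA")]] <- sqrt(1 / nS + gamma2 / 2)
  }
  A <- cbind(X[rows, , drop = FALSE], 1) * w
  Tm <- matrix(0, 3, 4)
  for (c_ in 1:3) {
    qrA <- qr(A)
    if (qrA$rank < 4) stop("degenerate point configuration: rank-deficient")
    Tm[c_, ] <- qr.coef(qrA, Yr[rows, c_] * w)
  }
  if (det(Tm[, 1:3]) <= 0)
    stop("fitted affine transform is orientation-reversing; rejected")

  evalRE <- function(M) {
    mapped <- X %*% t(M[, 1:3]) + matrix(M[, 4], nS, 3, byrow = TRUE)
    d2 <- rowSums((mapped - Yr)^2)
    SRE <- mean(d2)
    LRE1 <- mean(d2[lmIdx[c("Iz", "Nz")]])
    LRE2 <- mean(d2[lmIdx[c("LPA", "RPA")]])
    list(SRE = SRE, LRE1 = LRE1, LRE2 = LRE2,
         RE = SRE + gamma1 * LRE1 + gamma2 * LRE2,
         rmse = sqrt(mean(d2)))
  }
  id <- cbind(diag(3), 0)
  before <- evalRE(id)
  after <- evalRE(Tm)

  # absolute-frame transform: y = A x + (t + nzR - A nzS)
  Tabs <- Tm
  Tabs[, 4] <- Tm[, 4] + nzR - Tm[, 1:3] %*% nzS
  list(transform = Tabs,
       report = list(RE = after$RE, SRE = after$SRE, LRE1 = after$LRE1,
                     LRE2 = after$LRE2, RE0 = before$RE,
                     gamma1 = gamma1, gamma2 = gamma2,
                     rmseBefore = before$rmse, rmseAfter = after$rmse))
}

#' Apply a 3 x 4 affine transform to points
#'
#' @param points matrix n x 3.
#' @param transform 3 x 4 matrix.
#' @return transformed n x 3 matrix.
#' @export
applyTransform <- function(points, transform) {
  points %*% t(transform[, 1:3]) +
    matrix(transform[, 4], nrow(points), 3, byrow = TRUE)
}

#' Compose an anisotropic scaling about a fixed point with a transform
#'
#' @param transform 3 x 4 affine.
#' @param scales length-3 per-axis factors.
#' @param centre point held fixed by the scaling.
#' @return composed 3 x 4 transform (scaling applied after
#'   \code{transform}).
#' @export
composeScaling <- function(transform, scales, centre) {
  S <- diag(scales)
  A <- S %*% transform[, 1:3]
  t_ <- S %*% (transform[, 4] - centre) + centre
  cbind(A, as.numeric(t_))
}

#' Anisotropic probe-region scaling
#'
#' After the affine fit, finds the subject surface points lying in the
#' probe region (within \code{radius} of \code{probeCentre}), pairs each
#' with its closest reference surface point, and solves three per-axis
#' scale factors about the reference nasion minimizing the squared
#' distances of the pairs. The probe-region RMSE never increases.
#'
#' @param subjectPts subject surface points after the affine fit (n x 3).
#' @param referencePts reference surface points (m x 3).
#' @param probeCentre centre of the probe region, mm.
#' @param radius probe-region radius, mm (default 60).
#' @param centre fixed point of the scaling (reference Nz).
#' @return list with \code{scales}, \code{rmseBefore}, \code{rmseAfter}.
#' @export
probeRegionScaling <- function(subjectPts, referencePts, probeCentre,
                               radius = 60, centre) {
  d2 <- rowSums(sweep(subjectPts, 2, probeCentre)^2)
  sel <- d2 <= radius^2
  if (!any(sel)) stop("probe region contains no subject surface points")
  P <- subjectPts[sel, , drop = FALSE]
  nn <- .nn_index_cpp(P, referencePts)
  Q <- referencePts[nn, , drop = FALSE]
  rmse0 <- sqrt(mean(rowSums((P - Q)^2)))
  Pc <- sweep(P, 2, centre)
  Qc <- sweep(Q, 2, centre)
  s <- vapply(1:3, function(a) {
    den <- sum(Pc[, a]^2)
    if (den == 0) 1 else sum(Pc[, a] * Qc[, a]) / den
  }, numeric(1))
  P2 <- sweep(Pc, 2, s, `*`)
  rmse1 <- sqrt(mean(rowSums((P2 - Qc)^2)))
  list(scales = s, rmseBefore = rmse0, rmseAfter = rmse1)
}

#' Resample a head model through an affine transform onto a reference grid
#'
#' Nearest-label resampling: each reference voxel centre is pulled back
#' through the inverse transform and takes the label of the containing
#' subject voxel (0 outside). No new labels are created.
#'
#' @param head subject \code{VoxelHeadModel}.
#' @param transform 3 x 4 affine mapping subject to reference coordinates.
#' @param reference \code{VoxelHeadModel} defining the output grid.
#' @return \code{VoxelHeadModel} on the reference grid.
#' @export
resampleHead <- function(head, transform, reference) {
  d <- dim(reference@labels)
  h <- reference@spacing
  A <- transform[, 1:3]
  t_ <- transform[, 4]
  Ainv <- solve(A)
  ijk <- arrayInd(seq_len(prod(d)), d)
  ctrs <- sweep(ijk - 0.5, 2, c(h, h, h), `*`)
  ctrs <- sweep(ctrs, 2, reference@origin, `+`)
  src <- sweep(ctrs, 2, t_) %*% t(Ainv)
  sIjk <- floor(sweep(src, 2, head@origin) / head@spacing) + 1
  ds <- dim(head@labels)
  ok <- sIjk[, 1] >= 1 & sIjk[, 1] <= ds[1] &
        sIjk[, 2] >= 1 & sIjk[, 2] <= ds[2] &
        sIjk[, 3] >= 1 & sIjk[, 3] <= ds[3]
  out <- integer(prod(d))
  lin <- (sIjk[ok, 3] - 1) * ds[1] * ds[2] + (sIjk[ok, 2] - 1) * ds[1] +
         sIjk[ok, 1]
  out[ok] <- as.vector(head@labels)[lin]
  new("VoxelHeadModel", labels = array(out, d), spacing = h,
      origin = reference@origin)
}

# shell of labelled voxels within `thickness` of the exterior background
.shellMask <- function(head, thickness) {
  lab <- head@labels > 0
  d <- dim(lab)
  steps <- max(1L, ceiling(thickness / head@spacing))
  outer <- !lab
  grown <- outer
  for (s in seq_len(steps)) {
    g <- grown
    g[-1, , ] <- g[-1, , ] | grown[-d[1], , ]
    g[-d[1], , ] <- g[-d[1], , ] | grown[-1, , ]
    g[, -1, ] <- g[, -1, ] | grown[, -d[2], ]
    g[, -d[2], ] <- g[, -d[2], ] | grown[, -1, ]
    g[, , -1] <- g[, , -1] | grown[, , -d[3]]
    g[, , -d[3]] <- g[, , -d[3]] | grown[, , -1]
    grown <- g
  }
  lab & grown
}

#' Fill the reference scalp-and-skull shell with a warped interior
#'
#' Takes the reference extracerebral shell mask (labelled voxels within
#' \code{shellThickness} of the exterior, forced to S&S), keeps the
#' reference exterior boundary exactly, and fills the interior with the
#' warped subject labels: interior voxels that the warped model leaves
#' empty become S&S; warped tissue outside the reference head is cut.
#' Quality control: (1) within the probe region, the nonzero-region
#' mismatch between the warped and reference models may involve only S&S
#' and CSF-1, with at most \code{csfTolerance} mm^3 of CSF-1 difference;
#' (2) no white-matter voxels may be removed from the probe region by the
#' cut. A violation returns \code{accepted = FALSE} with the failing rule.
#'
#' @param reference reference \code{VoxelHeadModel}.
#' @param warped subject resampled onto the reference grid
#'   (\code{\link{resampleHead}}).
#' @param shellThickness S&S mask thickness, mm (default 2).
#' @param probeMask logical array on the reference grid marking the probe
#'   region (e.g. from \code{\link{probeRegionMask}}); NULL disables QC.
#' @param csfTolerance rule-(1) CSF-1 mismatch tolerance, mm^3 (default
#'   10).
#' @return list with \code{head} (filled \code{VoxelHeadModel}),
#'   \code{accepted}, \code{failedRule} (0 if accepted),
#'   \code{voxelsChanged} (per-tissue mm^3 changed inside the head),
#'   \code{gmLost} (mm^3 of GM cut outside the reference head in the probe
#'   region).
#' @export
fillReferenceShell <- function(reference, warped, shellThickness = 2,
                               probeMask = NULL, csfTolerance = 10) {
  if (!identical(dim(reference@labels), dim(warped@labels)))
    stop("warped model must live on the reference grid")
  h <- reference@spacing
  vvol <- h^3
  refLab <- reference@labels
  wLab <- warped@labels
  shell <- .shellMask(reference, shellThickness)
  inHead <- refLab > 0

  failedRule <- 0L
  if (!is.null(probeMask)) {
    pm <- probeMask
    mismatch <- (wLab > 0) != inHead
    mm <- mismatch & pm
    labsAt <- ifelse(wLab[mm] > 0, wLab[mm], refLab[mm])
    bad <- !(labsAt %in% .TISSUES[c("SS", "CSF1")])
    if (any(bad)) failedRule <- 1L
    csfDiff <- sum(labsAt == .TISSUES["CSF1"]) * vvol
    if (csfDiff > csfTolerance) failedRule <- 1L
    wmCut <- wLab == .TISSUES["WM"] & !inHead & pm
    if (any(wmCut)) failedRule <- 2L
  }

  out <- wLab
  out[!inHead] <- 0L                     # cut protrusions
  gap <- inHead & out == 0L
  out[gap] <- .TISSUES["SS"]             # interior cavities become S&S
  out[shell] <- .TISSUES["SS"]           # exact reference shell

  changed <- out != refLab & inHead
  perTissue <- vapply(names(.TISSUES), function(tn)
    sum(changed & out == .TISSUES[[tn]]) * vvol, numeric(1))
  gmLost <- if (is.null(probeMask)) NA_real_ else
    sum(wLab == .TISSUES["GM"] & !inHead & probeMask) * vvol

  list(head = new("VoxelHeadModel", labels = out, spacing = h,
                  origin = reference@origin),
       accepted = failedRule == 0L, failedRule = failedRule,
       voxelsChanged = perTissue, gmLost = gmLost)
}

#' Probe-region mask on a head grid
#'
#' Logical array marking voxels within \code{radius} of the probe
#' centroid.
#'
#' @param head \code{VoxelHeadModel} defining the grid.
#' @param layout \code{OptodeLayout}.
#' @param radius region radius, mm (default 60).
#' @return logical array with the head's dimensions.
#' @export
probeRegionMask <- function(head, layout, radius = 60) {
  d <- dim(head@labels)
  ctr <- colMeans(rbind(sourcePositions(layout), detectorPositions(layout)))
  ijk <- arrayInd(seq_len(prod(d)), d)
  p <- sweep(sweep(ijk - 0.5, 2, rep(head@spacing, 3), `*`), 2,
             head@origin, `+`)
  array(rowSums(sweep(p, 2, ctr)^2) <= radius^2, d)
}

#' Register one subject to the reference and fill the shell
#'
#' Convenience pipeline for one subject: affine fit on cranial points,
#' probe-region anisotropic scaling on the surface points, resampling onto
#' the reference grid, shell filling and QC.
#'
#' @param subjectHead,subjectPoints subject model and cranial points.
#' @param referenceHead,referencePoints reference model and cranial
#'   points.
#' @param layout reference \code{OptodeLayout} (defines the probe region).
#' @param probeRadius probe-region radius, mm.
#' @param shellThickness S&S mask thickness, mm.
#' @param gamma1,gamma2 landmark weights.
#' @param csfTolerance QC rule-(1) tolerance, mm^3.
#' @return list: \code{head} (filled model), \code{accepted},
#'   \code{failedRule}, \code{affine} (report), \code{scaling} (report),
#'   \code{transform} (final 3 x 4), \code{gmLost}.
#' @export
registerSubject <- function(subjectHead, subjectPoints, referenceHead,
                            referencePoints, layout, probeRadius = 60,
                            shellThickness = 2, gamma1 = 0.45,
                            gamma2 = 0.55, csfTolerance = 10) {
  af <- affineFit(subjectPoints, referencePoints, gamma1, gamma2)
  warpedPts <- applyTransform(allPoints(subjectPoints), af$transform)
  probeCtr <- colMeans(rbind(sourcePositions(layout),
                             detectorPositions(layout)))
  nzR <- landmarkPoints(referencePoints)["Nz", ]
  sc <- probeRegionScaling(warpedPts, allPoints(referencePoints), probeCtr,
                           radius = probeRadius, centre = nzR)
  Tm <- composeScaling(af$transform, sc$scales, nzR)
  warped <- resampleHead(subjectHead, Tm, referenceHead)
  pm <- probeRegionMask(referenceHead, layout, probeRadius)
  fill <- fillReferenceShell(referenceHead, warped, shellThickness,
                             probeMask = pm, csfTolerance = csfTolerance)
  list(head = fill$head, accepted = fill$accepted,
       failedRule = fill$failedRule, affine = af$report, scaling = sc,
       transform = Tm, gmLost = fill$gmLost,
       voxelsChanged = fill$voxelsChanged)
}

#' Majority-label downsampling of a head model
#'
#' Blocks of \code{factor}^3 voxels collapse to their most frequent
#' nonzero label (background wins only if it holds the strict majority of
#' the block), giving the coarser simulation grid.
#'
#' @param head \code{VoxelHeadModel}.
#' @param factor integer downsampling factor.
#' @return \code{VoxelHeadModel} at spacing \code{factor * spacing}.
#' @export
downsampleHead <- function(head, factor = 2L) {
  factor <- as.integer(factor)
  if (factor < 2L) return(head)
  d <- dim(head@labels)
  nd <- d %/% factor
  lab <- head@labels[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                     seq_len(nd[3] * factor)]
  # block decomposition: dims (f, nd1, f, nd2, f, nd3) index
  # (within-x, block-x, within-y, block-y, within-z, block-z)
  blockCounts <- function(mask) {
    arr <- array(as.integer(mask),
                 c(factor, nd[1], factor, nd[2], factor, nd[3]))
    arr <- aperm(arr, c(1, 3, 5, 2, 4, 6))
    colSums(matrix(arr, nrow = factor^3))
  }
  counts <- vapply(0:5, function(L) blockCounts(lab == L),
                   numeric(prod(nd)))
  # majority among tissue labels; background only when strictly dominant
  tissue <- counts[, 2:6, drop = FALSE]
  best <- max.col(tissue, ties.method = "first")
  bestCount <- tissue[cbind(seq_along(best), best)]
  bg <- counts[, 1L]
  out <- ifelse(bestCount == 0L | bg > factor^3 / 2, 0L, best)
  new("VoxelHeadModel", labels = array(as.integer(out), nd),
      spacing = head@spacing * factor, origin = head@origin)
}
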