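# Two-compartment CSF segmentation.
#
# The outer CSF is split into a semidiffusive subarachnoid layer (CSF-1)
# and clearer sulcal CSF (CSF-2, pooled with the ventricles) by solving a
# Laplace problem on the CSF domain D = Omega_CSF \ closure(Omega_LF):
# u = 0 where D touches the brain (GM/WM), u = 1 where it touches the
# skull or the longitudinal-fissure plate, homogeneous Neumann within an
# `a`-neighbourhood of junctions of the two Dirichlet sets, and Delta u = 0
# inside. CSF above the chosen level set (u > theta) stays subarachnoid,
# the rest becomes sulcal/ventricular CSF.

#' Build the CSF Laplace domain of a head model
#'
#' Meshes the outer-CSF voxels (label CSF-1) minus a one-voxel-thick plate
#' along the longitudinal fissure (x = head-centroid midline, above the
#' bottom of the cerebrum), and tags every boundary facet: Dirichlet 0
#' where the facet touches grey or white matter, Dirichlet 1 where it
#' touches anything else (scalp-and-skull, the fissure plate, ventricles,
#' background), Neumann where it lies within distance \code{a} of a
#' junction of the two Dirichlet sets.
#'
#' @param head a \code{VoxelHeadModel}.
#' @param a Neumann buffer radius, mm (default 1); with \code{a = 0} a
#'   genuine junction raises an error, since adjacent Dirichlet-0 and
#'   Dirichlet-1 boundary sections are not permitted.
#' @param fissurePlate include the longitudinal-fissure plate (default
#'   TRUE).
#' @return a list of class \code{"csfDomain"}: \code{mesh},
#'   \code{dirichlet} (node values, NA = free), \code{neumannNodes},
#'   \code{head}, \code{a}.
#' @export
buildCsfDomain <- function(head, a = 1.0, fissurePlate = TRUE) {
  lab <- head@labels
  d <- dim(lab)
  h <- head@spacing
  csf <- lab == .TISSUES["CSF1"]
  if (!any(csf)) stop("head contains no outer CSF (CSF-1) voxels")

  plate <- array(FALSE, d)
  if (fissurePlate) {
    ctr <- .headCentroid(head)
    midI <- floor((ctr[1] - head@origin[1]) / h) + 1
    brain <- lab == .TISSUES["GM"] | lab == .TISSUES["WM"]
    if (any(brain)) {
      zIdx <- arrayInd(which(brain), d)[, 3]
      zBottom <- min(zIdx)
      plate[midI, , ] <- TRUE
      plate[, , seq_len(max(zBottom - 1, 0))] <- FALSE
    }
  }
  domainVox <- csf & !plate
  if (!any(domainVox)) stop("CSF domain is empty after removing the plate")

  sub <- head
  sub@labels <- array(ifelse(domainVox, .TISSUES["CSF1"], 0L), d)
  mesh <- voxelToMesh(sub)
  tetvox <- attr(mesh, "tetVoxel")

  bfo <- .boundaryFacesFast(mesh@tets, withOwner = TRUE)
  bf <- bfo$faces
  own <- bfo$owner
  # neighbour voxel across each axis-aligned boundary face
  cent <- (mesh@nodes[bf[, 1], , drop = FALSE] +
           mesh@nodes[bf[, 2], , drop = FALSE] +
           mesh@nodes[bf[, 3], , drop = FALSE]) / 3
  ownVox <- tetvox[own]
  ownIjk <- arrayInd(ownVox, d)
  ownCtr <- head@origin + (ownIjk - 0.5) * h
  off <- cent - ownCtr
  ax <- max.col(abs(off))
  sgn <- sign(off[cbind(seq_len(nrow(off)), ax)])
  nbIjk <- ownIjk
  nbIjk[cbind(seq_len(nrow(nbIjk)), ax)] <-
    nbIjk[cbind(seq_len(nrow(nbIjk)), ax)] + sgn
  inGrid <- nbIjk[, 1] >= 1 & nbIjk[, 1] <= d[1] &
            nbIjk[, 2] >= 1 & nbIjk[, 2] <= d[2] &
            nbIjk[, 3] >= 1 & nbIjk[, 3] <= d[3]
  nbLab <- rep(0L, nrow(bf))
  nbLin <- (nbIjk[inGrid, 3] - 1) * d[1] * d[2] +
           (nbIjk[inGrid, 2] - 1) * d[1] + nbIjk[inGrid, 1]
  nbLab[inGrid] <- as.vector(lab)[nbLin]
  nbPlate <- rep(FALSE, nrow(bf))
  nbPlate[inGrid] <- as.vector(plate)[nbLin]

  isBrain <- nbLab %in% .TISSUES[c("GM", "WM")] & !nbPlate
  faceVal <- ifelse(isBrain, 0, 1) # Dirichlet data f per facet

  n <- nrow(mesh@nodes)
  on0 <- rep(FALSE, n); on1 <- rep(FALSE, n)
  on0[as.vector(bf[faceVal == 0, ])] <- TRUE
  on1[as.vector(bf[faceVal == 1, ])] <- TRUE
  junction <- which(on0 & on1)

  dir <- rep(NA_real_, n)
  dir[on0] <- 0
  dir[on1] <- 1
  dir[junction] <- NA # conflicting values cannot be imposed

  neumann <- integer(0)
  if (length(junction)) {
    if (a <= 0)
      stop("Dirichlet-0 and Dirichlet-1 sections meet (", length(junction),
           " junction nodes) and the Neumann buffer is zero; ",
           "increase `a`")
    bnodes <- which(on0 | on1)
    nn <- .nn_index_cpp(mesh@nodes[bnodes, , drop = FALSE],
                        mesh@nodes[junction, , drop = FALSE])
    dj <- sqrt(rowSums((mesh@nodes[bnodes, , drop = FALSE] -
                        mesh@nodes[junction[nn], , drop = FALSE])^2))
    release <- bnodes[dj < a]
    dir[release] <- NA
    neumann <- sort(unique(c(release, junction)))
  }
  if (!any(!is.na(dir)))
    stop("all boundary conditions released to Neumann: problem is singular")

  structure(list(mesh = mesh, dirichlet = dir, neumannNodes = neumann,
                 head = head, a = a, plate = plate),
            class = "csfDomain")
}

#' @export
print.csfDomain <- function(x, ...) {
  cat(sprintf(
    "csfDomain: %d nodes (%d Dirichlet-0, %d Dirichlet-1, %d Neumann-released)\n",
    length(x$dirichlet), sum(x$dirichlet == 0, na.rm = TRUE),
    sum(x$dirichlet == 1, na.rm = TRUE), length(x$neumannNodes)))
  invisible(x)
}

#' Solve the Laplace problem on a CSF domain
#'
#' P1 FEM solution of Delta u = 0 with the mixed Dirichlet/Neumann data of
#' the domain. The discrete maximum principle keeps the solution within
#' the Dirichlet range up to numerical tolerance.
#'
#' @param domain from \code{\link{buildCsfDomain}}.
#' @return numeric vector of node values (a harmonic field in [0, 1]).
#' @export
solveCsfLaplace <- function(domain) {
  mesh <- domain$mesh
  n <- nrow(mesh@nodes)
  ones <- rep(1, nrow(mesh@tets))
  K <- .assembleVolume(mesh, stiffCoef = ones, massCoef = 0 * ones)$S
  known <- which(!is.na(domain$dirichlet))
  if (!length(known)) stop("no Dirichlet nodes: singular Laplace problem")
  free <- setdiff(seq_len(n), known)
  u <- numeric(n)
  u[known] <- domain$dirichlet[known]
  if (length(free)) {
    Kff <- K[free, free, drop = FALSE]
    rhs <- -as.numeric(K[free, known, drop = FALSE] %*% u[known])
    ch <- Matrix::Cholesky(forceSymmetric(Kff), LDL = FALSE, super = NA)
    u[free] <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  }
  u
}

#' Relabel CSF voxels by thresholding the harmonic field
#'
#' Interpolates the harmonic field at the CSF voxel centres (each voxel
#' centre lies on the shared main diagonal of its six Kuhn tetrahedra, so
#' the P1 value is the mean of the two diagonal corner values; plate
#' voxels outside the mesh take the nearest node value) and relabels:
#' u > theta stays subarachnoid CSF-1, u <= theta becomes sulcal CSF-2.
#' Ventricles remain CSF-2; other tissues are untouched, so the total CSF
#' voxel count is conserved.
#'
#' @param field node values from \code{\link{solveCsfLaplace}}.
#' @param domain the \code{csfDomain} the field was solved on.
#' @param theta level-set threshold in (0, 1), default 0.6. Small theta
#'   gives a thick subarachnoid layer reaching into the sulci; large theta
#'   a thin one.
#' @return the relabelled \code{VoxelHeadModel}.
#' @export
thresholdSplit <- function(field, domain, theta = 0.6) {
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  head <- domain$head
  lab <- head@labels
  d <- dim(lab)
  h <- head@spacing
  mesh <- domain$mesh
  tetvox <- attr(mesh, "tetVoxel")
  # voxel centre value: mean of the two Kuhn-diagonal corners
  # (tet 1 of each voxel block has node1 = corner (0,0,0), node4 = (1,1,1))
  firstTet <- seq(1, nrow(mesh@tets), by = 6L)
  voxOf <- tetvox[firstTet]
  tt <- mesh@tets[firstTet, , drop = FALSE]
  csum <- matrix(rowSums(mesh@nodes)[tt], nrow(tt), 4)
  lowCorner <- tt[cbind(seq_len(nrow(tt)), max.col(-csum))]
  highCorner <- tt[cbind(seq_len(nrow(tt)), max.col(csum))]
  uvox <- (field[lowCorner] + field[highCorner]) / 2
  uAll <- rep(NA_real_, prod(d))
  uAll[voxOf] <- uvox

  csfIdx <- which(as.vector(lab == .TISSUES["CSF1"]))
  missing <- csfIdx[is.na(uAll[csfIdx])] # plate / slack voxels
  if (length(missing)) {
    ijk <- arrayInd(missing, d)
    ctrs <- head@origin + (ijk - 0.5) * h
    nn <- .nn_index_cpp(ctrs, mesh@nodes)
    uAll[missing] <- field[nn]
  }
  newLab <- as.vector(lab)
  sel <- csfIdx[uAll[csfIdx] <= theta]
  newLab[sel] <- .TISSUES["CSF2"]
  head@labels <- array(as.integer(newLab), d)
  head
}

#' Full CSF two-compartment split
#'
#' Convenience wrapper: build the domain, solve the Laplace problem and
#' threshold at \code{theta}.
#'
#' @inheritParams buildCsfDomain
#' @inheritParams thresholdSplit
#' @return the relabelled \code{VoxelHeadModel}.
#' @export
csfSplit <- function(head, theta = 0.6, a = 1.0, fissurePlate = TRUE) {
  dom <- buildCsfDomain(head, a = a, fissurePlate = fissurePlate)
  u <- solveCsfLaplace(dom)
  thresholdSplit(u, dom, theta = theta)
}
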