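#' @import methods
#' @useDynLib fdot, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom Matrix sparseMatrix Diagonal forceSymmetric
#' @importFrom stats rnorm runif setNames quantile sd
#' @importFrom utils read.csv write.csv head tail
NULL

# Tissue label coding used throughout: 0 = background (air),
# 1 = scalp & skull (S&S), 2 = subarachnoid CSF (CSF-1),
# 3 = sulcal/ventricular CSF (CSF-2), 4 = grey matter, 5 = white matter.
.TISSUES <- c(SS = 1L, CSF1 = 2L, CSF2 = 3L, GM = 4L, WM = 5L)

#' Tissue label codes
#'
#' Integer codes of the five head tissue compartments used in label volumes:
#' \code{SS} (scalp and skull), \code{CSF1} (subarachnoid cerebrospinal
#' fluid), \code{CSF2} (CSF in the sulci and ventricles), \code{GM} (grey
#' matter) and \code{WM} (white matter). Voxel value 0 is background.
#'
#' @return Named integer vector of length 5.
#' @export
tissueLabels <- function() .TISSUES

#' Speed of light in vacuum, mm per ns
#' @return Numeric scalar, 299.792458 mm/ns.
#' @export
speedOfLight <- function() 299.792458

#' Labelled voxel head model
#'
#' A segmented head as a 3D integer label array on an isotropic voxel grid.
#' Voxel \code{(i,j,k)} occupies the cube
#' \code{origin + (c(i,j,k)-1)*spacing .. origin + c(i,j,k)*spacing};
#' its centre is \code{origin + (c(i,j,k)-0.5)*spacing}. Axis convention:
#' y runs from inion to nasion, x approximately from LPA to RPA, z vertical.
#'
#' @slot labels 3D integer array; 0 = background, otherwise tissue codes
#'   (see \code{\link{tissueLabels}}).
#' @slot spacing isotropic voxel edge length, mm.
#' @slot origin position of the grid corner, mm (length 3).
#' @export
setClass("VoxelHeadModel",
  representation(labels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "labels must be a 3D array")
    if (!is.integer(object@labels))
      msg <- c(msg, "labels must be an integer array")
    if (length(object@spacing) != 1L || object@spacing <= 0)
      msg <- c(msg, "spacing must be a single positive number")
    if (length(object@origin) != 3L)
      msg <- c(msg, "origin must have length 3")
    bad <- setdiff(unique(as.vector(object@labels)), c(0L, .TISSUES))
    if (length(bad))
      msg <- c(msg, paste("unknown labels:", paste(bad, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
  })

#' Cranial point set
#'
#' Dense cranial surface points (10-5 style grid) plus the five anatomical
#' landmarks Iz, Nz, LPA, RPA, Cz, all in mm in the head frame.
#'
#' @slot surface numeric matrix (n x 3), named rows.
#' @slot landmarks numeric matrix (5 x 3) with rownames
#'   \code{c("Iz","Nz","LPA","RPA","Cz")}.
#' @export
setClass("CranialPointSet",
  representation(surface = "matrix", landmarks = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@surface) != 3L) msg <- c(msg, "surface must be n x 3")
    if (!identical(rownames(object@landmarks), c("Iz", "Nz", "LPA", "RPA", "Cz")))
      msg <- c(msg, "landmarks must have rows Iz, Nz, LPA, RPA, Cz")
    if (is.null(msg)) TRUE else msg
  })

#' Optode layout
#'
#' Source and detector patch centres on the head boundary, the common patch
#' radius, and the launch target (centre of the sphere fitted to the optode
#' positions; photons are launched toward it).
#'
#' @slot sources numeric matrix (n_s x 3), mm.
#' @slot detectors numeric matrix (n_d x 3), mm.
#' @slot patchRadius circular patch radius R, mm (default 1.5).
#' @slot launchTarget centre of the fitted sphere, mm (length 3).
#' @slot fitResidual RMS residual of the sphere fit, mm.
#' @export
setClass("OptodeLayout",
  representation(sources = "matrix", detectors = "matrix",
                 patchRadius = "numeric", launchTarget = "numeric",
                 fitResidual = "numeric"),
  prototype(patchRadius = 1.5, fitResidual = NA_real_),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@sources) != 3L || ncol(object@detectors) != 3L)
      msg <- c(msg, "sources and detectors must be n x 3 matrices")
    if (object@patchRadius <= 0) msg <- c(msg, "patchRadius must be positive")
    if (length(object@launchTarget) != 3L)
      msg <- c(msg, "launchTarget must have length 3")
    if (is.null(msg)) TRUE else msg
  })

#' Labelled tetrahedral mesh model
#'
#' Conforming tetrahedral mesh with one tissue label per element, boundary
#' triangles, and optode patch tags on the boundary. Hosts the P1 FEM
#' discretization of the diffusion approximation and of the CSF Laplace
#' problem.
#'
#' @slot nodes numeric matrix (N x 3), mm.
#' @slot tets integer matrix (M x 4), 1-based node indices.
#' @slot labels integer vector (M), tissue code per element.
#' @slot boundaryFaces integer matrix (F x 3), 1-based node indices of
#'   boundary triangles, outward orientation not guaranteed.
#' @slot faceTags integer vector (F); 0 = plain boundary, k > 0 = patch id.
#' @slot patches data.frame with one row per optode patch: \code{id},
#'   \code{type} ("source"/"detector"), \code{index} (source or detector
#'   number), \code{x,y,z} centre, \code{radius}.
#' @export
setClass("TetMeshModel",
  representation(nodes = "matrix", tets = "matrix", labels = "integer",
                 boundaryFaces = "matrix", faceTags = "integer",
                 patches = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@nodes) != 3L) msg <- c(msg, "nodes must be N x 3")
    if (ncol(object@tets) != 4L) msg <- c(msg, "tets must be M x 4")
    if (length(object@labels) != nrow(object@tets))
      msg <- c(msg, "one label per tetrahedron required")
    if (nrow(object@boundaryFaces) != length(object@faceTags))
      msg <- c(msg, "one tag per boundary face required")
    if (max(object@tets) > nrow(object@nodes))
      msg <- c(msg, "tet indices exceed node count")
    if (is.null(msg)) TRUE else msg
  })

#' Detected-photon record set
#'
#' Sparse per-voxel partial pathlengths and times-of-flight of the photons
#' detected during one Monte Carlo transport run (one source). Under the
#' microscopic Beer-Lambert law the stored trajectories are independent of
#' absorption, so weights and measurements can be recomputed for any
#' absorption field after the fact ("replay").
#'
#' @slot detector integer vector (P), detector index per detected photon.
#' @slot tof numeric vector (P), time of flight, ns.
#' @slot ptr integer vector (P + 1), CSC-style offsets into \code{voxel} /
#'   \code{pathlen} (0-based offsets; photon p owns entries
#'   \code{(ptr[p]+1):ptr[p+1]}).
#' @slot voxel integer vector, 1-based linear voxel indices.
#' @slot pathlen numeric vector, chord lengths, mm.
#' @slot nLaunched number of launched photon packets.
#' @slot nTerminated photons terminated by the time cutoff.
#' @slot dims integer vector (3), voxel grid dimensions.
#' @slot spacing voxel edge, mm.
#' @slot sourceId index of the source that was fired.
#' @slot seed RNG seed of the run (photon p uses stream (seed, p)).
#' @export
setClass("PhotonRecordSet",
  representation(detector = "integer", tof = "numeric", ptr = "numeric",
                 voxel = "integer", pathlen = "numeric",
                 nLaunched = "numeric", nTerminated = "numeric",
                 dims = "integer", spacing = "numeric",
                 sourceId = "integer", seed = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@tof) != length(object@detector))
      msg <- c(msg, "tof and detector lengths differ")
    if (length(object@ptr) != length(object@detector) + 1L)
      msg <- c(msg, "ptr must have length P + 1")
    if (length(object@voxel) != length(object@pathlen))
      msg <- c(msg, "voxel and pathlen lengths differ")
    if (any(object@pathlen < 0)) msg <- c(msg, "pathlengths must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Frequency-domain measurement vector
#'
#' One row per source-detector pair with the complex FD measurement
#' X + iY (per unit source strength), derived log-amplitude ln A and phase
#' (rad), the source-detector separation (mm), and a validity flag; pairs
#' beyond the SDS cutoff or without signal are masked out.
#'
#' @slot data data.frame with columns \code{source, detector, sds, X, Y,
#'   logamp, phase, valid}.
#' @slot f modulation frequency, GHz.
#' @slot solver "mc" or "da".
#' @slot sdsMax SDS inclusion cutoff used for the mask, mm.
#' @export
setClass("MeasurementVector",
  representation(data = "data.frame", f = "numeric", solver = "character",
                 sdsMax = "numeric"),
  validity = function(object) {
    need <- c("source", "detector", "sds", "X", "Y", "logamp", "phase", "valid")
    if (!all(need %in% names(object@data)))
      return(paste("data must contain columns:", paste(need, collapse = ", ")))
    TRUE
  })

#' Absorption Jacobian matrix
#'
#' Derivatives of the log-amplitude and phase of every (unmasked)
#' source-detector pair with respect to the absorption coefficient of every
#' model element (voxel or tetrahedron). Row order matches the owning
#' \code{MeasurementVector}. Units: mm (ln A rows) and rad mm (phase rows)
#' per mm^-1 change in one element; divide by \code{elementVolume} for the
#' per-1-mm^3 normalization.
#'
#' @slot logamp numeric matrix (m x n_e).
#' @slot phase numeric matrix (m x n_e).
#' @slot rows data.frame with columns \code{source, detector, sds}.
#' @slot elements integer vector (n_e): linear voxel indices (MC) or
#'   tetrahedron indices (DA) behind the columns.
#' @slot elementVolume numeric vector (n_e), mm^3.
#' @slot f modulation frequency, GHz.
#' @slot solver "mc" or "da".
#' @export
setClass("JacobianMatrix",
  representation(logamp = "matrix", phase = "matrix", rows = "data.frame",
                 elements = "integer", elementVolume = "numeric",
                 f = "numeric", solver = "character"),
  validity = function(object) {
    msg <- NULL
    if (!all(dim(object@logamp) == dim(object@phase)))
      msg <- c(msg, "logamp and phase must have equal dimensions")
    if (nrow(object@logamp) != nrow(object@rows))
      msg <- c(msg, "one rows entry per Jacobian row required")
    if (length(object@elementVolume) != ncol(object@logamp))
      msg <- c(msg, "one elementVolume per column required")
    if (length(object@elements) != ncol(object@logamp))
      msg <- c(msg, "one element id per column required")
    if (is.null(msg)) TRUE else msg
  })

#' Approximation-error statistics
#'
#' Sample mean and covariance of an ensemble of error vectors (reference
#' minus sample measurements, or Jacobian-mismatch difference errors), with
#' the eigendecomposition of the covariance in descending order and the
#' total standard deviation STD = sqrt(trace).
#'
#' @slot mean numeric vector (m).
#' @slot cov numeric matrix (m x m), symmetric PSD.
#' @slot values eigenvalues, descending (length m, trailing zeros beyond
#'   rank N-1).
#' @slot vectors orthonormal eigenvectors of the positive eigenvalues
#'   (m x r).
#' @slot std sqrt of the covariance trace.
#' @slot n ensemble size N.
#' @slot quantity label, e.g. "logamp:absolute" or "phase:difference".
#' @export
setClass("ErrorStatistics",
  representation(mean = "numeric", cov = "matrix", values = "numeric",
                 vectors = "matrix", std = "numeric", n = "numeric",
                 quantity = "character"),
  validity = function(object) {
    msg <- NULL
    m <- length(object@mean)
    if (!all(dim(object@cov) == c(m, m)))
      msg <- c(msg, "cov must be m x m")
    if (nrow(object@vectors) != m && m > 0)
      msg <- c(msg, "vectors must have m rows")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "VoxelHeadModel", function(object) {
  d <- dim(object@labels)
  tab <- table(factor(object@labels[object@labels > 0],
                      levels = .TISSUES, labels = names(.TISSUES)))
  cat(sprintf("VoxelHeadModel: %d x %d x %d voxels @ %.3g mm\n",
              d[1], d[2], d[3], object@spacing))
  cat("  tissue voxels:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})

setMethod("show", "TetMeshModel", function(object) {
  cat(sprintf("TetMeshModel: %d nodes, %d tets, %d boundary faces, %d patches\n",
              nrow(object@nodes), nrow(object@tets),
              nrow(object@boundaryFaces), nrow(object@patches)))
})

setMethod("show", "PhotonRecordSet", function(object) {
  cat(sprintf(
    "PhotonRecordSet: %d detected / %g launched photons (source %d, seed %g)\n",
    length(object@detector), object@nLaunched, object@sourceId, object@seed))
})

setMethod("show", "MeasurementVector", function(object) {
  cat(sprintf(
    "MeasurementVector [%s]: %d pairs (%d valid), f = %g GHz, SDS < %g mm\n",
    object@solver, nrow(object@data), sum(object@data$valid), object@f,
    object@sdsMax))
})

setMethod("show", "JacobianMatrix", function(object) {
  cat(sprintf("JacobianMatrix [%s]: %d pairs x %d elements, f = %g GHz\n",
              object@solver, nrow(object@logamp), ncol(object@logamp),
              object@f))
})

setMethod("show", "ErrorStatistics", function(object) {
  cat(sprintf("ErrorStatistics [%s]: m = %d, N = %g, STD = %.4g, rank = %d\n",
              object@quantity, length(object@mean), object@n, object@std,
              sum(object@values > 1e-12 * max(object@values, 1e-300))))
})
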