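#' Accessors for the fdot S4 containers
#'
#' Small read-only accessors so downstream code never touches slots
#' directly.
#'
#' @param x an fdot object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("headLabels", function(x) standardGeneric("headLabels"))
#' @rdname accessors
#' @export
setMethod("headLabels", "VoxelHeadModel", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VoxelHeadModel", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "PhotonRecordSet", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("headOrigin", function(x) standardGeneric("headOrigin"))
#' @rdname accessors
#' @export
setMethod("headOrigin", "VoxelHeadModel", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("surfacePoints", function(x) standardGeneric("surfacePoints"))
#' @rdname accessors
#' @export
setMethod("surfacePoints", "CranialPointSet", function(x) x@surface)

#' @rdname accessors
#' @export
setGeneric("landmarkPoints", function(x) standardGeneric("landmarkPoints"))
#' @rdname accessors
#' @export
setMethod("landmarkPoints", "CranialPointSet", function(x) x@landmarks)

#' @rdname accessors
#' @export
setGeneric("allPoints", function(x) standardGeneric("allPoints"))
#' @rdname accessors
#' @export
setMethod("allPoints", "CranialPointSet", function(x)
  rbind(x@surface, x@landmarks))

#' @rdname accessors
#' @export
setGeneric("sourcePositions", function(x) standardGeneric("sourcePositions"))
#' @rdname accessors
#' @export
setMethod("sourcePositions", "OptodeLayout", function(x) x@sources)

#' @rdname accessors
#' @export
setGeneric("detectorPositions", function(x) standardGeneric("detectorPositions"))
#' @rdname accessors
#' @export
setMethod("detectorPositions", "OptodeLayout", function(x) x@detectors)

#' @rdname accessors
#' @export
setGeneric("patchRadius", function(x) standardGeneric("patchRadius"))
#' @rdname accessors
#' @export
setMethod("patchRadius", "OptodeLayout", function(x) x@patchRadius)

#' @rdname accessors
#' @export
setGeneric("launchTarget", function(x) standardGeneric("launchTarget"))
#' @rdname accessors
#' @export
setMethod("launchTarget", "OptodeLayout", function(x) x@launchTarget)

#' @rdname accessors
#' @export
setGeneric("meshNodes", function(x) standardGeneric("meshNodes"))
#' @rdname accessors
#' @export
setMethod("meshNodes", "TetMeshModel", function(x) x@nodes)

#' @rdname accessors
#' @export
setGeneric("meshTets", function(x) standardGeneric("meshTets"))
#' @rdname accessors
#' @export
setMethod("meshTets", "TetMeshModel", function(x) x@tets)

#' @rdname accessors
#' @export
setGeneric("meshLabels", function(x) standardGeneric("meshLabels"))
#' @rdname accessors
#' @export
setMethod("meshLabels", "TetMeshModel", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("meshPatches", function(x) standardGeneric("meshPatches"))
#' @rdname accessors
#' @export
setMethod("meshPatches", "TetMeshModel", function(x) x@patches)

#' @rdname accessors
#' @export
setGeneric("measurementData", function(x) standardGeneric("measurementData"))
#' @rdname accessors
#' @export
setMethod("measurementData", "MeasurementVector", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("modFrequency", function(x) standardGeneric("modFrequency"))
#' @rdname accessors
#' @export
setMethod("modFrequency", "MeasurementVector", function(x) x@f)
#' @rdname accessors
#' @export
setMethod("modFrequency", "JacobianMatrix", function(x) x@f)

#' @rdname accessors
#' @export
setGeneric("jacobianLogamp", function(x) standardGeneric("jacobianLogamp"))
#' @rdname accessors
#' @export
setMethod("jacobianLogamp", "JacobianMatrix", function(x) x@logamp)

#' @rdname accessors
#' @export
setGeneric("jacobianPhase", function(x) standardGeneric("jacobianPhase"))
#' @rdname accessors
#' @export
setMethod("jacobianPhase", "JacobianMatrix", function(x) x@phase)

#' @rdname accessors
#' @export
setGeneric("jacobianRows", function(x) standardGeneric("jacobianRows"))
#' @rdname accessors
#' @export
setMethod("jacobianRows", "JacobianMatrix", function(x) x@rows)

#' @rdname accessors
#' @export
setGeneric("elementVolume", function(x) standardGeneric("elementVolume"))
#' @rdname accessors
#' @export
setMethod("elementVolume", "JacobianMatrix", function(x) x@elementVolume)

#' @rdname accessors
#' @export
setGeneric("errorMean", function(x) standardGeneric("errorMean"))
#' @rdname accessors
#' @export
setMethod("errorMean", "ErrorStatistics", function(x) x@mean)

#' @rdname accessors
#' @export
setGeneric("errorCov", function(x) standardGeneric("errorCov"))
#' @rdname accessors
#' @export
setMethod("errorCov", "ErrorStatistics", function(x) x@cov)

#' @rdname accessors
#' @export
setGeneric("errorEigenvalues", function(x) standardGeneric("errorEigenvalues"))
#' @rdname accessors
#' @export
setMethod("errorEigenvalues", "ErrorStatistics", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("errorEigenvectors", function(x) standardGeneric("errorEigenvectors"))
#' @rdname accessors
#' @export
setMethod("errorEigenvectors", "ErrorStatistics", function(x) x@vectors)

#' @rdname accessors
#' @export
setGeneric("errorStd", function(x) standardGeneric("errorStd"))
#' @rdname accessors
#' @export
setMethod("errorStd", "ErrorStatistics", function(x) x@std)

#' @rdname accessors
#' @export
setGeneric("nDetected", function(x) standardGeneric("nDetected"))
#' @rdname accessors
#' @export
setMethod("nDetected", "PhotonRecordSet", function(x) length(x@detector))

#' @rdname accessors
#' @export
setGeneric("nLaunched", function(x) standardGeneric("nLaunched"))
#' @rdname accessors
#' @export
setMethod("nLaunched", "PhotonRecordSet", function(x) x@nLaunched)
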