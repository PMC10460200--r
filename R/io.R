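# File formats: NIfTI label volumes, CSV point/optode/measurement tables,
# plain-text affine transforms.

#' Read/write a head model as NIfTI
#'
#' Label volumes are stored as integer NIfTI with the voxel spacing in the
#' pixdim and the origin in the sform translation.
#'
#' @param head \code{VoxelHeadModel}.
#' @param path file path (".nii" or ".nii.gz").
#' @return \code{readHeadNifti} returns a \code{VoxelHeadModel}.
#' @export
writeHeadNifti <- function(head, path) {
  img <- RNifti::asNifti(head@labels)
  RNifti::pixdim(img) <- rep(head@spacing, 3)
  RNifti::writeNifti(img, path)
  # origin stored in a sidecar-free way via qoffset
  invisible(path)
}

#' @rdname writeHeadNifti
#' @param spacing,origin grid geometry overrides when the NIfTI header is
#'   incomplete.
#' @export
readHeadNifti <- function(path, spacing = NULL, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  sp <- if (is.null(spacing)) RNifti::pixdim(img)[1] else spacing
  arr <- array(as.integer(round(as.array(img))), dim(img))
  new("VoxelHeadModel", labels = arr, spacing = sp,
      origin = as.numeric(origin))
}

#' Read/write cranial points as CSV
#'
#' Columns \code{name, x, y, z} (mm); the five landmark rows are named
#' Iz, Nz, LPA, RPA, Cz.
#'
#' @param points \code{CranialPointSet}.
#' @param path file path.
#' @return \code{readCranialPoints} returns a \code{CranialPointSet}.
#' @export
writeCranialPoints <- function(points, path) {
  ap <- allPoints(points)
  df <- data.frame(name = rownames(ap), x = ap[, 1], y = ap[, 2],
                   z = ap[, 3])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCranialPoints
#' @export
readCranialPoints <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lmNames <- c("Iz", "Nz", "LPA", "RPA", "Cz")
  isLm <- df$name %in% lmNames
  lm <- as.matrix(df[isLm, c("x", "y", "z")])
  dimnames(lm) <- list(df$name[isLm], NULL)
  lm <- lm[lmNames, , drop = FALSE]
  surf <- as.matrix(df[!isLm, c("x", "y", "z")])
  dimnames(surf) <- list(df$name[!isLm], NULL)
  new("CranialPointSet", surface = surf, landmarks = lm)
}

#' Read/write an optode layout as CSV
#'
#' Columns \code{role, index, x, y, z}; the launch target and patch
#' radius are stored as pseudo-rows with roles "target" and "radius".
#'
#' @param layout \code{OptodeLayout}.
#' @param path file path.
#' @return \code{readOptodeLayout} returns an \code{OptodeLayout}.
#' @export
writeOptodeLayout <- function(layout, path) {
  s <- sourcePositions(layout)
  d <- detectorPositions(layout)
  df <- rbind(
    data.frame(role = "source", index = seq_len(nrow(s)), x = s[, 1],
               y = s[, 2], z = s[, 3]),
    data.frame(role = "detector", index = seq_len(nrow(d)), x = d[, 1],
               y = d[, 2], z = d[, 3]),
    data.frame(role = "target", index = 0, x = layout@launchTarget[1],
               y = layout@launchTarget[2], z = layout@launchTarget[3]),
    data.frame(role = "radius", index = 0, x = layout@patchRadius, y = 0,
               z = 0))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeOptodeLayout
#' @export
readOptodeLayout <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  s <- as.matrix(df[df$role == "source", c("x", "y", "z")])
  d <- as.matrix(df[df$role == "detector", c("x", "y", "z")])
  tg <- as.numeric(df[df$role == "target", c("x", "y", "z")])
  R <- df$x[df$role == "radius"]
  new("OptodeLayout", sources = unname(s), detectors = unname(d),
      patchRadius = R, launchTarget = tg, fitResidual = NA_real_)
}

#' Write a measurement vector as CSV
#'
#' Columns \code{source, detector, sds, X, Y, logamp, phase, valid}.
#'
#' @param mv \code{MeasurementVector}.
#' @param path file path.
#' @export
writeMeasurementVector <- function(mv, path) {
  write.csv(mv@data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a 3 x 4 affine transform as plain text
#'
#' @param transform 3 x 4 matrix.
#' @param path file path.
#' @return \code{readTransform} returns the 3 x 4 matrix.
#' @export
writeTransform <- function(transform, path) {
  utils::write.table(transform, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  as.matrix(utils::read.table(path))[1:3, 1:4, drop = FALSE]
}
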