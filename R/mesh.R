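# Structured tetrahedral meshing of labelled voxel volumes.
#
# Every labelled voxel is split into six tetrahedra by the Freudenthal/Kuhn
# pattern (all cubes cut the same way along the main diagonal), which is
# conforming across voxel faces by construction and preserves per-tissue
# volume exactly (6 tets of h^3/6 per voxel). Local refinement near the
# optode patches uses recursive longest-edge (Rivara) bisection, which keeps
# the mesh conforming and has bounded element-quality degradation.

.KUHN_PERMS <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                     c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

#' Tetrahedral mesh from a labelled voxel volume
#'
#' Builds a conforming tetrahedral mesh covering the selected labels of a
#' voxel head model (six Kuhn tetrahedra per voxel). Boundary triangles
#' are the faces shared by exactly one tetrahedron; they carry tag 0 until
#' optode patches are assigned with \code{\link{tagPatches}}.
#'
#' @param head a \code{VoxelHeadModel}.
#' @param keepLabels labels to mesh (default: all nonzero labels).
#' @return a \code{TetMeshModel}; attribute \code{"tetVoxel"} maps each
#'   tetrahedron to the 1-based linear index of its parent voxel.
#' @export
voxelToMesh <- function(head, keepLabels = NULL) {
  lab <- head@labels
  d <- dim(lab)
  h <- head@spacing
  if (is.null(keepLabels)) keepLabels <- setdiff(unique(as.vector(lab)), 0L)
  vox <- which(array(lab %in% keepLabels, d))
  if (!length(vox)) stop("no voxels with the requested labels")
  ijk <- arrayInd(vox, d) # 1-based voxel indices
  nx1 <- d[1] + 1L; ny1 <- d[2] + 1L
  nid <- function(i, j, k) i + nx1 * (j + (ny1 * k)) # 0-based corner ids
  i0 <- ijk[, 1] - 1L; j0 <- ijk[, 2] - 1L; k0 <- ijk[, 3] - 1L
  # eight corner ids per voxel (bit order x, y, z)
  corner <- matrix(0L, length(vox), 8)
  for (b in 0:7) {
    bx <- bitwAnd(b, 1L); by <- bitwAnd(bitwShiftR(b, 1L), 1L)
    bz <- bitwAnd(bitwShiftR(b, 2L), 1L)
    corner[, b + 1] <- nid(i0 + bx, j0 + by, k0 + bz)
  }
  nvoxel <- length(vox)
  tets <- matrix(0L, 6L * nvoxel, 4L)
  for (p in 1:6) {
    ax <- .KUHN_PERMS[p, ]
    bits <- integer(4)
    bits[1] <- 0L
    bits[2] <- bitwShiftL(1L, ax[1] - 1L)
    bits[3] <- bitwOr(bits[2], bitwShiftL(1L, ax[2] - 1L))
    bits[4] <- 7L
    rows <- seq.int(p, by = 6L, length.out = nvoxel)
    tets[rows, ] <- corner[, bits + 1L]
  }
  tetvox <- rep(vox, each = 1L)[rep(seq_len(nvoxel), each = 6L)]
  labels <- as.vector(lab)[tetvox]
  used <- sort(unique(as.vector(tets)))
  remap <- integer(max(used) + 1L)
  remap[used + 1L] <- seq_along(used)
  tets <- matrix(remap[tets + 1L], ncol = 4)
  gx <- used %% nx1
  gy <- (used %/% nx1) %% ny1
  gz <- used %/% (nx1 * ny1)
  nodes <- cbind(head@origin[1] + gx * h, head@origin[2] + gy * h,
                 head@origin[3] + gz * h)
  # fix orientation so all signed volumes are positive
  vol <- .tetSignedVolumes(nodes, tets)
  neg <- vol < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  bf <- .boundaryFacesFast(tets)
  mesh <- new("TetMeshModel", nodes = nodes, tets = tets,
              labels = as.integer(labels), boundaryFaces = bf,
              faceTags = integer(nrow(bf)),
              patches = data.frame(id = integer(), type = character(),
                                   index = integer(), x = numeric(),
                                   y = numeric(), z = numeric(),
                                   radius = numeric()))
  attr(mesh, "tetVoxel") <- tetvox
  mesh
}

.tetSignedVolumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' @rdname voxelToMesh
#' @param mesh a \code{TetMeshModel}.
#' @return \code{tetVolumes}: unsigned element volumes, mm^3.
#' @export
tetVolumes <- function(mesh) abs(.tetSignedVolumes(mesh@nodes, mesh@tets))

# faces occurring in exactly one tetrahedron, with the owning tet index
.boundaryFacesFast <- function(tets, withOwner = FALSE) {
  M <- nrow(tets)
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
                 tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  owner <- rep(seq_len(M), 4)
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  o <- order(lo, mid, hi)
  ls <- lo[o]; ms <- mid[o]; hs <- hi[o]
  n <- length(ls)
  dupNext <- c(ls[-n] == ls[-1] & ms[-n] == ms[-1] & hs[-n] == hs[-1], FALSE)
  dupPrev <- c(FALSE, dupNext[-n])
  singleIdx <- o[!(dupNext | dupPrev)]
  out <- faces[singleIdx, , drop = FALSE]
  if (withOwner) list(faces = out, owner = owner[singleIdx]) else out
}

#' Assign optode patches to boundary faces
#'
#' A boundary triangle belongs to an optode patch when its centroid lies
#' within the patch radius of the optode centre. Sources get patch ids
#' 1..n_s and detectors n_s+1..n_s+n_d. A triangle matching both a source
#' and a detector patch is an error (patches must not overlap).
#'
#' @param mesh \code{TetMeshModel}.
#' @param layout \code{OptodeLayout}.
#' @return the mesh with \code{faceTags} and \code{patches} filled in.
#' @export
tagPatches <- function(mesh, layout) {
  src <- sourcePositions(layout)
  det <- detectorPositions(layout)
  R <- patchRadius(layout)
  centres <- rbind(src, det)
  types <- c(rep("source", nrow(src)), rep("detector", nrow(det)))
  idxs <- c(seq_len(nrow(src)), seq_len(nrow(det)))
  bf <- mesh@boundaryFaces
  cent <- (mesh@nodes[bf[, 1], , drop = FALSE] +
           mesh@nodes[bf[, 2], , drop = FALSE] +
           mesh@nodes[bf[, 3], , drop = FALSE]) / 3
  tags <- integer(nrow(bf))
  for (p in seq_len(nrow(centres))) {
    d2 <- (cent[, 1] - centres[p, 1])^2 + (cent[, 2] - centres[p, 2])^2 +
          (cent[, 3] - centres[p, 3])^2
    hit <- d2 <= R^2
    clash <- hit & tags > 0L
    if (any(clash))
      stop("optode patches overlap on the boundary (patch ", p, ")")
    tags[hit] <- p
  }
  for (p in seq_len(nrow(centres)))
    if (!any(tags == p))
      warning("patch ", p, " captured no boundary faces")
  mesh@faceTags <- tags
  mesh@patches <- data.frame(id = seq_len(nrow(centres)), type = types,
                             index = idxs, x = centres[, 1], y = centres[, 2],
                             z = centres[, 3], radius = R)
  validObject(mesh)
  mesh
}

# ---- recursive longest-edge (Rivara) bisection --------------------------

.edgeKey <- function(a, b) pmin(a, b) * 2^26 + pmax(a, b)

.longestEdge <- function(nodes, tet) {
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  best <- 0; bi <- 1
  for (q in 1:6) {
    dd <- sum((nodes[tet[pairs[q, 1]], ] - nodes[tet[pairs[q, 2]], ])^2)
    if (dd > best + 1e-12 * best) { best <- dd; bi <- q }
  }
  sort(c(tet[pairs[bi, 1]], tet[pairs[bi, 2]]))
}

#' Refine a tetrahedral mesh near the optode patches
#'
#' Marks every tetrahedron whose centroid lies within \code{radius} of an
#' optode centre and bisects each marked element \code{passes} times using
#' recursive longest-edge (Rivara) bisection; conformity is maintained by
#' propagating bisections to neighbours sharing the refined edge. Three
#' passes roughly halve the local edge lengths.
#'
#' @param mesh \code{TetMeshModel} (patch tags are re-derived afterwards if
#'   a layout is given).
#' @param centres matrix of points (n x 3) near which to refine.
#' @param radius neighbourhood radius, mm.
#' @param passes number of bisection sweeps (default 3).
#' @param layout optional \code{OptodeLayout} to re-tag patches afterwards.
#' @return the refined \code{TetMeshModel}.
#' @export
refineNearPatches <- function(mesh, centres, radius, passes = 3,
                              layout = NULL) {
  nodes <- mesh@nodes
  tets <- mesh@tets
  labels <- mesh@labels
  for (sweep in seq_len(passes)) {
    cent <- (nodes[tets[, 1], , drop = FALSE] + nodes[tets[, 2], , drop = FALSE] +
             nodes[tets[, 3], , drop = FALSE] + nodes[tets[, 4], , drop = FALSE]) / 4
    marked <- rep(FALSE, nrow(tets))
    for (p in seq_len(nrow(centres)))
      marked <- marked | ((cent[, 1] - centres[p, 1])^2 +
                          (cent[, 2] - centres[p, 2])^2 +
                          (cent[, 3] - centres[p, 3])^2 <= radius^2)
    r <- .bisectMarked(nodes, tets, labels, which(marked))
    nodes <- r$nodes; tets <- r$tets; labels <- r$labels
  }
  bf <- .boundaryFacesFast(tets)
  out <- new("TetMeshModel", nodes = nodes, tets = tets,
             labels = as.integer(labels), boundaryFaces = bf,
             faceTags = integer(nrow(bf)), patches = mesh@patches)
  if (!is.null(layout)) out <- tagPatches(out, layout)
  out
}

# bisect all marked tets once (each), propagating for conformity via the
# LEPP (longest-edge propagation path) strategy; node->tet incidence lists
# avoid full-mesh scans
.bisectMarked <- function(nodes, tets, labels, markedIdx) {
  env <- new.env(parent = emptyenv())
  env$nodes <- nodes
  env$tets <- tets
  env$labels <- labels
  env$alive <- rep(TRUE, nrow(tets))
  env$needs <- rep(FALSE, nrow(tets))
  env$needs[markedIdx] <- TRUE
  env$inc <- split(rep(seq_len(nrow(tets)), 4), as.vector(tets))
  # inc is keyed by node id as character through split(); normalize to list
  inc <- vector("list", nrow(nodes))
  inc[as.integer(names(env$inc))] <- env$inc
  env$inc <- inc
  env$mid <- new.env(parent = emptyenv())

  holders <- function(e) {
    cand <- intersect(env$inc[[e[1]]], env$inc[[e[2]]])
    cand[env$alive[cand]]
  }
  longest <- function(i) .longestEdge(env$nodes, env$tets[i, ])

  splitEdge <- function(e) {
    key <- as.character(.edgeKey(e[1], e[2]))
    m <- env$mid[[key]]
    if (is.null(m)) {
      env$nodes <- rbind(env$nodes, (env$nodes[e[1], ] + env$nodes[e[2], ]) / 2)
      m <- nrow(env$nodes)
      env$mid[[key]] <- m
      env$inc[[m]] <- integer()
    }
    for (i in holders(e)) {
      tet <- env$tets[i, ]
      others <- setdiff(tet, e)
      kids <- rbind(c(e[1], m, others), c(e[2], m, others))
      env$alive[i] <- FALSE
      for (r in 1:2) {
        env$tets <- rbind(env$tets, kids[r, ])
        env$labels <- c(env$labels, env$labels[i])
        env$alive <- c(env$alive, TRUE)
        env$needs <- c(env$needs, FALSE)
        id <- nrow(env$tets)
        for (v in kids[r, ]) env$inc[[v]] <- c(env$inc[[v]], id)
      }
    }
  }

  guard <- 0L
  repeat {
    idx <- which(env$alive & env$needs)
    if (!length(idx)) break
    guard <- guard + 1L
    if (guard > 200000L) stop("refinement did not terminate")
    i <- idx[1]
    # LEPP climb: follow neighbours whose own longest edge is longer
    e <- longest(i)
    depth <- 0L
    repeat {
      depth <- depth + 1L
      if (depth > 1000L) stop("longest-edge propagation did not terminate")
      blockers <- holders(e)
      blockers <- blockers[vapply(blockers, function(j)
        !identical(longest(j), e), logical(1))]
      if (!length(blockers)) break
      e <- longest(blockers[1])
    }
    wasTarget <- i %in% holders(e)
    splitEdge(e)
    if (wasTarget) env$needs[i] <- FALSE
  }
  keep <- env$alive
  list(nodes = env$nodes, tets = env$tets[keep, , drop = FALSE],
       labels = env$labels[keep])
}

#' Mean edge length of elements near given points
#'
#' Diagnostic used to verify local refinement: mean of the six edge
#' lengths of every tetrahedron whose centroid is within \code{radius} of
#' any of the \code{centres}.
#'
#' @inheritParams refineNearPatches
#' @return mean edge length, mm.
#' @export
meanEdgeLengthNear <- function(mesh, centres, radius) {
  nodes <- mesh@nodes; tets <- mesh@tets
  cent <- (nodes[tets[, 1], , drop = FALSE] + nodes[tets[, 2], , drop = FALSE] +
           nodes[tets[, 3], , drop = FALSE] + nodes[tets[, 4], , drop = FALSE]) / 4
  sel <- rep(FALSE, nrow(tets))
  for (p in seq_len(nrow(centres)))
    sel <- sel | ((cent[, 1] - centres[p, 1])^2 + (cent[, 2] - centres[p, 2])^2 +
                  (cent[, 3] - centres[p, 3])^2 <= radius^2)
  if (!any(sel)) return(NA_real_)
  tt <- tets[sel, , drop = FALSE]
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  tot <- 0
  for (q in 1:6) {
    dd <- sqrt(rowSums((nodes[tt[, pairs[q, 1]], , drop = FALSE] -
                        nodes[tt[, pairs[q, 2]], , drop = FALSE])^2))
    tot <- tot + sum(dd)
  }
  tot / (6 * nrow(tt))
}
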