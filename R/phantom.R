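# Synthetic layered neonatal-head phantoms.
#
# Stand-in for a segmented MRI database: nested ellipsoidal tissue shells
# (scalp & skull, subarachnoid CSF, grey matter, white matter) with
# meridional sinusoidal-groove sulci carved into the grey matter and filled
# with CSF, plus ellipsoidal ventricles. Population variation draws head
# size, layer thicknesses and sulcus placement per head.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default phantom population parameters
#'
#' Geometry of the synthetic layered head: outer ellipsoid semi-axes (mm),
#' scalp-and-skull shell thickness, subarachnoid CSF thickness, grey-matter
#' thickness, ventricle semi-axes, and the sulci model (number of
#' meridional grooves, their depth into GM and width). Defaults are sized
#' to a term neonate (head circumference about 33 cm); \code{scale} shrinks
#' the whole geometry for desk-scale studies.
#'
#' @param scale global geometric scale factor (1 = neonatal size).
#' @param ... overrides of individual entries.
#' @return named list of parameters.
#' @export
phantomParams <- function(scale = 1, ...) {
  p <- list(
    semiAxes = c(48, 58, 45) * scale,
    shellThickness = 3 * scale,
    csfThickness = 1.5 * scale,
    gmThickness = 7 * scale,
    ventricleAxes = c(7, 12, 6) * scale,
    nSulci = 8,
    grooveDepth = 5 * scale,
    grooveWidth = 2.5 * scale,
    groovePhase = NULL)
  dots <- list(...)
  p[names(dots)] <- dots
  p
}

#' Generate one labelled voxel head phantom
#'
#' Builds the nested-ellipsoid head at the given voxel spacing. The sulci
#' are meridional grooves (planes of constant azimuth around the vertical
#' axis, at random phase for nonzero seed jitter) cut \code{grooveDepth} mm
#' into the grey matter and filled with CSF; the ventricles are an interior
#' ellipsoid labelled CSF-2 from the start. Deterministic for a fixed seed.
#'
#' @param seed integer seed (drives the groove phase jitter).
#' @param params list from \code{\link{phantomParams}}.
#' @param spacing isotropic voxel edge, mm (default 1).
#' @return a \code{VoxelHeadModel}.
#' @export
generateHead <- function(seed = 1, params = phantomParams(), spacing = 1) {
  ax <- params$semiAxes
  tSS <- params$shellThickness
  tCSF <- params$csfThickness
  tGM <- params$gmThickness
  if (tSS < 2 * spacing)
    stop("shell thickness must be at least two voxels")
  if (tCSF < 0 || tGM <= 0) stop("layer thicknesses must be nonnegative")
  if (params$nSulci > 0 && params$grooveDepth >= tGM)
    stop("groove depth must be smaller than the grey-matter thickness ",
         "(grey matter must stay between CSF and white matter)")
  if (min(ax) <= tSS + tCSF + tGM)
    stop("layer thicknesses exceed the head semi-axes")
  phase <- if (!is.null(params$groovePhase)) params$groovePhase
           else .withSeed(seed, stats::runif(1, 0, 2 * pi))

  pad <- 2
  n <- as.integer(ceiling(2 * (ax + pad) / spacing))
  origin <- -(n * spacing) / 2
  cx <- seq_len(n[1]) * spacing - spacing / 2 + origin[1]
  cy <- seq_len(n[2]) * spacing - spacing / 2 + origin[2]
  cz <- seq_len(n[3]) * spacing - spacing / 2 + origin[3]
  X <- array(cx, n)
  Y <- array(rep(cy, each = n[1]), n)
  Z <- array(rep(cz, each = n[1] * n[2]), n)

  rho <- function(axes) sqrt((X / axes[1])^2 + (Y / axes[2])^2 + (Z / axes[3])^2)
  rOuter <- rho(ax)
  rCSF <- rho(ax - tSS)
  rGM <- rho(ax - tSS - tCSF)
  rWM <- rho(ax - tSS - tCSF - tGM)

  lab <- array(0L, n)
  lab[rOuter < 1] <- .TISSUES["SS"]
  lab[rCSF < 1] <- .TISSUES["CSF1"]
  lab[rGM < 1] <- .TISSUES["GM"]
  lab[rWM < 1] <- .TISSUES["WM"]

  if (params$nSulci > 0 && params$grooveDepth > 0) {
    # meridional grooves: azimuthal bands of width grooveWidth (arc length)
    theta <- atan2(Y, X)
    rxy <- sqrt(X^2 + Y^2)
    dth <- (theta - phase) * params$nSulci / (2 * pi)
    frac <- abs(dth - round(dth)) * 2 * pi / params$nSulci # radians to band
    arc <- frac * rxy
    grooveAxes <- ax - tSS - tCSF - params$grooveDepth
    inGroove <- arc < params$grooveWidth / 2 & lab == .TISSUES["GM"] &
      rho(grooveAxes) >= 1 & Z > 0
    lab[inGroove] <- .TISSUES["CSF1"]
  }

  va <- params$ventricleAxes
  if (all(va > 0)) {
    rV <- sqrt((X / va[1])^2 + ((Y - 0.05 * ax[2]) / va[2])^2 +
               ((Z + 0.15 * ax[3]) / va[3])^2)
    lab[rV < 1 & lab == .TISSUES["WM"]] <- .TISSUES["CSF2"]
  }

  new("VoxelHeadModel", labels = lab, spacing = spacing,
      origin = as.numeric(origin))
}

#' Generate a phantom population with inter-individual variation
#'
#' Draws per-head random deviates of the global size (lognormal-like
#' normal factor), shell/CSF thicknesses, groove depth and groove phase,
#' producing a list of heads plus their cranial point sets. Variation
#' \code{spread = 0} reproduces identical heads.
#'
#' @param N number of heads (>= 2).
#' @param seed integer seed; head i uses sub-seed \code{seed + i}.
#' @param params base geometry from \code{\link{phantomParams}}.
#' @param spread list of fractional standard deviations:
#'   \code{size} (head scale, default 0.063, matching a ~2.1/33.4 cm
#'   relative circumference spread), \code{shell}, \code{csf},
#'   \code{groove} (each default 0.15), and \code{sulci} (1 = random
#'   per-head groove placement, 0 = fixed placement).
#' @param spacing voxel edge, mm.
#' @param points if TRUE also compute cranial point sets.
#' @return list with elements \code{heads} (list of
#'   \code{VoxelHeadModel}) and \code{points} (list of
#'   \code{CranialPointSet} or NULL).
#' @export
generatePopulation <- function(N, seed = 1, params = phantomParams(),
                               spread = list(), spacing = 1, points = TRUE) {
  if (N < 2) stop("N must be >= 2")
  sp <- list(size = 0.063, shell = 0.15, csf = 0.15, groove = 0.15,
             sulci = 1)
  sp[names(spread)] <- spread
  heads <- vector("list", N)
  pts <- if (points) vector("list", N) else NULL
  for (i in seq_len(N)) {
    draws <- .withSeed(seed + i, list(
      size = stats::rnorm(1, 1, sp$size),
      shell = stats::rnorm(1, 1, sp$shell),
      csf = stats::rnorm(1, 1, sp$csf),
      groove = stats::rnorm(1, 1, sp$groove)))
    pi_ <- params
    pi_$semiAxes <- params$semiAxes * max(0.7, min(1.3, draws$size))
    pi_$shellThickness <- max(2 * spacing,
                              params$shellThickness * max(0.5, draws$shell))
    pi_$csfThickness <- params$csfThickness * max(0.3, draws$csf)
    pi_$grooveDepth <- min(params$gmThickness - spacing,
                           params$grooveDepth * max(0.3, draws$groove))
    if (sp$sulci == 0)
      pi_$groovePhase <- if (is.null(params$groovePhase)) 0
                         else params$groovePhase
    heads[[i]] <- generateHead(seed = seed + i, params = pi_,
                               spacing = spacing)
    if (points) pts[[i]] <- cranialPoints(heads[[i]])
  }
  list(heads = heads, points = pts)
}

# outermost labelled crossing along direction d from the head centroid,
# refined to ~h/8 accuracy
.surfaceCast <- function(head, centre, dirs) {
  d <- dim(head@labels)
  h <- head@spacing
  rmax <- sqrt(sum((d * h)^2)) / 2 + 2 * h
  out <- matrix(NA_real_, nrow(dirs), 3)
  for (q in seq_len(nrow(dirs))) {
    u <- dirs[q, ] / sqrt(sum(dirs[q, ]^2))
    lo <- 0; hi <- rmax
    # bracket: march inward from outside until labelled
    t <- rmax
    found <- FALSE
    while (t > 0) {
      p <- centre + t * u
      ijk <- floor((p - head@origin) / h) + 1
      if (all(ijk >= 1) && all(ijk <= d) &&
          head@labels[ijk[1], ijk[2], ijk[3]] > 0) { found <- TRUE; break }
      t <- t - h / 2
    }
    if (!found) next
    lo <- t; hi <- min(t + h / 2, rmax)
    for (b in 1:12) {
      mid <- (lo + hi) / 2
      p <- centre + mid * u
      ijk <- floor((p - head@origin) / h) + 1
      inside <- all(ijk >= 1) && all(ijk <= d) &&
        head@labels[ijk[1], ijk[2], ijk[3]] > 0
      if (inside) lo <- mid else hi <- mid
    }
    out[q, ] <- centre + ((lo + hi) / 2) * u
  }
  out
}

.headCentroid <- function(head) {
  idx <- which(head@labels > 0)
  ijk <- arrayInd(idx, dim(head@labels))
  head@origin + (colMeans(ijk) - 0.5) * head@spacing
}

# ring layout of the dense cranial grid: 12 latitude rings, counts sum 249
.CRANIAL_RING_N <- c(4, 8, 12, 16, 20, 24, 27, 29, 30, 30, 25, 24)
.CRANIAL_RING_POLAR <- c(seq(0.09, 0.5, length.out = 10), 0.56, 0.62) * pi

#' Cranial point set of a phantom head
#'
#' The five landmarks (Nz at +y, Iz at -y, LPA at -x, RPA at +x, Cz at +z,
#' ray-cast from the head centroid to the surface) plus a deterministic
#' dense grid of 249 surface points arranged on 12 latitude rings between
#' the vertex and just below the equator, in the spirit of the 10-5
#' system's dense coverage. All points lie on the voxel surface to within
#' half a voxel.
#'
#' @param head a \code{VoxelHeadModel}.
#' @return a \code{CranialPointSet} (249 surface + 5 landmark points).
#' @export
cranialPoints <- function(head) {
  ctr <- .headCentroid(head)
  lmDirs <- rbind(Iz = c(0, -1, 0), Nz = c(0, 1, 0), LPA = c(-1, 0, 0),
                  RPA = c(1, 0, 0), Cz = c(0, 0, 1))
  lm <- .surfaceCast(head, ctr, lmDirs)
  rownames(lm) <- rownames(lmDirs)
  if (any(is.na(lm))) stop("landmark ray casting left the head surface")
  dirs <- NULL
  for (k in seq_along(.CRANIAL_RING_N)) {
    nk <- .CRANIAL_RING_N[k]
    phi <- .CRANIAL_RING_POLAR[k]
    th <- 2 * pi * (seq_len(nk) - 0.5) / nk
    dirs <- rbind(dirs, cbind(sin(phi) * cos(th), sin(phi) * sin(th),
                              rep(cos(phi), nk)))
  }
  surf <- .surfaceCast(head, ctr, dirs)
  rownames(surf) <- sprintf("P%03d", seq_len(nrow(surf)))
  if (any(is.na(surf))) stop("cranial ray casting left the head surface")
  new("CranialPointSet", surface = surf, landmarks = lm)
}

#' Algebraic least-squares sphere fit
#'
#' @param pts matrix n x 3.
#' @return list with \code{centre}, \code{radius}, \code{rms} residual.
#' @export
fitSphere <- function(pts) {
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  sol <- qr.solve(A, b)
  ctr <- sol[1:3]
  r <- sqrt(sol[4] + sum(ctr^2))
  res <- sqrt(rowSums((pts - matrix(ctr, nrow(pts), 3, byrow = TRUE))^2)) - r
  list(centre = as.numeric(ctr), radius = r, rms = sqrt(mean(res^2)))
}

#' Planar optode probe templates
#'
#' \code{"desk"}: 8 optodes (4 sources, 4 detectors) on a 2 x 4 grid with
#' 12 mm pitch, checkerboard roles. \code{"full"}: 30 optodes
#' (15 sources, 15 detectors) on a 5 x 6 grid with 10 mm pitch.
#'
#' @param type "desk" or "full".
#' @param pitch grid pitch, mm (defaults 12 / 10).
#' @return data.frame with columns \code{u, v} (planar mm) and
#'   \code{role} ("source"/"detector").
#' @export
probeTemplate <- function(type = c("desk", "full"), pitch = NULL) {
  type <- match.arg(type)
  if (type == "desk") {
    if (is.null(pitch)) pitch <- 12
    g <- expand.grid(i = 0:3, j = 0:1)
  } else {
    if (is.null(pitch)) pitch <- 10
    g <- expand.grid(i = 0:5, j = 0:4)
  }
  u <- (g$i - mean(g$i)) * pitch
  v <- (g$j - mean(g$j)) * pitch
  role <- ifelse((g$i + g$j) %% 2 == 0, "source", "detector")
  data.frame(u = u, v = v, role = role, stringsAsFactors = FALSE)
}

#' Press a planar probe onto the head surface
#'
#' Projects the planar optode template onto the scalp: a sphere is fitted
#' to the surface patch around the probe centre, template points are laid
#' out in the tangent plane and projected radially toward the fitted
#' sphere centre onto the voxel surface. An iterative on-surface
#' relaxation then reduces the mismatch between the projected pairwise
#' optode separations (geodesic, approximated as arcs on the fitted
#' sphere) and the template separations. Finally a sphere is fitted to
#' the optode positions and its centre stored as the common launch target.
#'
#' @param head \code{VoxelHeadModel}.
#' @param template data.frame from \code{\link{probeTemplate}}.
#' @param direction unit-ish vector from the head centroid toward the
#'   probe centre (default left hemisphere, slightly above the ear).
#' @param patchRadius optode patch radius R, mm (default 1.5).
#' @param sweeps relaxation sweeps (default 40).
#' @return an \code{OptodeLayout}.
#' @export
placeProbe <- function(head, template = probeTemplate("desk"),
                       direction = c(-1, 0, 0.4), patchRadius = 1.5,
                       sweeps = 40) {
  ctr <- .headCentroid(head)
  dir0 <- direction / sqrt(sum(direction^2))
  c0 <- .surfaceCast(head, ctr, matrix(dir0, 1))[1, ]
  if (any(is.na(c0))) stop("probe centre projection left the head surface")
  extent <- max(sqrt(template$u^2 + template$v^2)) + 5
  # sample the covered surface region with a cone of directions
  ang <- extent / sqrt(sum((c0 - ctr)^2))
  e1 <- if (abs(dir0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- e1 - sum(e1 * dir0) * dir0; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir0[2] * e1[3] - dir0[3] * e1[2],
          dir0[3] * e1[1] - dir0[1] * e1[3],
          dir0[1] * e1[2] - dir0[2] * e1[1])
  gr <- expand.grid(a = seq(-ang, ang, length.out = 9),
                    b = seq(-ang, ang, length.out = 9))
  dirs <- t(apply(gr, 1, function(w)
    dir0 + w[1] * e1 + w[2] * e2))
  region <- .surfaceCast(head, ctr, dirs)
  region <- region[!is.na(region[, 1]), , drop = FALSE]
  sph <- fitSphere(region)

  castFromSphere <- function(p) {
    # radial projection toward the fitted sphere centre
    u <- p - sph$centre
    .surfaceCast(head, sph$centre, matrix(u, 1))[1, ]
  }
  pos <- matrix(NA_real_, nrow(template), 3)
  for (q in seq_len(nrow(template))) {
    p <- c0 + template$u[q] * e1 + template$v[q] * e2
    pos[q, ] <- castFromSphere(p)
  }
  if (any(is.na(pos))) stop("probe projection left the head surface")

  tmplD <- as.matrix(stats::dist(cbind(template$u, template$v)))
  geo <- function(P) {
    # arc-length separations on the fitted sphere
    U <- P - matrix(sph$centre, nrow(P), 3, byrow = TRUE)
    r <- sqrt(rowSums(U^2))
    Un <- U / r
    cosang <- pmin(1, pmax(-1, tcrossprod(Un)))
    mean(r) * acos(cosang)
  }
  loss <- function(P) sum((geo(P) - tmplD)^2) / 2
  cur <- loss(pos)
  step <- head@spacing
  for (sw in seq_len(sweeps)) {
    improved <- FALSE
    for (q in seq_len(nrow(pos))) {
      # local tangent directions at optode q
      u <- pos[q, ] - sph$centre; u <- u / sqrt(sum(u^2))
      t1 <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      t1 <- t1 - sum(t1 * u) * u; t1 <- t1 / sqrt(sum(t1^2))
      t2 <- c(u[2] * t1[3] - u[3] * t1[2], u[3] * t1[1] - u[1] * t1[3],
              u[1] * t1[2] - u[2] * t1[1])
      for (mv in list(t1, -t1, t2, -t2)) {
        cand <- castFromSphere(pos[q, ] + step * mv)
        if (any(is.na(cand))) next
        newpos <- pos; newpos[q, ] <- cand
        l2 <- loss(newpos)
        if (l2 < cur - 1e-12) { pos <- newpos; cur <- l2; improved <- TRUE }
      }
    }
    if (!improved) {
      step <- step / 2
      if (step < head@spacing / 16) break
    }
  }
  fit <- fitSphere(pos)
  new("OptodeLayout",
      sources = pos[template$role == "source", , drop = FALSE],
      detectors = pos[template$role == "detector", , drop = FALSE],
      patchRadius = patchRadius, launchTarget = fit$centre,
      fitResidual = fit$rms)
}

#' Head circumference of a phantom
#'
#' Perimeter of the surface polygon obtained by ray casting 72 azimuthal
#' directions in the horizontal plane through the head centroid, mm.
#'
#' @param head \code{VoxelHeadModel}.
#' @return circumference, mm.
#' @export
headCircumference <- function(head) {
  ctr <- .headCentroid(head)
  th <- 2 * pi * (0:71) / 72
  dirs <- cbind(cos(th), sin(th), 0)
  p <- .surfaceCast(head, ctr, dirs)
  p <- rbind(p, p[1, ])
  sum(sqrt(rowSums(diff(p)^2)))
}
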