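# P1 finite-element discretization of the frequency-domain diffusion
# approximation:
#   -div(kappa grad Phi) + (i w / c + mu_a) Phi = 0        in Omega
#   (1 - rho) Phi + 2 (1 + rho) nu . kappa grad Phi = 4 Q_k on the boundary
# with kappa = 1 / (3 (mu_a + mu_s')) treated as a function of mu_a, and
# the measurement M_jk = 1/2 (1-rho)/(1+rho) int P_j Phi_k dS.
# Complex sparse systems are solved through the equivalent 2n x 2n real
# block form with a single sparse LU factorization reused for all source
# and detector (adjoint) right-hand sides.

.tetGradients <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  a <- nodes[tets[, 2], , drop = FALSE] - p1
  b <- nodes[tets[, 3], , drop = FALSE] - p1
  c_ <- nodes[tets[, 4], , drop = FALSE] - p1
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bc <- cross(b, c_)
  det6 <- rowSums(a * bc) # 6 * volume, positive for oriented meshes
  g2 <- bc / det6
  g3 <- cross(c_, a) / det6
  g4 <- cross(a, b) / det6
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), vol = det6 / 6)
}

.triAreas <- function(nodes, faces) {
  a <- nodes[faces[, 2], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  b <- nodes[faces[, 3], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# sparse assembly of sum_e coef_e * (stiffness_e) and sum_e coef_e * mass_e
.assembleVolume <- function(mesh, stiffCoef, massCoef, geom = NULL) {
  tets <- mesh@tets
  n <- nrow(mesh@nodes)
  if (is.null(geom)) geom <- .tetGradients(mesh@nodes, tets)
  V <- geom$vol
  ii <- jj <- integer(0)
  xs <- xm <- numeric(0)
  iiL <- vector("list", 16)
  jjL <- vector("list", 16)
  xsL <- vector("list", 16)
  xmL <- vector("list", 16)
  q <- 0
  for (r in 1:4) for (s in 1:4) {
    q <- q + 1
    iiL[[q]] <- tets[, r]
    jjL[[q]] <- tets[, s]
    xsL[[q]] <- stiffCoef * V * rowSums(geom$g[[r]] * geom$g[[s]])
    xmL[[q]] <- massCoef * V / 20 * (1 + (r == s))
  }
  ii <- unlist(iiL); jj <- unlist(jjL)
  list(S = sparseMatrix(i = ii, j = jj, x = unlist(xsL), dims = c(n, n)),
       M = sparseMatrix(i = ii, j = jj, x = unlist(xmL), dims = c(n, n)),
       geom = geom)
}

.assembleBoundaryMass <- function(mesh, faceSel = NULL) {
  bf <- mesh@boundaryFaces
  if (!is.null(faceSel)) bf <- bf[faceSel, , drop = FALSE]
  n <- nrow(mesh@nodes)
  if (!nrow(bf)) return(sparseMatrix(i = integer(), j = integer(),
                                     x = numeric(), dims = c(n, n)))
  A <- .triAreas(mesh@nodes, bf)
  ii <- jj <- list(); xx <- list(); q <- 0
  for (r in 1:3) for (s in 1:3) {
    q <- q + 1
    ii[[q]] <- bf[, r]; jj[[q]] <- bf[, s]
    xx[[q]] <- A / 12 * (1 + (r == s))
  }
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
               dims = c(n, n))
}

#' Assemble and factorize the FD diffusion-approximation system
#'
#' Builds the P1 Galerkin system of the frequency-domain diffusion
#' approximation on a tagged tetrahedral mesh and factorizes it once. The
#' returned solver object solves forward problems (diffuse source on a
#' source patch) and adjoint problems (diffuse source on a detector patch)
#' with the same factorization, and evaluates boundary measurements and
#' element-wise Frechet absorption derivatives.
#'
#' @param mesh a \code{TetMeshModel} with patch tags (see
#'   \code{\link{tagPatches}}).
#' @param optics tissue table (DA variant).
#' @param f modulation frequency, GHz.
#' @param nExterior exterior refractive index for the effective reflection
#'   coefficient rho (default 1; rho = 0 when indices match).
#' @param muaElement optional per-element absorption override (length =
#'   number of tetrahedra, mm^-1); the diffusion coefficient is recomputed
#'   from it, so local absorption perturbations propagate through kappa.
#' @param solverTol relative residual target of the COCG iteration
#'   (default 1e-11; tighten when the solution feeds a finite-difference
#'   quotient subject to cancellation).
#' @return an object of class \code{daSolver} (a list) with elements
#'   \code{solveSource(k)}, \code{solveDetector(j)} returning complex node
#'   fields, \code{measure(field, j)}, \code{frechet(phiK, phiStarJ)},
#'   \code{rho}, \code{nFactorizations}.
#' @export
daSolver <- function(mesh, optics = tissueTable("da"), f = 0.1,
                     nExterior = 1.0, muaElement = NULL,
                     solverTol = 1e-11) {
  der <- derivedCoefficients(optics, n_exterior = nExterior)
  mua <- .tissueValue(der, "mu_a")[mesh@labels]
  musr <- .tissueValue(der, "mu_s_reduced")[mesh@labels]
  if (!is.null(muaElement)) {
    if (length(muaElement) != nrow(mesh@tets))
      stop("muaElement must have one value per tetrahedron")
    mua <- muaElement
  }
  kap <- 1 / (3 * (mua + musr))
  nmed <- .tissueValue(der, "n")[mesh@labels]
  cmed <- speedOfLight() / nmed
  rho <- effectiveReflection(nmed[1], nExterior)
  omega <- 2 * pi * f

  asm <- .assembleVolume(mesh, stiffCoef = kap, massCoef = mua)
  Mun <- .assembleVolume(mesh, stiffCoef = rep(0, length(kap)),
                         massCoef = omega / cmed, geom = asm$geom)$M
  Ball <- .assembleBoundaryMass(mesh)
  A <- asm$S + asm$M + (1 - rho) / (2 * (1 + rho)) * Ball
  n <- nrow(mesh@nodes)

  patches <- mesh@patches
  srcIds <- patches$id[patches$type == "source"]
  detIds <- patches$id[patches$type == "detector"]
  patchVec <- function(id) { # boundary-mass-weighted characteristic fn
    sel <- which(mesh@faceTags == id)
    if (!length(sel)) stop("patch ", id, " has no boundary faces")
    Bp <- .assembleBoundaryMass(mesh, faceSel = sel)
    v <- as.numeric(Bp %*% rep(1, n))
    area <- sum(.triAreas(mesh@nodes, mesh@boundaryFaces[sel, , drop = FALSE]))
    list(v = v, area = area)
  }

  # one sparse Cholesky of the real (SPD) part; the complex-symmetric
  # system (A + i Mun) x = b is then solved by preconditioned COCG, which
  # converges in a handful of iterations since the imaginary part is a
  # small mass-matrix perturbation
  ch <- Matrix::Cholesky(forceSymmetric(A), LDL = FALSE, perm = TRUE,
                         super = NA)
  nfact <- 1L
  precond <- function(r)
    complex(real = as.numeric(Matrix::solve(ch, Re(r), system = "A")),
            imaginary = as.numeric(Matrix::solve(ch, Im(r), system = "A")))
  applyK <- function(x)
    complex(real = as.numeric(A %*% Re(x)) - as.numeric(Mun %*% Im(x)),
            imaginary = as.numeric(Mun %*% Re(x)) + as.numeric(A %*% Im(x)))
  solveC <- function(b, tol = solverTol, maxit = 400) {
    if (omega == 0)
      return(complex(real = as.numeric(Matrix::solve(ch, Re(b), system = "A")),
                     imaginary = 0))
    nb <- sqrt(sum(Mod(b)^2))
    x <- rep(0 + 0i, n)
    r <- b
    z <- precond(r)
    p <- z
    rz <- sum(r * z) # unconjugated (COCG) inner product
    for (it in seq_len(maxit)) {
      Kp <- applyK(p)
      alpha <- rz / sum(p * Kp)
      x <- x + alpha * p
      r <- r - alpha * Kp
      if (sqrt(sum(Mod(r)^2)) <= tol * nb) return(x)
      z <- precond(r)
      rzNew <- sum(r * z)
      beta <- rzNew / rz
      rz <- rzNew
      p <- z + beta * p
    }
    warning("COCG did not reach tolerance; returning last iterate")
    x
  }

  geom <- asm$geom
  tets <- mesh@tets
  V <- geom$vol
  kapDer <- 1 / (3 * (mua + musr)^2) # d kappa / d mu_a = -this

  obj <- list(
    mesh = mesh, rho = rho, f = f, omega = omega,
    nFactorizations = function() nfact,
    solveSource = function(k) {
      id <- patches$id[patches$type == "source" & patches$index == k]
      pv <- patchVec(id)
      solveC((2 / (1 + rho)) * pv$v / pv$area)
    },
    solveDetector = function(j) {
      id <- patches$id[patches$type == "detector" & patches$index == j]
      pv <- patchVec(id)
      solveC((2 / (1 + rho)) * pv$v)
    },
    measure = function(field, j) {
      id <- patches$id[patches$type == "detector" & patches$index == j]
      pv <- patchVec(id)
      0.5 * (1 - rho) / (1 + rho) * sum(pv$v * field)
    },
    frechet = function(phiK, phiStarJ, elements = NULL) {
      idx <- if (is.null(elements)) seq_len(nrow(tets)) else elements
      tt <- tets[idx, , drop = FALSE]
      gK <- matrix(0i, length(idx), 3)
      gJ <- matrix(0i, length(idx), 3)
      for (r in 1:4) {
        gr <- geom$g[[r]][idx, , drop = FALSE]
        gK <- gK + gr * phiK[tt[, r]]
        gJ <- gJ + gr * phiStarJ[tt[, r]]
      }
      gradDot <- rowSums(gK * gJ)
      sK <- phiK[tt[, 1]] + phiK[tt[, 2]] + phiK[tt[, 3]] + phiK[tt[, 4]]
      sJ <- phiStarJ[tt[, 1]] + phiStarJ[tt[, 2]] + phiStarJ[tt[, 3]] +
            phiStarJ[tt[, 4]]
      pp <- phiK[tt[, 1]] * phiStarJ[tt[, 1]] +
            phiK[tt[, 2]] * phiStarJ[tt[, 2]] +
            phiK[tt[, 3]] * phiStarJ[tt[, 3]] +
            phiK[tt[, 4]] * phiStarJ[tt[, 4]]
      massInt <- V[idx] / 20 * (sK * sJ + pp)
      0.25 * (1 - rho) * (kapDer[idx] * V[idx] * gradDot - massInt)
    })
  class(obj) <- "daSolver"
  obj
}

#' @export
print.daSolver <- function(x, ...) {
  cat(sprintf("daSolver: %d nodes, f = %g GHz, rho = %.4f\n",
              nrow(x$mesh@nodes), x$f, x$rho))
  invisible(x)
}

#' Diffusion-approximation measurement vector
#'
#' Solves the FD diffusion approximation for every source and evaluates
#' the boundary measurement at every detector, assembling the same
#' measurement schema as the Monte Carlo solver (X = Re M, Y = Im M).
#'
#' @param mesh tagged \code{TetMeshModel}.
#' @param optics tissue table (DA variant).
#' @param layout \code{OptodeLayout} (for SDS bookkeeping).
#' @param f modulation frequency, GHz.
#' @param sdsMax SDS mask cutoff, mm.
#' @param nExterior exterior refractive index.
#' @param keepSolver attach the solver state and fields as attributes (for
#'   the Jacobian).
#' @param muaElement optional per-element absorption override (see
#'   \code{\link{daSolver}}).
#' @return a \code{MeasurementVector} (solver "da").
#' @export
daMeasurementVector <- function(mesh, optics = tissueTable("da"), layout,
                                f = 0.1, sdsMax = 55, nExterior = 1.0,
                                keepSolver = FALSE, muaElement = NULL) {
  sol <- daSolver(mesh, optics, f, nExterior, muaElement = muaElement)
  src <- sourcePositions(layout)
  det <- detectorPositions(layout)
  fields <- lapply(seq_len(nrow(src)), sol$solveSource)
  rows <- list()
  for (k in seq_len(nrow(src))) {
    sds <- sqrt(rowSums((det - matrix(src[k, ], nrow(det), 3, byrow = TRUE))^2))
    M <- vapply(seq_len(nrow(det)), function(j) sol$measure(fields[[k]], j),
                complex(1))
    rows[[k]] <- data.frame(source = k, detector = seq_len(nrow(det)),
                            sds = sds, X = Re(M), Y = Im(M),
                            logamp = log(Mod(M)), phase = atan2(Im(M), Re(M)),
                            valid = Mod(M) > 0 & sds < sdsMax)
  }
  mv <- new("MeasurementVector", data = do.call(rbind, rows), f = f,
            solver = "da", sdsMax = sdsMax)
  if (keepSolver) {
    attr(mv, "solver") <- sol
    attr(mv, "fields") <- fields
  }
  mv
}

#' Adjoint-method absorption Jacobian for the diffusion approximation
#'
#' One adjoint solve per detector (same factorized operator as the forward
#' problem) combined with the forward fields gives the Frechet derivative
#' of every measurement with respect to the absorption coefficient of
#' every tetrahedron; the complex derivatives are reduced to ln A and
#' phase rows with the shared log-amplitude/phase formulas.
#'
#' @param measurement \code{MeasurementVector} from
#'   \code{\link{daMeasurementVector}} with \code{keepSolver = TRUE}.
#' @return a \code{JacobianMatrix} (solver "da") over all mesh elements.
#' @export
daJacobian <- function(measurement) {
  sol <- attr(measurement, "solver")
  fields <- attr(measurement, "fields")
  if (is.null(sol)) stop("measurement must carry solver state (keepSolver = TRUE)")
  dat <- measurement@data
  keep <- dat$valid
  dets <- sort(unique(dat$detector[keep]))
  adj <- list()
  for (j in dets) adj[[as.character(j)]] <- sol$solveDetector(j)
  ne <- nrow(sol$mesh@tets)
  m <- sum(keep)
  logamp <- matrix(0, m, ne)
  phase <- matrix(0, m, ne)
  r <- 0
  ord <- which(keep)
  for (q in ord) {
    r <- r + 1
    k <- dat$source[q]; j <- dat$detector[q]
    DM <- sol$frechet(fields[[k]], adj[[as.character(j)]])
    M <- complex(real = dat$X[q], imaginary = dat$Y[q])
    lp <- logampPhaseJacobian(Re(M), Im(M), Re(DM), Im(DM))
    logamp[r, ] <- lp$logamp
    phase[r, ] <- lp$phase
  }
  new("JacobianMatrix", logamp = logamp, phase = phase,
      rows = dat[keep, c("source", "detector", "sds")],
      elements = seq_len(ne),
      elementVolume = tetVolumes(sol$mesh), f = measurement@f,
      solver = "da")
}
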