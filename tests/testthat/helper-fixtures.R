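# Shared fixtures, all generated in code. Expensive Monte Carlo runs are
# cached per session in .fixtures so several tests can share one run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# homogeneous or layered slab: dims in voxels, spacing h, origin 0;
# layers = list(list(label, zmax_vox), ...) from the top (z = max) down
slabHead <- function(nx, ny, nz, h = 1, label = 4L, layers = NULL) {
  lab <- array(label, c(nx, ny, nz))
  if (!is.null(layers)) {
    for (ly in layers) {
      sel <- seq.int(ly$from, ly$to)
      lab[, , sel] <- ly$label
    }
  }
  new("VoxelHeadModel", labels = lab, spacing = h, origin = c(0, 0, 0))
}

sphereHead <- function(radius, h = 1, label = 4L, pad = 2) {
  n <- as.integer(ceiling(2 * (radius + pad) / h))
  ctr <- rep(n * h / 2, 3)
  ijk <- arrayInd(seq_len(n^3), c(n, n, n))
  r <- sqrt(rowSums((sweep(ijk, 2, 0.5) * h -
                     matrix(ctr, n^3, 3, byrow = TRUE))^2))
  lab <- array(ifelse(r < radius, label, 0L), c(n, n, n))
  new("VoxelHeadModel", labels = lab, spacing = h, origin = c(0, 0, 0))
}

# concentric shells for the CSF tests: GM ball, CSF-1 shell, S&S shell
shellHead <- function(rGM = 10, rCSF = 12, rSS = 14, h = 0.5) {
  n <- as.integer(ceiling(2 * (rSS + 1) / h))
  ctr <- rep(n * h / 2, 3)
  ijk <- arrayInd(seq_len(n^3), c(n, n, n))
  r <- sqrt(rowSums((sweep(ijk, 2, 0.5) * h -
                     matrix(ctr, n^3, 3, byrow = TRUE))^2))
  lab <- array(0L, c(n, n, n))
  lab[r < rSS] <- 1L
  lab[r < rCSF] <- 2L
  lab[r < rGM] <- 4L
  new("VoxelHeadModel", labels = lab, spacing = h, origin = c(0, 0, 0))
}

# single-tissue optics with controllable coefficients; all five tissues
uniformOptics <- function(mu_a = 0.01, mu_s = 1, g = 0, n = 1) {
  data.frame(tissue = c("SS", "CSF1", "CSF2", "GM", "WM"),
             mu_a = mu_a, mu_s = mu_s, g = g, n = n,
             stringsAsFactors = FALSE)
}

# layout with one source on the top face (z = zTop) aimed straight down
topLayout <- function(src, dets, R = 2, zTarget = 0) {
  new("OptodeLayout", sources = matrix(src, 1, 3, byrow = TRUE),
      detectors = matrix(dets, ncol = 3, byrow = TRUE), patchRadius = R,
      launchTarget = c(src[1], src[2], zTarget), fitResidual = 0)
}

# hand-built photon record set on a given grid
makeRecords <- function(dims, spacing, detector, tof, paths) {
  # paths: list per photon of cbind(voxel, length)
  vox <- unlist(lapply(paths, function(p) p[, 1]))
  len <- unlist(lapply(paths, function(p) p[, 2]))
  ptr <- c(0, cumsum(vapply(paths, nrow, integer(1))))
  new("PhotonRecordSet", detector = as.integer(detector),
      tof = as.numeric(tof), ptr = as.numeric(ptr),
      voxel = as.integer(vox), pathlen = as.numeric(len),
      nLaunched = length(detector), nTerminated = 0,
      dims = as.integer(dims), spacing = spacing, sourceId = 1L, seed = 0)
}

# shared small Monte Carlo slab run (diffusive GM slab, one source,
# two detectors), reused by the forward, jacobian and approx tests
mcSlabRun <- function() fixture("mcSlabRun", function() {
  head <- slabHead(30, 30, 15)
  opt <- uniformOptics(mu_a = 0.01, mu_s = 2, g = 0.5, n = 1)
  lay <- topLayout(src = c(10, 15, 15), zTarget = 0,
                   dets = c(20, 15, 15, 15, 22, 15), R = 2.5)
  rec <- mcTransport(head, opt, lay, 1, 40000, seed = 7)
  list(head = head, optics = opt, layout = lay, records = rec,
       mu_a = absorptionVolume(head, opt))
})
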