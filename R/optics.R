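#' Default tissue optical parameter table at 800 nm
#'
#' Literature-based absorption coefficient mu_a (mm^-1), scattering
#' coefficient mu_s (mm^-1), anisotropy g, and refractive index n for the
#' five tissue compartments. The clear CSF compartment (CSF-2, sulci and
#' ventricles) is solver-specific: the Monte Carlo solver uses a clearer
#' medium (mu_a = 0.002, mu_s = 0.4), while the diffusion-approximation
#' solver treats CSF-2 like the semidiffusive subarachnoid CSF-1
#' (mu_a = 0.004, mu_s = 1.6), because the diffusion approximation is not
#' valid in nearly clear media.
#'
#' @param solver "mc" or "da"; selects the CSF-2 override.
#' @return data.frame with columns \code{tissue, mu_a, mu_s, g, n} and one
#'   row per tissue in label-code order (SS, CSF1, CSF2, GM, WM).
#' @export
tissueTable <- function(solver = c("mc", "da")) {
  solver <- match.arg(solver)
  tab <- data.frame(
    tissue = c("SS", "CSF1", "CSF2", "GM", "WM"),
    mu_a = c(0.015, 0.004, 0.002, 0.048, 0.037),
    mu_s = c(16, 1.6, 0.4, 5, 10),
    g = c(0.9, 0.9, 0.9, 0.9, 0.9),
    n = c(1.4, 1.4, 1.4, 1.4, 1.4),
    stringsAsFactors = FALSE)
  if (solver == "da") {
    tab$mu_a[tab$tissue == "CSF2"] <- 0.004
    tab$mu_s[tab$tissue == "CSF2"] <- 1.6
  }
  tab
}

#' Reduced scattering coefficient
#'
#' mu_s' = (1 - g) mu_s.
#'
#' @param mu_s scattering coefficient, mm^-1 (>= 0).
#' @param g scattering anisotropy in [-1, 1].
#' @return mu_s', mm^-1.
#' @export
reducedScattering <- function(mu_s, g) {
  if (any(mu_s < 0)) stop("mu_s must be >= 0")
  if (any(abs(g) > 1)) stop("g must lie in [-1, 1]")
  (1 - g) * mu_s
}

#' Diffusion coefficient
#'
#' kappa = 1 / (3 (mu_a + mu_s')), in mm.
#'
#' @param mu_a absorption coefficient, mm^-1.
#' @param mu_s_reduced reduced scattering coefficient mu_s', mm^-1.
#' @return kappa, mm.
#' @export
diffusionCoefficient <- function(mu_a, mu_s_reduced) {
  s <- mu_a + mu_s_reduced
  if (any(s <= 0)) stop("mu_a + mu_s' must be positive")
  1 / (3 * s)
}

.fresnelUnpolarized <- function(cti, ni, nt) {
  # reflectance for incidence cosine cti from medium ni into nt
  sti <- sqrt(pmax(0, 1 - cti^2))
  stt <- ni / nt * sti
  r <- ifelse(stt >= 1, 1, {
    ctt <- sqrt(pmax(0, 1 - stt^2))
    rs <- ((ni * cti - nt * ctt) / (ni * cti + nt * ctt))^2
    rp <- ((ni * ctt - nt * cti) / (ni * ctt + nt * cti))^2
    (rs + rp) / 2
  })
  r
}

#' Effective reflection coefficient of the diffuse boundary condition
#'
#' The scalar rho in the Robin boundary condition of the diffusion
#' approximation, modelling internal reflection at a refractive-index
#' mismatch. Computed by numerical integration of the unpolarized Fresnel
#' reflectance over the hemisphere of incidence angles (the standard
#' effective-reflectance construction): with
#' R_phi = int_0^{pi/2} 2 sin(t) cos(t) R_F(t) dt and
#' R_j = int_0^{pi/2} 3 sin(t) cos(t)^2 R_F(t) dt,
#' rho = (R_phi + R_j) / (2 - R_phi + R_j). Results are cached per index
#' pair. rho = 0 when the indices match and rho grows monotonically with
#' the interior/exterior index ratio.
#'
#' @param n_interior refractive index inside the domain (>= 1).
#' @param n_exterior refractive index outside (default 1, air).
#' @return rho in [0, 1).
#' @export
effectiveReflection <- local({
  cache <- new.env(parent = emptyenv())
  function(n_interior, n_exterior = 1.0) {
    if (n_interior < 1 || n_exterior < 1)
      stop("refractive indices must be >= 1")
    if (abs(n_interior - n_exterior) < 1e-12) return(0)
    key <- sprintf("%.10g|%.10g", n_interior, n_exterior)
    if (!is.null(cache[[key]])) return(cache[[key]])
    f_phi <- function(t) 2 * sin(t) * cos(t) *
      .fresnelUnpolarized(cos(t), n_interior, n_exterior)
    f_j <- function(t) 3 * sin(t) * cos(t)^2 *
      .fresnelUnpolarized(cos(t), n_interior, n_exterior)
    R_phi <- stats::integrate(f_phi, 0, pi / 2, rel.tol = 1e-10)$value
    R_j <- stats::integrate(f_j, 0, pi / 2, rel.tol = 1e-10)$value
    rho <- (R_phi + R_j) / (2 - R_phi + R_j)
    cache[[key]] <- rho
    rho
  }
})

#' Derived optical coefficients per tissue
#'
#' Expands a tissue table with the reduced scattering coefficient, the
#' diffusion coefficient, the speed of light in the medium
#' (c_vacuum / n, mm/ns) and the effective reflection coefficient against
#' an exterior index.
#'
#' @param table tissue table as from \code{\link{tissueTable}}.
#' @param n_exterior exterior refractive index (default 1).
#' @return the table with extra columns \code{mu_s_reduced, kappa,
#'   c_medium, rho}.
#' @export
derivedCoefficients <- function(table = tissueTable(), n_exterior = 1.0) {
  table$mu_s_reduced <- reducedScattering(table$mu_s, table$g)
  table$kappa <- diffusionCoefficient(table$mu_a, table$mu_s_reduced)
  table$c_medium <- speedOfLight() / table$n
  table$rho <- vapply(table$n, effectiveReflection, numeric(1),
                      n_exterior = n_exterior)
  table
}

#' Read/write a tissue table as CSV
#'
#' Plain CSV with header \code{tissue, mu_a, mu_s, g, n}; round-trips the
#' default table bit-exactly.
#'
#' @param table tissue table.
#' @param path file path.
#' @return \code{readTissueTable} returns the table.
#' @export
writeTissueTable <- function(table, path) {
  write.csv(table[, c("tissue", "mu_a", "mu_s", "g", "n")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTissueTable
#' @export
readTissueTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue", "mu_a", "mu_s", "g", "n")
  if (!all(need %in% names(tab)))
    stop("tissue table must have columns: ", paste(need, collapse = ", "))
  tab[, need]
}

# map a per-tissue column onto labels 1..5; label 0 gets NA
.tissueValue <- function(table, column) {
  v <- rep(NA_real_, max(.TISSUES))
  idx <- match(table$tissue, names(.TISSUES))
  if (any(is.na(idx))) stop("unknown tissue name in table")
  v[.TISSUES[idx]] <- table[[column]]
  v
}
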