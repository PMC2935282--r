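## Gaussian solvent model: smoothly thresholded atom-centered Gaussians.
##
## Each atom contributes a unit-height Gaussian with sigma = sigmaScale *
## vdW radius. The summed density rho_sum is thresholded through
## chi_s = 1 - exp(-A * rho_sum), giving a characteristic function that is
## ~1 at atom centers and decays smoothly to 0 in bulk solvent. The solvent
## mask exp(-A * rho_sum) is retained because the coordinate derivative
## needs it pointwise:
##   d chi_s / d alpha_i =
##     A * solvent(r_g) * occ_i * exp(-r^2/(2 sigma_i^2)) *
##     (r_g,alpha - r_i,alpha) / sigma_i^2.

#' Gaussian mask parameters
#'
#' @param A dimensionless thresholding scale (default 11.5).
#' @param sigmaScale multiplier on the vdW radius giving each atom's sigma
#'   (default 0.55).
#' @param supportSigma truncation cutoff for each atomic Gaussian, in sigma
#'   units (default 5; must be >= 3). The tail value at the cutoff is
#'   subtracted so the accumulated density is continuous at the support
#'   edge; the truncation error per atom is below 4e-6.
#' @return parameter list used by the Gaussian mask functions.
#' @examples
#' gaussianMaskParams()
#' @export
gaussianMaskParams <- function(A = 11.5, sigmaScale = 0.55, supportSigma = 5) {
  if (A <= 0) .stopf("A must be positive")
  if (sigmaScale <= 0) .stopf("sigmaScale must be positive")
  if (supportSigma < 3) .stopf("supportSigma must be at least 3")
  list(model = "gaussian", A = A, sigmaScale = sigmaScale,
       supportSigma = supportSigma)
}

#' Atom-centered Gaussian density
#'
#' Unit-height Gaussian \eqn{\exp(-r^2 / (2\sigma^2))}; the amplitude scale
#' of the model lives in the thresholding constant \code{A}, not here.
#'
#' @param r distance(s) in \eqn{\AA} (>= 0).
#' @param sigma Gaussian width in \eqn{\AA} (> 0).
#' @return density values in (0, 1].
#' @examples
#' atomicGaussian(0, 1)                 # 1
#' atomicGaussian(sqrt(2 * log(2)), 1)  # half height
#' @export
atomicGaussian <- function(r, sigma) {
  if (any(sigma <= 0)) .stopf("sigma must be positive")
  if (any(r < 0)) .stopf("distances must be non-negative")
  exp(-r^2 / (2 * sigma^2))
}

#' Accumulate the summed Gaussian density
#'
#' First pass of the Gaussian model: each grid point receives
#' \eqn{\rho_{sum} = \sum_i occ_i \exp(-r_{gi}^2 / (2\sigma_i^2))} over all
#' atoms (including symmetry-shell images) whose truncated support reaches
#' it.
#'
#' @param atoms atom data.frame (typically
#'   \code{expandSymmetryShell(model, 0)}: one record per symmetry copy;
#'   periodic lattice images are implicit through minimum-image
#'   accumulation); needs \code{x,y,z,occ,radius}.
#' @param grid a \linkS4class{DensityGrid} defining the geometry.
#' @param params from \code{\link{gaussianMaskParams}}.
#' @return a \linkS4class{DensityGrid} holding \eqn{\rho_{sum}}.
#' @export
accumulateRhoSum <- function(atoms, grid, params = gaussianMaskParams()) {
  vals <- array(0, dim = dim(grid@values))
  n <- dim(vals)
  if (nrow(atoms) > 0) {
    tail <- exp(-params$supportSigma^2 / 2)
    for (ia in seq_len(nrow(atoms))) {
      sigma <- params$sigmaScale * atoms$radius[ia]
      nb <- .gridNeighborhood(grid, c(atoms$x[ia], atoms$y[ia], atoms$z[ia]),
                              params$supportSigma * sigma)
      if (nrow(nb$idx) == 0) next
      li <- .linearIndex(nb$idx, n)
      vals[li] <- vals[li] +
        atoms$occ[ia] * pmax(exp(-nb$r^2 / (2 * sigma^2)) - tail, 0)
    }
  }
  densityGrid(grid@cell, values = vals)
}

#' Threshold the summed density into a solute/solvent mask pair
#'
#' Second pass of the Gaussian model: pointwise
#' \eqn{\chi_s = 1 - \exp(-A \rho_{sum})}, solvent \eqn{= \exp(-A \rho_{sum})}.
#'
#' @param rhoSum \linkS4class{DensityGrid} from
#'   \code{\link{accumulateRhoSum}}.
#' @param params from \code{\link{gaussianMaskParams}}.
#' @param sigmas optional per-atom sigma vector to record in the result.
#' @return a \linkS4class{MaskPair}.
#' @export
gaussianSoluteMask <- function(rhoSum, params = gaussianMaskParams(),
                               sigmas = numeric()) {
  v <- rhoSum@values
  if (min(v) < -1e-12)
    .stopf("negative rho_sum values: upstream accumulation is corrupt")
  solvent <- exp(-params$A * pmax(v, 0))
  new("MaskPair",
      solute = densityGrid(rhoSum@cell, values = 1 - solvent),
      solvent = densityGrid(rhoSum@cell, values = solvent),
      model = "gaussian", params = params, sigmas = sigmas)
}

#' Build the Gaussian mask pair for a crystal
#'
#' Convenience wrapper: symmetry-shell expansion, density accumulation and
#' thresholding in one call.
#'
#' @param model a \linkS4class{CrystalModel}.
#' @param grid a \linkS4class{DensityGrid} (geometry only), or NULL to build
#'   one from \code{dmin}.
#' @param params from \code{\link{gaussianMaskParams}}.
#' @param dmin resolution limit used when \code{grid} is NULL.
#' @param expanded optional precomputed operator expansion
#'   (\code{expandSymmetryShell(model, 0)}): one record per symmetry copy
#'   of each atom. Lattice periodicity is handled exactly by minimum-image
#'   distances in the grid queries, so explicit lattice-shell copies must
#'   not be passed here (they would be double-counted).
#' @return a \linkS4class{MaskPair}.
#' @examples
#' mdl <- toyCrystal(toySpec(nAtoms = 5, seed = 1))
#' mask <- gaussianMasks(mdl, dmin = 2.5)
#' range(gridValues(soluteMask(mask)))
#' @export
gaussianMasks <- function(model, grid = NULL, params = gaussianMaskParams(),
                          dmin = 2.0, expanded = NULL) {
  if (is.null(grid))
    grid <- densityGrid(model@cell, gridDimensions(model@cell, dmin))
  if (is.null(expanded)) expanded <- expandSymmetryShell(model, 0)
  rho <- accumulateRhoSum(expanded, grid, params)
  gaussianSoluteMask(rho, params,
                     sigmas = params$sigmaScale * model@atoms$radius)
}

#' Coordinate derivative of the Gaussian solute mask
#'
#' Derivative of \eqn{\chi_s} at grid points with respect to one atom's
#' Cartesian position, from the chain rule through the thresholding
#' exponential. Vectorized over grid points.
#'
#' @param dvec n-by-3 matrix of offsets (grid point minus atom position,
#'   Cartesian \eqn{\AA}, minimum image).
#' @param solvent solvent-mask values at those grid points.
#' @param sigma the atom's Gaussian width (\eqn{\AA}).
#' @param A thresholding scale.
#' @param occ atom occupancy.
#' @return n-by-3 matrix of \eqn{\partial\chi_s/\partial\alpha_i}.
#' @export
gaussianMaskGradient <- function(dvec, solvent, sigma, A = 11.5, occ = 1) {
  r2 <- rowSums(dvec^2)
  coef <- A * solvent * occ * exp(-r2 / (2 * sigma^2)) / sigma^2
  dvec * coef
}

#' @rdname MaskPair-class
#' @param object a MaskPair.
#' @export
setMethod("soluteMask", "MaskPair", function(object) object@solute)

#' @rdname MaskPair-class
#' @export
setMethod("solventMask", "MaskPair", function(object) object@solvent)

setMethod("show", "MaskPair", function(object) {
  v <- object@solute@values
  cat(sprintf("MaskPair (%s model): grid %s, solute fraction %.3f\n",
              object@model, paste(dim(v), collapse = " x "), mean(v)))
})
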