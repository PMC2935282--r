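## Coordinate gradients of the refinement target, propagated through both
## the atomic structure factors and the smooth bulk-solvent mask.
##
## The solvent chain term works in three stages:
##   (i)  per reflection, dT/dF_m = -k_s exp(-B_s s^2/4) * dT/dF_t;
##   (ii) an inverse FFT turns those coefficients into a real-space
##        derivative map D(r_g) on the mask grid;
##   (iii) per atom (including every symmetry/lattice image, rotated back
##        onto its unique atom), the mask's analytic point derivative is
##        accumulated against D over the atom's support.
## The binary mask is indicator-valued, hence not differentiable: asking
## for its gradients is an error by design.

.maskBuilders <- list(
  gaussian = function(model, grid, params, expanded)
    gaussianMasks(model, grid = grid, params = params, expanded = expanded),
  polynomial = function(model, grid, params, expanded)
    polynomialMasks(model, grid = grid, params = params, expanded = expanded),
  binary = function(model, grid, params, expanded)
    binaryMasks(model, grid = grid, params = params, expanded = expanded))

.defaultMaskParams <- function(maskModel) {
  switch(maskModel,
         gaussian = gaussianMaskParams(),
         polynomial = polynomialMaskParams(),
         binary = binaryMaskParams(),
         none = NULL,
         .stopf("unknown mask model '%s'", maskModel))
}

#' Evaluate the solvent-corrected refinement target
#'
#' Full forward pass for one coordinate set: symmetry-shell expansion, mask
#' construction, \eqn{F_c}, \eqn{F_m}, \eqn{F_t} and the least-squares
#' target against \code{fobs} stored in \code{refl}.
#'
#' @param model a \linkS4class{CrystalModel}.
#' @param refl a \linkS4class{ReflectionSet} with \code{fobs} (and
#'   optionally \code{free}) filled.
#' @param maskModel "gaussian", "polynomial", "binary" or "none".
#' @param maskParams mask parameter list (model-specific defaults if NULL).
#' @param solvParams from \code{\link{solventScaleParams}}.
#' @param grid optional \linkS4class{DensityGrid} fixing the mask geometry;
#'   built from \code{dmin} otherwise.
#' @param dmin resolution for the default grid.
#' @param weights optional target weights.
#' @return list with \code{value}, \code{scale}, \code{refl} (structure
#'   factors filled), \code{mask}, \code{expanded}, \code{grid},
#'   \code{dTdFmodel}.
#' @export
solventTarget <- function(model, refl, maskModel = "gaussian",
                          maskParams = NULL,
                          solvParams = solventScaleParams(), grid = NULL,
                          dmin = 2.0, weights = NULL) {
  stopifnot(length(refl@fobs) > 0)
  if (is.null(maskParams)) maskParams <- .defaultMaskParams(maskModel)
  if (is.null(grid))
    grid <- densityGrid(model@cell, gridDimensions(model@cell, dmin))
  expanded <- expandSymmetryShell(model, 0)
  mask <- if (maskModel == "none") NULL
          else .maskBuilders[[maskModel]](model, grid, maskParams, expanded)
  refl <- computeStructureFactors(refl, model, mask, solvParams)
  free <- if (length(refl@free)) refl@free else NULL
  lst <- leastSquaresTarget(refl@fobs, Mod(refl@ft), weights, free)
  list(value = lst$value, scale = lst$scale, refl = refl, mask = mask,
       expanded = expanded, grid = grid, dTdFmodel = lst$dTdFmodel,
       maskParams = maskParams, solvParams = solvParams, weights = weights)
}

#' Target as a function of the coordinate matrix
#'
#' Returns a closure \code{function(xyz)} evaluating the refinement target
#' for an n-by-3 Cartesian coordinate matrix (same atom order as the
#' model), rebuilding the mask and all structure factors at every call.
#' This is the function the finite-difference verifications probe.
#'
#' @inheritParams solventTarget
#' @return a function mapping an n-by-3 matrix to the scalar target.
#' @export
solventTargetFunction <- function(model, refl, maskModel = "gaussian",
                                  maskParams = NULL,
                                  solvParams = solventScaleParams(),
                                  grid = NULL, dmin = 2.0, weights = NULL) {
  if (is.null(grid))
    grid <- densityGrid(model@cell, gridDimensions(model@cell, dmin))
  force(maskParams); force(solvParams); force(weights)
  function(xyz) {
    m <- model
    at <- m@atoms
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    m@atoms <- at
    solventTarget(m, refl, maskModel, maskParams, solvParams, grid = grid,
                  weights = weights)$value
  }
}

#' Double-wide finite difference
#'
#' Central difference \eqn{(f(x + \Delta) - f(x - \Delta)) / (2\Delta)},
#' the criterion used to verify every analytic gradient in the package.
#'
#' @param f function of a scalar.
#' @param x expansion point.
#' @param dx step (> 0).
#' @return numeric derivative estimate.
#' @examples
#' finiteDifferenceGradient(function(x) x^2, 1, 0.1)  # exactly 2
#' @export
finiteDifferenceGradient <- function(f, x, dx) {
  if (dx <= 0) .stopf("dx must be positive")
  (f(x + dx) - f(x - dx)) / (2 * dx)
}

## Support cutoff of one atom's mask contribution.
.maskSupport <- function(maskModel, maskParams, radius) {
  switch(maskModel,
         gaussian = maskParams$supportSigma * maskParams$sigmaScale * radius,
         polynomial = radius + maskParams$w,
         .stopf("mask model '%s' has no differentiable support", maskModel))
}

#' Analytic coordinate gradients of the refinement target
#'
#' Total per-atom Cartesian gradient of the least-squares target,
#' decomposed into the atomic-scattering chain term and the bulk-solvent
#' chain term. Contributions arriving through symmetry images are rotated
#' back onto the unique atoms. The binary mask model is rejected: an
#' indicator-valued mask has no coordinate derivative.
#'
#' @inheritParams solventTarget
#' @param includeSolventTerm include the solvent chain term? Setting FALSE
#'   reproduces the systematic finite-difference mismatch seen when the
#'   mask derivatives are omitted (an ablation, not a mode to use).
#' @return a \linkS4class{GradientField}.
#' @export
coordinateGradients <- function(model, refl, maskModel = "gaussian",
                                maskParams = NULL,
                                solvParams = solventScaleParams(),
                                grid = NULL, dmin = 2.0,
                                weights = NULL, includeSolventTerm = TRUE) {
  if (maskModel == "binary" && includeSolventTerm)
    .stopf("the binary mask is not differentiable with respect to atomic coordinates")
  fw <- solventTarget(model, refl, maskModel, maskParams, solvParams,
                      grid = grid, dmin = dmin, weights = weights)
  refl <- fw$refl
  cell <- model@cell
  nAt <- nrow(model@atoms)
  amp <- Mod(refl@ft)
  ## complex weight: dT/dF_t contracted against Re(conj(ft)/|ft| * dF_t)
  u <- fw$dTdFmodel * Conj(refl@ft) * ifelse(amp > 0, 1 / amp, 0)

  ## --- atomic-scattering chain term -------------------------------------
  at <- model@atoms
  s <- refl@s
  fmat <- matrix(0, length(s), nAt)
  for (el in unique(at$element)) {
    sel <- at$element == el
    fmat[, sel] <- formFactor(el, s)
  }
  coef <- exp(outer(-s^2 / 4, at$b)) * fmat * rep(at$occ, each = length(s))
  frac <- fractionalize(cell, as.matrix(at[, c("x", "y", "z")]))
  gAtomic <- matrix(0, nAt, 3)
  for (op in model@symmetry) {
    pos <- frac %*% t(op$R) + rep(op$t, each = nAt)
    phase <- 2 * pi * (refl@hkl %*% t(pos))
    W <- Re((2i * pi * u) * coef * exp(1i * phase))
    cartv <- (refl@hkl %*% op$R) %*% cell@fracMat
    gAtomic <- gAtomic + t(W) %*% cartv
  }

  ## --- bulk-solvent chain term ------------------------------------------
  gSolvent <- matrix(0, nAt, 3)
  if (maskModel != "none" && includeSolventTerm) {
    n <- dim(fw$grid@values)
    att <- solventScale(s, solvParams)
    Garr <- array(0i, dim = n)
    idx <- refl@hkl %% rep(n, each = nrow(refl@hkl)) + 1L
    li <- .linearIndex(idx, n)
    gvals <- -att * u
    ## accumulate (indices are unique for a Friedel-unique list on a grid
    ## obeying |h_k| < n_k/2, but accumulate defensively)
    for (j in seq_along(li)) Garr[li[j]] <- Garr[li[j]] + gvals[j]
    D <- Re(fft(Garr, inverse = TRUE)) * (cellVolume(cell) / prod(n))

    solvent <- fw$mask@solvent
    prm <- fw$maskParams
    exp_ <- fw$expanded
    for (ir in seq_len(nrow(exp_))) {
      cutoff <- .maskSupport(maskModel, prm, exp_$radius[ir])
      nb <- .gridNeighborhood(fw$grid, c(exp_$x[ir], exp_$y[ir], exp_$z[ir]),
                              cutoff)
      if (nrow(nb$idx) == 0) next
      lidx <- .linearIndex(nb$idx, n)
      dchi <- if (maskModel == "gaussian")
        gaussianMaskGradient(nb$dvec, solvent@values[lidx],
                             prm$sigmaScale * exp_$radius[ir], prm$A,
                             exp_$occ[ir])
      else
        polynomialMaskGradient(nb$dvec, nb$r, solvent@values[lidx],
                               exp_$radius[ir], prm$w, exp_$occ[ir])
      gImg <- drop(crossprod(dchi, D[lidx]))
      op <- model@symmetry[[exp_$op[ir]]]
      ## dp_image/dr_unique is the Cartesian rotation orth %*% R %*% frac
      rot <- cell@orthMat %*% op$R %*% cell@fracMat
      gSolvent[exp_$parent[ir], ] <- gSolvent[exp_$parent[ir], ] +
        drop(t(rot) %*% gImg)
    }
  }

  new("GradientField", total = gAtomic + gSolvent, atomic = gAtomic,
      solvent = gSolvent, target = fw$value, model = maskModel)
}

setMethod("show", "GradientField", function(object) {
  cat(sprintf("GradientField (%s model): %d atoms, target = %.6g\n",
              object@model, nrow(object@total), object@target))
  cat(sprintf("  |grad| rms total %.4g, atomic %.4g, solvent %.4g\n",
              sqrt(mean(object@total^2)), sqrt(mean(object@atomic^2)),
              sqrt(mean(object@solvent^2))))
})
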