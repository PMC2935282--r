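## Synthetic toy crystals and simulated observations. These stand in for
## deposited macromolecular structures at desk scale: a cluster of atoms
## (a "solute blob") in a mostly-solvent P1 or two-operator cell, with a
## water-like single atom near the solute surface for the translation-scan
## experiments, and noiseless-or-noisy amplitudes generated from a chosen
## true solvent model so parameter recovery has a known answer.

#' Specification for a synthetic toy crystal
#'
#' The seed fully determines the fixture: same seed, identical atoms,
#' identical observations.
#'
#' @param cell cell lengths (length 3) in \eqn{\AA}.
#' @param angles cell angles (length 3) in degrees.
#' @param symmetry "P1" or a list of \code{\link{symOp}} operators.
#' @param nAtoms number of atoms including the water-like atom (>= 1).
#' @param elements element pool sampled for the cluster atoms.
#' @param minSep minimum pairwise separation under the periodic metric
#'   (\eqn{\AA}, > 1.5).
#' @param placement "cluster" (atoms in a central ball, leaving bulk
#'   solvent channels) or "uniform".
#' @param dmin resolution limit for observations.
#' @param trueModel solvent model generating the observations
#'   ("gaussian", "polynomial", "binary", "none").
#' @param ks,bs true solvent parameters.
#' @param noise relative Gaussian amplitude noise (0 = noiseless).
#' @param freeFrac fraction of reflections flagged free (default 0.10).
#' @param seed integer random seed.
#' @return specification list.
#' @examples
#' spec <- toySpec(nAtoms = 10, seed = 7)
#' toyCrystal(spec)
#' @export
toySpec <- function(cell = c(18, 20, 22), angles = c(90, 90, 90),
                    symmetry = "P1", nAtoms = 20,
                    elements = c("C", "C", "C", "N", "O", "S"),
                    minSep = 2.0, placement = "cluster", dmin = 2.0,
                    trueModel = "gaussian", ks = 0.33, bs = 50,
                    noise = 0, freeFrac = 0.10, seed = 1) {
  if (minSep <= 1.5) .stopf("minimum separation must exceed 1.5 A")
  if (nAtoms < 1) .stopf("at least one atom is required")
  list(cell = cell, angles = angles, symmetry = symmetry, nAtoms = nAtoms,
       elements = elements, minSep = minSep, placement = placement,
       dmin = dmin, trueModel = trueModel, ks = ks, bs = bs, noise = noise,
       freeFrac = freeFrac, seed = seed)
}

## Periodic minimum-image distance between one point and a matrix of points.
.periodicDist <- function(cell, x, pts) {
  if (nrow(pts) == 0) return(numeric())
  df <- .wrapHalf(sweep(fractionalize(cell, pts), 2,
                        drop(fractionalize(cell, x)), "-"))
  sqrt(rowSums((df %*% t(cell@orthMat))^2))
}

#' Build a reproducible toy crystal
#'
#' Places \code{nAtoms - 1} cluster atoms (rejection sampling under the
#' periodic minimum-separation constraint) plus one water-like oxygen just
#' outside the cluster surface, flagged in the \code{water} column. B
#' factors are drawn uniformly from [10, 30] \eqn{\AA^2}; occupancies are
#' 1.
#'
#' @param spec from \code{\link{toySpec}}.
#' @return a \linkS4class{CrystalModel}.
#' @export
toyCrystal <- function(spec = toySpec()) {
  cell <- unitCell(spec$cell[1], spec$cell[2], spec$cell[3],
                   spec$angles[1], spec$angles[2], spec$angles[3])
  nCluster <- spec$nAtoms - 1L
  .withSeed(spec$seed, {
    center <- orthogonalize(cell, c(0.5, 0.5, 0.5))
    ballR <- min(cellLengths(cell)) / 4
    pos <- matrix(0, 0, 3)
    tries <- 0
    while (nrow(pos) < nCluster) {
      tries <- tries + 1
      if (tries > 2000 * max(1, nCluster))
        .stopf("could not place %d atoms at %.1f A separation", nCluster,
               spec$minSep)
      cand <- if (spec$placement == "cluster") {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        center + ballR * runif(1)^(1 / 3) * u
      } else {
        orthogonalize(cell, runif(3))
      }
      if (all(.periodicDist(cell, cand, pos) >= spec$minSep))
        pos <- rbind(pos, cand)
    }
    elements <- if (nCluster > 0)
      sample(spec$elements, nCluster, replace = TRUE) else character()
    ## water-like atom just outside the solute surface
    waterOK <- FALSE
    tries <- 0
    while (!waterOK) {
      tries <- tries + 1
      if (tries > 5000) .stopf("could not place the water-like atom")
      if (nCluster > 0) {
        anchor <- pos[sample.int(nCluster, 1), ]
        u <- anchor - center
        if (sum(u^2) < 1e-6) u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        wat <- anchor + runif(1, 2.8, 3.4) * u
      } else {
        wat <- center + c(3, 0, 0)
      }
      waterOK <- all(.periodicDist(cell, wat, pos) >= spec$minSep)
    }
    at <- data.frame(element = c(elements, "O"),
                     x = c(pos[, 1], wat[1]),
                     y = c(pos[, 2], wat[2]),
                     z = c(pos[, 3], wat[3]),
                     occ = 1,
                     b = runif(spec$nAtoms, 10, 30),
                     water = c(rep(FALSE, nCluster), TRUE))
    sym <- if (identical(spec$symmetry, "P1")) list(symOp()) else spec$symmetry
    crystalModel(cell, at, symmetry = sym,
                 id = sprintf("toy-seed%d", spec$seed))
  })
}

#' Simulate observed amplitudes from a true solvent model
#'
#' Computes \eqn{|F_t|} for the crystal under the specified true mask
#' model and \eqn{(k_s, B_s)}, optionally applies relative Gaussian noise,
#' assigns sigmas (\code{noise * amplitude}) and flags a seeded random
#' subset of reflections free.
#'
#' @param model a \linkS4class{CrystalModel} (typically from
#'   \code{\link{toyCrystal}}).
#' @param spec from \code{\link{toySpec}}; supplies d_min, true model and
#'   parameters, noise, free fraction and seed.
#' @return a \linkS4class{ReflectionSet} with \code{fobs}, \code{sigobs},
#'   \code{free} filled; \code{fc}, \code{fm}, \code{ft} hold the
#'   truth-model structure factors.
#' @examples
#' spec <- toySpec(nAtoms = 8, dmin = 3.0, seed = 2)
#' refl <- syntheticObservations(toyCrystal(spec), spec)
#' refl
#' @export
syntheticObservations <- function(model, spec = toySpec()) {
  refl <- makeReflectionSet(model@cell, spec$dmin)
  grid <- densityGrid(model@cell, gridDimensions(model@cell, spec$dmin))
  expanded <- expandSymmetryShell(model, 0)
  mask <- if (spec$trueModel == "none") NULL
          else .maskBuilders[[spec$trueModel]](model, grid,
                 .defaultMaskParams(spec$trueModel), expanded)
  refl <- computeStructureFactors(refl, model, mask,
                                  solventScaleParams(spec$ks, spec$bs))
  amp <- Mod(refl@ft)
  .withSeed(spec$seed + 1000003L, {
    fobs <- if (spec$noise > 0)
      pmax(amp * (1 + spec$noise * rnorm(length(amp))), 1e-6) else amp
    nfree <- round(spec$freeFrac * length(amp))
    free <- rep(FALSE, length(amp))
    if (nfree > 0) free[sample.int(length(amp), nfree)] <- TRUE
    refl@fobs <- fobs
    refl@sigobs <- spec$noise * amp
    refl@free <- free
  })
  validObject(refl)
  refl
}
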