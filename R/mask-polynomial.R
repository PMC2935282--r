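## Polynomial solvent model: multiplicative cubic switch at the vdW
## boundary.
##
## For an atom of radius a and window half-width w, the window coordinate is
## d = r - a + w, so the switch runs over r in (a - w, a + w). With
## t = d/(2w):
##   S = 1            for d <= 0        (inside the core)
##   S = 1 - 3t^2 + 2t^3  for 0 < d < 2w
##   S = 0            for d >= 2w       (bulk)
## and dS/dd = -6 t (1 - t) / (2w) inside the window. S is C1 at both
## endpoints. The solvent density is the product over atoms of
## h_i = 1 - occ_i * S_i; the solute mask is chi_s = 1 - prod(h_i). The
## product form keeps the mask exactly 0/1 outside the transition zones —
## a compactly supported transition, unlike the Gaussian model.

#' Polynomial mask parameters
#'
#' @param w window half-width in \eqn{\AA} (default 0.8). Must be positive
#'   and smaller than every atom radius so the switch never crosses r = 0.
#' @return parameter list used by the polynomial mask functions.
#' @examples
#' polynomialMaskParams()
#' @export
polynomialMaskParams <- function(w = 0.8) {
  if (w <= 0) .stopf("window half-width w must be positive")
  list(model = "polynomial", w = w)
}

#' Cubic switch function and its slope
#'
#' Evaluates the C1 cubic switch on the window coordinate
#' \code{d = r - a + w}.
#'
#' @param d window coordinate(s) in \eqn{\AA}.
#' @param w window half-width in \eqn{\AA} (> 0).
#' @return list with numeric vectors \code{S} (switch value, 1 at
#'   \code{d <= 0}, 0 at \code{d >= 2w}) and \code{dS} (dS/dd, 0 outside
#'   the window).
#' @examples
#' switchValue(0.8, 0.8)$S   # 0.5 at the window midpoint (r = a)
#' switchValue(0, 0.8)       # endpoint fixed at one, zero slope
#' @export
switchValue <- function(d, w) {
  if (w <= 0) .stopf("window half-width w must be positive")
  t <- pmin(pmax(d / (2 * w), 0), 1)
  inw <- d > 0 & d < 2 * w
  S <- ifelse(d <= 0, 1, ifelse(d >= 2 * w, 0, 1 - 3 * t^2 + 2 * t^3))
  dS <- ifelse(inw, -6 * t * (1 - t) / (2 * w), 0)
  list(S = S, dS = dS)
}

#' Build the polynomial mask pair for a crystal
#'
#' Single pass over the atoms: each atom multiplies its factor
#' \eqn{h_i = 1 - occ_i S_i} into the solvent grid over the points within
#' \eqn{a_i + w} of its center; everything farther keeps the empty-product
#' value 1.
#'
#' @inheritParams gaussianMasks
#' @param params from \code{\link{polynomialMaskParams}}.
#' @return a \linkS4class{MaskPair}.
#' @examples
#' mdl <- toyCrystal(toySpec(nAtoms = 5, seed = 1))
#' mask <- polynomialMasks(mdl, dmin = 2.5)
#' range(gridValues(soluteMask(mask)))
#' @export
polynomialMasks <- function(model, grid = NULL,
                            params = polynomialMaskParams(), dmin = 2.0,
                            expanded = NULL) {
  if (is.null(grid))
    grid <- densityGrid(model@cell, gridDimensions(model@cell, dmin))
  if (is.null(expanded)) expanded <- expandSymmetryShell(model, 0)
  if (any(model@atoms$radius <= params$w))
    .stopf("every atom radius must exceed the window half-width w = %.2f",
           params$w)
  solvent <- array(1, dim = dim(grid@values))
  n <- dim(solvent)
  for (ia in seq_len(nrow(expanded))) {
    a <- expanded$radius[ia]
    nb <- .gridNeighborhood(grid, c(expanded$x[ia], expanded$y[ia],
                                    expanded$z[ia]), a + params$w)
    if (nrow(nb$idx) == 0) next
    sw <- switchValue(nb$r - a + params$w, params$w)
    li <- .linearIndex(nb$idx, n)
    solvent[li] <- solvent[li] * (1 - expanded$occ[ia] * sw$S)
  }
  new("MaskPair",
      solute = densityGrid(grid@cell, values = 1 - solvent),
      solvent = densityGrid(grid@cell, values = solvent),
      model = "polynomial", params = params, sigmas = numeric())
}

#' Coordinate derivative of the polynomial solute mask
#'
#' Derivative of \eqn{\chi_s} at grid points with respect to one atom's
#' Cartesian position. Only points strictly inside the atom's switch window
#' contribute; elsewhere the switch is locally constant and the derivative
#' is zero. The factor \eqn{\rho_{solv}/h_i} (the product over the other
#' atoms) never divides by zero in exact arithmetic because dS/dd vanishes
#' wherever \eqn{h_i} does; underflowed zero factors are guarded to a zero
#' contribution.
#'
#' @param dvec n-by-3 matrix of offsets (grid point minus atom position).
#' @param r distances corresponding to \code{dvec}.
#' @param solvent solvent-mask values \eqn{\rho_{solv}} at the points.
#' @param radius the atom's radius \eqn{a}.
#' @param w window half-width.
#' @param occ atom occupancy.
#' @return n-by-3 matrix of \eqn{\partial\chi_s/\partial\alpha_i}.
#' @export
polynomialMaskGradient <- function(dvec, r, solvent, radius, w, occ = 1) {
  sw <- switchValue(r - radius + w, w)
  h <- 1 - occ * sw$S
  ratio <- ifelse(h > 0, solvent / h, 0)
  coef <- -ratio * occ * sw$dS / pmax(r, 1e-300)
  dvec * coef
}
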