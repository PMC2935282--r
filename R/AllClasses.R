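## S4 class definitions for the crystallographic data model.

#' UnitCell: crystallographic unit cell
#'
#' Holds cell lengths (\eqn{\AA}) and angles (degrees) together with the
#' derived orthogonalization matrix (fractional to Cartesian), its inverse,
#' and the cell volume. All mask arithmetic in the package is done in
#' Cartesian \eqn{\AA}; fractional coordinates appear only at I/O and
#' symmetry boundaries.
#'
#' @slot a,b,c cell edge lengths in \eqn{\AA}.
#' @slot alpha,beta,gamma cell angles in degrees.
#' @slot orthMat 3x3 matrix mapping fractional to Cartesian coordinates.
#' @slot fracMat 3x3 inverse of \code{orthMat}.
#' @slot volume cell volume in \eqn{\AA^3}.
#' @exportClass UnitCell
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric",
                 orthMat = "matrix", fracMat = "matrix", volume = "numeric"),
  validity = function(object) {
    msg <- character()
    len <- c(object@a, object@b, object@c)
    ang <- c(object@alpha, object@beta, object@gamma)
    if (any(!is.finite(len)) || any(len <= 0))
      msg <- c(msg, "cell lengths must be positive and finite")
    if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
      msg <- c(msg, "cell angles must lie strictly between 0 and 180 degrees")
    if (length(msg) == 0 && (!is.finite(object@volume) || object@volume <= 0))
      msg <- c(msg, "cell volume must be positive (angles are degenerate)")
    if (length(msg)) msg else TRUE
  })

#' CrystalModel: unit cell, symmetry and atoms
#'
#' The central container: a \linkS4class{UnitCell}, a list of symmetry
#' operators in fractional coordinates (identity first), and an atom table.
#' The atom table is a data.frame with columns \code{element}, \code{x},
#' \code{y}, \code{z} (Cartesian \eqn{\AA}), \code{occ}, \code{b}
#' (isotropic B, \eqn{\AA^2}), \code{radius} (van der Waals, \eqn{\AA}) and
#' \code{water} (logical flag for water-like surface atoms used by the
#' translation-scan experiments).
#'
#' @slot cell a \linkS4class{UnitCell}.
#' @slot symmetry list of \code{list(R = 3x3, t = length-3)} fractional
#'   operators; the identity is always first.
#' @slot atoms atom data.frame (see description).
#' @slot id free-text identifier.
#' @exportClass CrystalModel
setClass("CrystalModel",
  representation(cell = "UnitCell", symmetry = "list", atoms = "data.frame",
                 id = "character"),
  validity = function(object) {
    msg <- character()
    at <- object@atoms
    need <- c("element", "x", "y", "z", "occ", "b", "radius")
    if (!all(need %in% names(at)))
      msg <- c(msg, paste("atom table must have columns:",
                          paste(need, collapse = ", ")))
    else {
      if (nrow(at) < 1) msg <- c(msg, "at least one atom is required")
      if (any(at$radius <= 0)) msg <- c(msg, "vdW radii must be positive")
      if (any(at$b < 0)) msg <- c(msg, "B factors must be non-negative")
      if (any(at$occ < 0 | at$occ > 1))
        msg <- c(msg, "occupancies must lie in [0, 1]")
    }
    if (length(object@symmetry) < 1)
      msg <- c(msg, "symmetry operator list must contain the identity")
    else {
      op <- object@symmetry[[1]]
      if (max(abs(op$R - diag(3))) > 1e-9 || max(abs(op$t)) > 1e-9)
        msg <- c(msg, "first symmetry operator must be the identity")
    }
    if (length(msg)) msg else TRUE
  })

#' DensityGrid: real-space scalar field over one unit cell
#'
#' A 3D array of values sampled at fractional positions
#' \eqn{(i/n_x, j/n_y, k/n_z)} with \eqn{i = 0, \dots, n_x - 1} (array index
#' \code{i + 1}: R arrays are 1-based, grid offsets are 0-based). Indexing is
#' periodic: index \eqn{n} is the same point as index 0.
#'
#' @slot values numeric 3D array.
#' @slot cell the owning \linkS4class{UnitCell}.
#' @exportClass DensityGrid
setClass("DensityGrid",
  representation(values = "array", cell = "UnitCell"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3) return("values must be a 3D array")
    if (any(d < 2)) return("grid dimensions must be at least 2 per axis")
    if (any(!is.finite(object@values))) return("grid values must be finite")
    TRUE
  })

#' MaskPair: solute and solvent characteristic functions
#'
#' The solute mask \eqn{\chi_s} (1 in the solute, 0 in bulk solvent) and the
#' complementary solvent mask \eqn{1 - \chi_s} on the same grid. The solvent
#' mask is retained because the coordinate derivatives of the smooth models
#' need it pointwise.
#'
#' @slot solute,solvent \linkS4class{DensityGrid}s with values in [0, 1]
#'   summing to 1 pointwise.
#' @slot model one of "gaussian", "polynomial", "binary".
#' @slot params the parameter list that produced the masks.
#' @slot sigmas per-atom Gaussian sigma values (empty for other models).
#' @exportClass MaskPair
setClass("MaskPair",
  representation(solute = "DensityGrid", solvent = "DensityGrid",
                 model = "character", params = "list", sigmas = "numeric"),
  validity = function(object) {
    a <- object@solute@values; b <- object@solvent@values
    if (!identical(dim(a), dim(b)))
      return("solute and solvent grids must share dimensions")
    if (min(a) < -1e-9 || max(a) > 1 + 1e-9)
      return("solute mask values must lie in [0, 1]")
    if (max(abs(a + b - 1)) > 1e-9)
      return("solute + solvent must equal 1 at every grid point")
    if (!object@model %in% c("gaussian", "polynomial", "binary"))
      return("model must be gaussian, polynomial or binary")
    TRUE
  })

#' ReflectionSet: Miller indices with structure factors and observations
#'
#' Reflection list for one crystal: integer Miller indices, the reciprocal
#' coordinate \eqn{s = 1/d} per reflection, complex structure factors
#' (\code{fc} atomic, \code{fm} mask, \code{ft} solvent-corrected total) and
#' optional observed amplitudes with sigmas and free-R flags. F(000) is never
#' a member. Complex/observation slots may be empty (length 0) until filled.
#'
#' @slot hkl integer matrix, one row per reflection.
#' @slot s numeric, \eqn{1/d} in \eqn{\AA^{-1}}.
#' @slot fc,fm,ft complex vectors (length 0 or nrow(hkl)).
#' @slot fobs,sigobs numeric vectors (length 0 or nrow(hkl)).
#' @slot free logical vector (length 0 or nrow(hkl)).
#' @slot dmin high-resolution limit in \eqn{\AA}.
#' @slot cell the \linkS4class{UnitCell} the indices refer to.
#' @exportClass ReflectionSet
setClass("ReflectionSet",
  representation(hkl = "matrix", s = "numeric", fc = "complex",
                 fm = "complex", ft = "complex", fobs = "numeric",
                 sigobs = "numeric", free = "logical", dmin = "numeric",
                 cell = "UnitCell"),
  validity = function(object) {
    n <- nrow(object@hkl)
    msg <- character()
    if (ncol(object@hkl) != 3) msg <- c(msg, "hkl must have 3 columns")
    if (any(rowSums(object@hkl == 0) == 3))
      msg <- c(msg, "F(000) must not be part of a reflection set")
    if (anyDuplicated(object@hkl))
      msg <- c(msg, "duplicate Miller indices")
    if (length(object@s) != n) msg <- c(msg, "s must match hkl rows")
    for (sl in c("fc", "fm", "ft", "fobs", "sigobs", "free")) {
      v <- slot(object, sl)
      if (!length(v) %in% c(0L, n))
        msg <- c(msg, sprintf("slot %s must have length 0 or %d", sl, n))
    }
    if (length(msg)) msg else TRUE
  })

#' GradientField: per-atom coordinate derivatives of a refinement target
#'
#' Cartesian derivative triples of a scalar target with respect to each
#' unique atom, decomposed into the atomic-scattering chain term and the
#' bulk-solvent chain term (total = atomic + solvent).
#'
#' @slot total,atomic,solvent n-by-3 numeric matrices (target units per
#'   \eqn{\AA}).
#' @slot target the target value at the expansion point.
#' @slot model the mask model the solvent term was computed with.
#' @exportClass GradientField
setClass("GradientField",
  representation(total = "matrix", atomic = "matrix", solvent = "matrix",
                 target = "numeric", model = "character"),
  validity = function(object) {
    if (!identical(dim(object@total), dim(object@atomic)) ||
        !identical(dim(object@total), dim(object@solvent)))
      return("gradient components must share dimensions")
    if (ncol(object@total) != 3) return("gradients are n-by-3 matrices")
    if (any(!is.finite(object@total))) return("gradients must be finite")
    if (max(abs(object@total - object@atomic - object@solvent)) > 1e-8)
      return("total must equal atomic + solvent")
    TRUE
  })
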