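## Unit-cell geometry: orthogonalization, fractionalization, reciprocal
## metric. Convention: s = 1/d, so the Debye-Waller attenuation for an
## isotropic B is exp(-B s^2 / 4).

#' Construct a UnitCell
#'
#' Builds a \linkS4class{UnitCell} from lengths (\eqn{\AA}) and angles
#' (degrees) using the standard PDB orthogonalization convention (a along x,
#' b in the xy plane).
#'
#' @param a,b,c cell lengths in \eqn{\AA}.
#' @param alpha,beta,gamma cell angles in degrees (default 90).
#' @return a \linkS4class{UnitCell}.
#' @examples
#' cell <- unitCell(20, 22, 24)
#' cellVolume(cell)
#' fractionalize(cell, c(10, 11, 12))
#' @export
unitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(!is.finite(c(a, b, c))) || any(c(a, b, c) <= 0))
    .stopf("cell lengths must be positive")
  ang <- c(alpha, beta, gamma)
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    .stopf("cell angles must lie strictly between 0 and 180 degrees")
  ca <- cos(.deg2rad(alpha)); cb <- cos(.deg2rad(beta))
  cg <- cos(.deg2rad(gamma)); sg <- sin(.deg2rad(gamma))
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (!is.finite(disc) || disc <= 0)
    .stopf("degenerate cell: angles (%g, %g, %g) give non-positive volume",
           alpha, beta, gamma)
  vol <- a * b * c * sqrt(disc)
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0, vol / (a * b * sg)), nrow = 3, byrow = TRUE)
  new("UnitCell", a = a, b = b, c = c,
      alpha = alpha, beta = beta, gamma = gamma,
      orthMat = orth, fracMat = solve(orth), volume = vol)
}

#' @rdname UnitCell-class
#' @export
setMethod("cellVolume", "UnitCell", function(object) object@volume)

#' @rdname UnitCell-class
#' @export
setMethod("cellLengths", "UnitCell",
          function(object) c(a = object@a, b = object@b, c = object@c))

#' @rdname UnitCell-class
#' @export
setMethod("cellAngles", "UnitCell",
          function(object) c(alpha = object@alpha, beta = object@beta,
                             gamma = object@gamma))

.asCoordMatrix <- function(xyz) {
  if (is.matrix(xyz)) {
    stopifnot(ncol(xyz) == 3)
    list(m = xyz, vec = FALSE)
  } else {
    stopifnot(length(xyz) == 3)
    list(m = matrix(xyz, nrow = 1), vec = TRUE)
  }
}

#' @rdname orthogonalize
#' @export
setMethod("orthogonalize", "UnitCell", function(object, xyz) {
  cm <- .asCoordMatrix(xyz)
  out <- cm$m %*% t(object@orthMat)
  if (cm$vec) drop(out) else out
})

#' @rdname orthogonalize
#' @export
setMethod("fractionalize", "UnitCell", function(object, xyz) {
  cm <- .asCoordMatrix(xyz)
  out <- cm$m %*% t(object@fracMat)
  if (cm$vec) drop(out) else out
})

#' Reciprocal-lattice vectors and resolution of Miller indices
#'
#' \code{sVectors} returns the Cartesian reciprocal-lattice vector
#' \eqn{\mathbf{s}} (\eqn{\AA^{-1}}) for each Miller index;
#' \code{sLength} returns its magnitude \eqn{s = 1/d}. \eqn{s(0,0,0) = 0}.
#'
#' @param cell a \linkS4class{UnitCell}.
#' @param hkl integer vector of length 3 or an n-by-3 matrix.
#' @return \code{sVectors}: n-by-3 matrix; \code{sLength}: numeric vector.
#' @examples
#' cell <- unitCell(30, 30, 30)
#' sLength(cell, c(3, 0, 0))  # 0.1 = 1/(10 A)
#' @export
sVectors <- function(cell, hkl) {
  cm <- .asCoordMatrix(hkl)
  cm$m %*% cell@fracMat
}

#' @rdname sVectors
#' @export
sLength <- function(cell, hkl) {
  sv <- sVectors(cell, hkl)
  sqrt(rowSums(sv^2))
}

#' Perpendicular cell widths
#'
#' Distance between opposite cell faces along each fractional axis
#' (volume / face area); used to convert Cartesian cutoffs to fractional
#' margins for neighbor searches and symmetry shells.
#'
#' @param cell a \linkS4class{UnitCell}.
#' @return length-3 numeric vector in \eqn{\AA}.
#' @keywords internal
perpWidths <- function(cell) {
  ## width along axis k = 1 / |row k of fracMat| (fracMat rows are the
  ## reciprocal axis vectors a*, b*, c*)
  1 / sqrt(rowSums(cell@fracMat^2))
}

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell: a=%.3f b=%.3f c=%.3f A  alpha=%.2f beta=%.2f gamma=%.2f deg  V=%.1f A^3\n",
              object@a, object@b, object@c, object@alpha, object@beta,
              object@gamma, object@volume))
})
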