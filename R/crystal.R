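## CrystalModel construction, symmetry operators and the symmetry-shell
## expansion that the many-body solvent masks require.

#' Symmetry operator in fractional coordinates
#'
#' @param R 3x3 rotation matrix (fractional basis).
#' @param t length-3 translation vector (fractional).
#' @return a list with elements \code{R} and \code{t}.
#' @examples
#' symOp()                                  # identity
#' symOp(diag(c(-1, -1, 1)), c(0, 0, 0.5))  # two-fold screw along c
#' @export
symOp <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- matrix(as.numeric(R), 3, 3)
  t <- as.numeric(t)
  stopifnot(length(t) == 3, all(is.finite(R)), all(is.finite(t)))
  list(R = R, t = t)
}

#' Construct a CrystalModel
#'
#' Atoms are given in Cartesian \eqn{\AA} and are wrapped into the unit cell
#' (by fractional wrapping) on construction. Missing \code{radius} values
#' are filled from the bundled vdW table; missing \code{occ}/\code{b}
#' default to 1 and 0.
#'
#' @param cell a \linkS4class{UnitCell}.
#' @param atoms data.frame with at least \code{element}, \code{x}, \code{y},
#'   \code{z}; optional \code{occ}, \code{b}, \code{radius}, \code{water}.
#' @param symmetry list of operators from \code{\link{symOp}}; the identity
#'   is prepended if absent. Default: P1 (identity only).
#' @param id free-text identifier.
#' @return a \linkS4class{CrystalModel}.
#' @examples
#' cell <- unitCell(20, 20, 20)
#' mdl <- crystalModel(cell, data.frame(element = "C", x = 5, y = 5, z = 5))
#' atoms(mdl)
#' @export
crystalModel <- function(cell, atoms, symmetry = list(symOp()), id = "model") {
  stopifnot(is(cell, "UnitCell"), is.data.frame(atoms))
  at <- atoms
  if (is.null(at$occ)) at$occ <- rep(1, nrow(at))
  if (is.null(at$b)) at$b <- rep(0, nrow(at))
  if (is.null(at$radius)) at$radius <- vdwRadius(at$element)
  if (is.null(at$water)) at$water <- rep(FALSE, nrow(at))
  at$element <- vapply(as.character(at$element), .normElement, character(1))
  ## wrap into the cell
  fr <- .wrapFrac(fractionalize(cell, as.matrix(at[, c("x", "y", "z")])))
  xyz <- orthogonalize(cell, fr)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  rownames(at) <- NULL
  idop <- symOp()
  if (length(symmetry) == 0 ||
      max(abs(symmetry[[1]]$R - diag(3))) > 1e-9 ||
      max(abs(symmetry[[1]]$t)) > 1e-9)
    symmetry <- c(list(idop), symmetry)
  new("CrystalModel", cell = cell, symmetry = symmetry,
      atoms = at[, c("element", "x", "y", "z", "occ", "b", "radius", "water")],
      id = id)
}

#' @rdname CrystalModel-class
#' @export
setMethod("atoms", "CrystalModel", function(object) object@atoms)

#' @rdname CrystalModel-class
#' @export
setMethod("atoms<-", "CrystalModel", function(object, value) {
  object@atoms <- value
  validObject(object)
  object
})

#' @rdname CrystalModel-class
#' @export
setMethod("modelCell", "CrystalModel", function(object) object@cell)

#' @rdname CrystalModel-class
#' @export
setMethod("symmetryOps", "CrystalModel", function(object) object@symmetry)

setMethod("show", "CrystalModel", function(object) {
  cat(sprintf("CrystalModel '%s': %d atoms, %d symmetry operator(s)\n",
              object@id, nrow(object@atoms), length(object@symmetry)))
  show(object@cell)
  print(head(object@atoms, 5))
  if (nrow(object@atoms) > 5) cat(sprintf("... %d more atoms\n",
                                          nrow(object@atoms) - 5))
})

#' Expand atoms by symmetry into a shell around the unit cell
#'
#' The smooth solvent masks are many-body: the density at a grid point can
#' depend on symmetry- and lattice-related copies of the unique atoms. This
#' returns the unique atom set plus every symmetry/lattice image whose
#' center falls inside the unit-cell box expanded by \code{shell}
#' (per-axis fractional margin \code{shell} / perpendicular cell width).
#' Ordering is deterministic: operator index, then atom index, then lattice
#' translation index.
#'
#' @param model a \linkS4class{CrystalModel}.
#' @param shell shell width in \eqn{\AA} (>= 0); the mask default is 4.0.
#' @return data.frame of atom records plus \code{parent} (unique-atom row),
#'   \code{op} (operator index) and \code{unique} (TRUE for the untouched
#'   unique set).
#' @examples
#' mdl <- crystalModel(unitCell(20, 20, 20),
#'                     data.frame(element = "C", x = 1, y = 10, z = 10))
#' nrow(expandSymmetryShell(mdl, 4))  # unique atom + image across x = 0 face
#' @export
expandSymmetryShell <- function(model, shell = 4.0) {
  stopifnot(shell >= 0)
  cell <- model@cell
  at <- model@atoms
  n <- nrow(at)
  delta <- shell / perpWidths(cell)
  frac <- .wrapFrac(fractionalize(cell, as.matrix(at[, c("x", "y", "z")])))
  shifts <- as.matrix(expand.grid(u1 = -1:1, u2 = -1:1, u3 = -1:1))
  ## deterministic shift ordering with the zero shift first
  shifts <- shifts[order(rowSums(shifts != 0) > 0,
                         shifts[, 1], shifts[, 2], shifts[, 3]), , drop = FALSE]
  nsh <- nrow(shifts)
  out <- vector("list", length(model@symmetry))
  for (io in seq_along(model@symmetry)) {
    op <- model@symmetry[[io]]
    base <- .wrapFrac(frac %*% t(op$R) + rep(op$t, each = n))
    ## candidate order: atom index, then shift index (zero shift first)
    ia <- rep(seq_len(n), each = nsh)
    is <- rep(seq_len(nsh), times = n)
    f <- base[ia, , drop = FALSE] + shifts[is, , drop = FALSE]
    isUnique <- io == 1L & rowSums(shifts[is, , drop = FALSE] != 0) == 0
    inShell <- f[, 1] >= -delta[1] & f[, 1] <= 1 + delta[1] &
               f[, 2] >= -delta[2] & f[, 2] <= 1 + delta[2] &
               f[, 3] >= -delta[3] & f[, 3] <= 1 + delta[3]
    keep <- isUnique | inShell
    xyz <- orthogonalize(cell, f[keep, , drop = FALSE])
    res <- at[ia[keep], , drop = FALSE]
    res$x <- xyz[, 1]; res$y <- xyz[, 2]; res$z <- xyz[, 3]
    res$parent <- ia[keep]; res$op <- io; res$unique <- isUnique[keep]
    out[[io]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
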