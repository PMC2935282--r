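## Density grids over one unit cell and the grid-geometry rules shared by
## all mask models.

#' Choose grid dimensions for a resolution limit
#'
#' The mask grid spacing targets one third of the resolution limit
#' \code{dmin}. When \code{bounded = TRUE} the spacing is clamped to the
#' interval [0.57, 0.9] \eqn{\AA} (fine bound for high-resolution, coarse
#' bound for low-resolution structures). Each dimension is the smallest
#' FFT-friendly integer (prime factors 2, 3, 5, 7) whose spacing along that
#' axis does not exceed the target.
#'
#' @param cell a \linkS4class{UnitCell}.
#' @param dmin resolution limit in \eqn{\AA} (> 0).
#' @param bounded clamp the target spacing to [0.57, 0.9] \eqn{\AA}?
#' @return integer vector (nx, ny, nz).
#' @examples
#' gridDimensions(unitCell(30, 30, 30), 2.0)  # target 2/3 A -> 45 points
#' @export
gridDimensions <- function(cell, dmin, bounded = TRUE) {
  if (!is.numeric(dmin) || dmin <= 0) .stopf("dmin must be positive")
  target <- dmin / 3
  if (bounded) target <- min(max(target, 0.57), 0.9)
  len <- cellLengths(cell)
  vapply(len, function(l) .nextSmooth(l / target), integer(1))
}

#' Construct a DensityGrid
#'
#' @param cell a \linkS4class{UnitCell}.
#' @param dim integer vector (nx, ny, nz), or values array supplied via
#'   \code{values}.
#' @param values optional 3D array; defaults to zeros of dimension
#'   \code{dim}.
#' @return a \linkS4class{DensityGrid}.
#' @examples
#' g <- densityGrid(unitCell(20, 20, 20), c(24, 24, 24))
#' gridSpacing(g)
#' @export
densityGrid <- function(cell, dim = NULL, values = NULL) {
  if (is.null(values)) {
    stopifnot(length(dim) == 3)
    values <- array(0, dim = as.integer(dim))
  }
  new("DensityGrid", values = values, cell = cell)
}

#' @rdname DensityGrid-class
#' @export
setMethod("gridValues", "DensityGrid", function(object) object@values)

#' @rdname DensityGrid-class
#' @export
setMethod("gridDim", "DensityGrid", function(object) dim(object@values))

#' @rdname DensityGrid-class
#' @export
setMethod("gridSpacing", "DensityGrid",
          function(object) unname(cellLengths(object@cell) / dim(object@values)))

#' @rdname DensityGrid-class
#' @export
setMethod("modelCell", "DensityGrid", function(object) object@cell)

setMethod("show", "DensityGrid", function(object) {
  d <- dim(object@values)
  sp <- gridSpacing(object)
  cat(sprintf("DensityGrid %d x %d x %d (spacing %.3f %.3f %.3f A), range [%.4g, %.4g]\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3],
              min(object@values), max(object@values)))
})

## Core spatial query: all grid points within `cutoff` (Cartesian A, minimum
## image) of a Cartesian center. Returns 1-based array indices, the
## Cartesian offset vectors (grid point - center) and distances. The
## enumeration walks a fractional index box around the center, so the cost
## scales with the cutoff volume, not the grid size.
.gridNeighborhood <- function(grid, center, cutoff) {
  cell <- grid@cell
  n <- dim(grid@values)
  pw <- perpWidths(cell)
  if (cutoff > min(pw) / 2)
    .stopf("cutoff %.2f A exceeds half the smallest cell width (%.2f A): minimum-image neighborhoods are ambiguous",
           cutoff, min(pw))
  fc <- drop(fractionalize(cell, center))
  df <- cutoff / pw
  lo <- floor((fc - df) * n)
  hi <- ceiling((fc + df) * n)
  hi <- pmin(hi, lo + n - 1L)  # never span more than one full period
  idx1 <- lo[1]:hi[1]; idx2 <- lo[2]:hi[2]; idx3 <- lo[3]:hi[3]
  box <- as.matrix(expand.grid(i = idx1, j = idx2, k = idx3))
  fr <- sweep(box, 2, n, "/")
  d <- .wrapHalf(sweep(fr, 2, fc, "-"))
  dv <- d %*% t(cell@orthMat)
  r <- sqrt(rowSums(dv^2))
  keep <- r <= cutoff
  idx <- box[keep, , drop = FALSE] %% rep(n, each = sum(keep))
  list(idx = idx + 1L, dvec = dv[keep, , drop = FALSE], r = r[keep])
}

#' Grid points within a cutoff of a point
#'
#' All grid points within \code{cutoff} \eqn{\AA} of a Cartesian center
#' under minimum-image periodicity. Returned indices are 1-based array
#' indices into the grid (the grid's fractional offsets are 0-based).
#'
#' @param grid a \linkS4class{DensityGrid}.
#' @param center Cartesian coordinates (length 3, \eqn{\AA}).
#' @param cutoff radius in \eqn{\AA} (> 0); must not exceed half the
#'   smallest perpendicular cell width.
#' @return integer matrix (n-by-3) of array indices; attribute
#'   \code{"distance"} carries the distances.
#' @examples
#' g <- densityGrid(unitCell(10, 10, 10), c(10, 10, 10))
#' nrow(neighborGridPoints(g, c(5, 5, 5), 1.05))  # center node + 6 axial
#' @export
neighborGridPoints <- function(grid, center, cutoff) {
  if (cutoff <= 0) .stopf("cutoff must be positive")
  nb <- .gridNeighborhood(grid, center, cutoff)
  structure(nb$idx, distance = nb$r)
}

## Convert an n-by-3 1-based index matrix to linear array indices.
.linearIndex <- function(idx, n) {
  (idx[, 1] - 1L) + n[1] * ((idx[, 2] - 1L) + n[2] * (idx[, 3] - 1L)) + 1L
}

## Cartesian coordinates of every grid point (nx*ny*nz rows, x fastest —
## matching R array linear order).
.gridCoords <- function(grid) {
  n <- dim(grid@values)
  fr <- cbind(rep((0:(n[1] - 1)) / n[1], times = n[2] * n[3]),
              rep(rep((0:(n[2] - 1)) / n[2], each = n[1]), times = n[3]),
              rep((0:(n[3] - 1)) / n[3], each = n[1] * n[2]))
  fr %*% t(grid@cell@orthMat)
}
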