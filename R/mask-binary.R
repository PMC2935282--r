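## Binary probe/shrink solvent mask (the classical reference model).
##
## Pass 1 marks as solute every grid point within (vdW radius + probe) of
## any atom — the solvent-accessible surface. Pass 2 "shrinks": every
## solute point within the shrink radius of a solvent point is reassigned
## to solvent, pulling the surface back toward the molecular surface while
## keeping small interior cavities excluded. The result is indicator-valued
## and therefore not differentiable with respect to atomic coordinates.

#' Binary mask parameters
#'
#' @param probe probe radius in \eqn{\AA} (default 1.0).
#' @param shrink shrink radius in \eqn{\AA} (default 1.0).
#' @return parameter list used by \code{\link{binaryMasks}}.
#' @export
binaryMaskParams <- function(probe = 1.0, shrink = 1.0) {
  if (probe < 0 || shrink < 0) .stopf("probe and shrink radii must be >= 0")
  list(model = "binary", probe = probe, shrink = shrink)
}

## Periodic integer offsets (rows) of grid nodes within `radius` of a node,
## as index deltas, excluding the zero offset.
.sphereOffsets <- function(grid, radius) {
  n <- dim(grid@values)
  pw <- perpWidths(grid@cell)
  m <- ceiling(radius / (pw / n))
  box <- as.matrix(expand.grid(i = -m[1]:m[1], j = -m[2]:m[2], k = -m[3]:m[3]))
  dv <- sweep(box, 2, n, "/") %*% t(grid@cell@orthMat)
  r <- sqrt(rowSums(dv^2))
  box[r <= radius & r > 0, , drop = FALSE]
}

.shift3d <- function(arr, by) {
  n <- dim(arr)
  ix <- ((seq_len(n[1]) - 1 - by[1]) %% n[1]) + 1
  iy <- ((seq_len(n[2]) - 1 - by[2]) %% n[2]) + 1
  iz <- ((seq_len(n[3]) - 1 - by[3]) %% n[3]) + 1
  arr[ix, iy, iz, drop = FALSE]
}

#' Build the binary probe/shrink mask pair
#'
#' @inheritParams gaussianMasks
#' @param params from \code{\link{binaryMaskParams}}.
#' @return a \linkS4class{MaskPair} with values in {0, 1}.
#' @examples
#' mdl <- toyCrystal(toySpec(nAtoms = 5, seed = 1))
#' mask <- binaryMasks(mdl, dmin = 2.5)
#' unique(as.vector(gridValues(soluteMask(mask))))
#' @export
binaryMasks <- function(model, grid = NULL, params = binaryMaskParams(),
                        dmin = 2.0, expanded = NULL) {
  if (is.null(grid))
    grid <- densityGrid(model@cell, gridDimensions(model@cell, dmin))
  if (is.null(expanded)) expanded <- expandSymmetryShell(model, 0)
  n <- dim(grid@values)
  solute <- array(FALSE, dim = n)
  for (ia in seq_len(nrow(expanded))) {
    nb <- .gridNeighborhood(grid, c(expanded$x[ia], expanded$y[ia],
                                    expanded$z[ia]),
                            expanded$radius[ia] + params$probe)
    if (nrow(nb$idx) > 0) solute[.linearIndex(nb$idx, n)] <- TRUE
  }
  if (params$shrink > 0 && any(solute) && any(!solute)) {
    ## dilate the solvent region by the shrink radius: any solute point
    ## within `shrink` of a solvent point flips back to solvent
    solventRegion <- !solute
    dilated <- solventRegion
    offs <- .sphereOffsets(grid, params$shrink)
    for (k in seq_len(nrow(offs)))
      dilated <- dilated | .shift3d(solventRegion, offs[k, ])
    solute <- solute & !dilated
  }
  vals <- array(as.numeric(solute), dim = n)
  new("MaskPair",
      solute = densityGrid(grid@cell, values = vals),
      solvent = densityGrid(grid@cell, values = 1 - vals),
      model = "binary", params = params, sigmas = numeric())
}
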