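## Generics for accessors shared across classes.

#' @rdname UnitCell-class
#' @param object,x an object.
#' @export
setGeneric("cellVolume", function(object) standardGeneric("cellVolume"))

#' @rdname UnitCell-class
#' @export
setGeneric("cellLengths", function(object) standardGeneric("cellLengths"))

#' @rdname UnitCell-class
#' @export
setGeneric("cellAngles", function(object) standardGeneric("cellAngles"))

#' Fractional <-> Cartesian coordinate transforms
#'
#' \code{orthogonalize} maps fractional coordinates to Cartesian \eqn{\AA};
#' \code{fractionalize} is its inverse. Both accept a length-3 vector or an
#' n-by-3 matrix and return the same shape. The round trip
#' \code{fractionalize(orthogonalize(x))} reproduces \code{x} to numerical
#' precision.
#'
#' @param object a \linkS4class{UnitCell}.
#' @param xyz length-3 vector or n-by-3 matrix of coordinates.
#' @return coordinates with the same shape as \code{xyz}.
#' @export
setGeneric("orthogonalize", function(object, xyz) standardGeneric("orthogonalize"))

#' @rdname orthogonalize
#' @export
setGeneric("fractionalize", function(object, xyz) standardGeneric("fractionalize"))

#' @rdname CrystalModel-class
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))

#' @rdname CrystalModel-class
#' @param value replacement value.
#' @export
setGeneric("atoms<-", function(object, value) standardGeneric("atoms<-"))

#' @rdname CrystalModel-class
#' @export
setGeneric("modelCell", function(object) standardGeneric("modelCell"))

#' @rdname CrystalModel-class
#' @export
setGeneric("symmetryOps", function(object) standardGeneric("symmetryOps"))

#' @rdname DensityGrid-class
#' @export
setGeneric("gridValues", function(object) standardGeneric("gridValues"))

#' @rdname DensityGrid-class
#' @export
setGeneric("gridDim", function(object) standardGeneric("gridDim"))

#' @rdname DensityGrid-class
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))

#' @rdname MaskPair-class
#' @export
setGeneric("soluteMask", function(object) standardGeneric("soluteMask"))

#' @rdname MaskPair-class
#' @export
setGeneric("solventMask", function(object) standardGeneric("solventMask"))

#' @rdname ReflectionSet-class
#' @export
setGeneric("millerIndices", function(object) standardGeneric("millerIndices"))

#' @rdname ReflectionSet-class
#' @export
setGeneric("sValues", function(object) standardGeneric("sValues"))

#' @rdname ReflectionSet-class
#' @export
setGeneric("freeFlags", function(object) standardGeneric("freeFlags"))
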