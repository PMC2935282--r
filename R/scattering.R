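## Structure-factor engine: atomic F_c by direct summation, mask F_m by
## FFT, solvent scaling k_s exp(-B_s s^2/4) and the Babinet combination
## F_t = F_c - k_s exp(-B_s s^2/4) F_m. The mask here is the SOLUTE mask
## (one inside the protein, zero in bulk); subtracting its scaled transform
## is equivalent, at every non-origin reflection, to adding the transform
## of the solvent-region mask, because the Fourier transform of a constant
## scattering volume vanishes away from the origin.

#' Construct a ReflectionSet
#'
#' @param cell a \linkS4class{UnitCell}.
#' @param hkl integer n-by-3 matrix of Miller indices (no (0,0,0) row).
#' @param dmin resolution limit; defaults to min d over the list.
#' @param fobs,sigobs,free optional observation columns.
#' @return a \linkS4class{ReflectionSet}.
#' @export
reflectionSet <- function(cell, hkl, dmin = NULL, fobs = numeric(),
                          sigobs = numeric(), free = logical()) {
  hkl <- matrix(as.integer(round(hkl)), ncol = 3)
  s <- sLength(cell, hkl)
  if (is.null(dmin)) dmin <- 1 / max(s)
  new("ReflectionSet", hkl = hkl, s = s, fc = complex(), fm = complex(),
      ft = complex(), fobs = fobs, sigobs = sigobs, free = free,
      dmin = dmin, cell = cell)
}

#' Enumerate reflections to a resolution limit
#'
#' All Friedel-unique Miller indices with \eqn{s = 1/d \le 1/d_{min}},
#' excluding F(000), sorted by resolution. The Friedel-unique half is
#' h > 0, or h = 0 and k > 0, or h = k = 0 and l > 0.
#'
#' @param cell a \linkS4class{UnitCell}.
#' @param dmin resolution limit in \eqn{\AA}.
#' @return a \linkS4class{ReflectionSet}.
#' @examples
#' refl <- makeReflectionSet(unitCell(20, 20, 20), 3.0)
#' nrow(millerIndices(refl))
#' @export
makeReflectionSet <- function(cell, dmin) {
  if (dmin <= 0) .stopf("dmin must be positive")
  lim <- ceiling(cellLengths(cell) / dmin) + 1L
  hkl <- as.matrix(expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2],
                               l = -lim[3]:lim[3]))
  uniq <- hkl[, 1] > 0 | (hkl[, 1] == 0 & hkl[, 2] > 0) |
    (hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] > 0)
  hkl <- hkl[uniq, , drop = FALSE]
  s <- sLength(cell, hkl)
  keep <- s <= 1 / dmin
  hkl <- hkl[keep, , drop = FALSE]
  s <- s[keep]
  o <- order(s, hkl[, 1], hkl[, 2], hkl[, 3])
  reflectionSet(cell, hkl[o, , drop = FALSE], dmin = dmin)
}

#' @rdname ReflectionSet-class
#' @param object a ReflectionSet.
#' @export
setMethod("millerIndices", "ReflectionSet", function(object) object@hkl)

#' @rdname ReflectionSet-class
#' @export
setMethod("sValues", "ReflectionSet", function(object) object@s)

#' @rdname ReflectionSet-class
#' @export
setMethod("freeFlags", "ReflectionSet", function(object) object@free)

#' @rdname ReflectionSet-class
#' @export
setMethod("modelCell", "ReflectionSet", function(object) object@cell)

#' @rdname ReflectionSet-class
#' @export
setMethod("length", "ReflectionSet", function(x) nrow(x@hkl))

setMethod("show", "ReflectionSet", function(object) {
  cat(sprintf("ReflectionSet: %d reflections to %.2f A (s up to %.3f 1/A)\n",
              nrow(object@hkl), object@dmin, max(object@s)))
  filled <- c("fc", "fm", "ft", "fobs", "sigobs", "free")
  filled <- filled[vapply(filled, function(sl) length(slot(object, sl)) > 0,
                          logical(1))]
  if (length(filled)) cat("  filled:", paste(filled, collapse = ", "), "\n")
})

#' Solvent-parameter pair (k_s, B_s)
#'
#' @param ks bulk-solvent electron density in e \eqn{\AA^{-3}} (>= 0);
#'   the standard starting value 0.33 is the electron density of bulk
#'   water near 267 K.
#' @param bs solvent smearing B factor in \eqn{\AA^2} (>= 0); standard
#'   start 50.
#' @return parameter list.
#' @export
solventScaleParams <- function(ks = 0.33, bs = 50.0) {
  if (ks < 0 || bs < 0) .stopf("k_s and B_s must be non-negative")
  list(ks = ks, bs = bs)
}

#' Solvent attenuation factor
#'
#' \eqn{k_s \exp(-B_s s^2 / 4)}: the reciprocal-space multiplier applied to
#' the mask structure factors. The exponential smears the solvent model in
#' real space; it is monotone decreasing in \eqn{s} for \eqn{B_s > 0}.
#'
#' @param s reciprocal coordinates \eqn{1/d} (\eqn{\AA^{-1}}).
#' @param params from \code{\link{solventScaleParams}}.
#' @return numeric attenuation factors.
#' @examples
#' solventScale(0, solventScaleParams(0.33, 50))    # k_s
#' solventScale(1/6, solventScaleParams(0.33, 50))  # 0.33*exp(-50/144)
#' @export
solventScale <- function(s, params) {
  if (any(s < 0)) .stopf("s must be non-negative")
  params$ks * exp(-params$bs * s^2 / 4)
}

#' Atomic structure factors by direct summation
#'
#' \eqn{F_c(h) = \sum_{ops} \sum_i occ_i f_i(s) e^{-B_i s^2/4}
#' e^{2\pi i h \cdot x_i}} over all symmetry copies of the atoms, with
#' \eqn{x_i} fractional.
#'
#' @param model a \linkS4class{CrystalModel}.
#' @param refl a \linkS4class{ReflectionSet}.
#' @return complex vector of \eqn{F_c}, one per reflection.
#' @examples
#' mdl <- crystalModel(unitCell(10, 10, 10),
#'                     data.frame(element = "C", x = 0, y = 0, z = 0))
#' refl <- makeReflectionSet(unitCell(10, 10, 10), 5)
#' Re(atomicStructureFactors(mdl, refl))  # f_C(s): real, origin atom
#' @export
atomicStructureFactors <- function(model, refl) {
  at <- model@atoms
  s <- refl@s
  damp <- outer(-s^2 / 4, at$b)  # nrefl x natoms
  fmat <- matrix(0, length(s), nrow(at))
  for (el in unique(at$element)) {
    sel <- at$element == el
    fmat[, sel] <- formFactor(el, s)
  }
  coef <- exp(damp) * fmat * rep(at$occ, each = length(s))
  frac <- fractionalize(model@cell, as.matrix(at[, c("x", "y", "z")]))
  fc <- complex(real = rep(0, length(s)), imaginary = 0)
  for (op in model@symmetry) {
    pos <- frac %*% t(op$R) + rep(op$t, each = nrow(frac))
    phase <- 2 * pi * (refl@hkl %*% t(pos))
    fc <- fc + rowSums(coef * exp(1i * phase))
  }
  fc
}

#' Mask structure factors by FFT
#'
#' Forward transform of the solute mask sampled on its grid, in the
#' electron-count convention \eqn{F_m(h) = (V/N) \sum_g \chi_g
#' e^{2\pi i h \cdot x_g}}. F(000) is not part of any reflection set and is
#' dropped by construction.
#'
#' @param mask a \linkS4class{MaskPair} (its solute grid is transformed) or
#'   a \linkS4class{DensityGrid}.
#' @param refl a \linkS4class{ReflectionSet}; every index must satisfy
#'   \eqn{|h_k| < n_k / 2} on the mask grid.
#' @return complex vector of \eqn{F_m}, one per reflection.
#' @export
maskStructureFactors <- function(mask, refl) {
  grid <- if (is(mask, "MaskPair")) mask@solute else mask
  n <- dim(grid@values)
  hkl <- refl@hkl
  if (any(abs(hkl) >= rep(n, each = nrow(hkl)) / 2))
    .stopf("mask grid (%s) too coarse for the reflection list: need |h_k| < n_k/2",
           paste(n, collapse = " x "))
  ## positive-exponent DFT (unnormalized inverse FFT)
  X <- fft(grid@values, inverse = TRUE)
  idx <- hkl %% rep(n, each = nrow(hkl)) + 1L
  vol <- cellVolume(grid@cell)
  (vol / prod(n)) * X[.linearIndex(idx, n)]
}

#' Total structure factors via Babinet's principle
#'
#' \eqn{F_t(h) = F_c(h) - k_s e^{-B_s s^2/4} F_m(h)}. With \eqn{k_s = 0}
#' this reduces to \eqn{F_c} exactly.
#'
#' @param fc,fm complex vectors on the same reflection list.
#' @param s reciprocal coordinates \eqn{1/d} for the list.
#' @param params from \code{\link{solventScaleParams}}.
#' @return complex vector of \eqn{F_t}.
#' @export
totalStructureFactors <- function(fc, fm, s, params) {
  if (length(fc) != length(fm) || length(fc) != length(s))
    .stopf("fc, fm and s must be on the same reflection list")
  fc - solventScale(s, params) * fm
}

#' Anisotropic overall scale parameters
#'
#' @param k0 overall scale factor.
#' @param B symmetric 3x3 anisotropic B tensor (\eqn{\AA^2}), applied in
#'   the Cartesian reciprocal metric; a tensor proportional to the identity
#'   reduces to the isotropic Debye-Waller factor.
#' @return parameter list.
#' @export
anisoScaleParams <- function(k0 = 1, B = matrix(0, 3, 3)) {
  B <- matrix(as.numeric(B), 3, 3)
  if (max(abs(B - t(B))) > 1e-9) .stopf("aniso B tensor must be symmetric")
  list(k0 = k0, B = (B + t(B)) / 2)
}

#' Apply the anisotropic overall scale to model amplitudes
#'
#' \eqn{|F_{model}|(h) = k_0 \exp(-\tfrac14 \mathbf{s}^T B \mathbf{s})
#' |F_t|(h)} with \eqn{\mathbf{s}} the Cartesian reciprocal-lattice vector
#' of each reflection.
#'
#' @param amplitudes numeric \eqn{|F_t|} values.
#' @param refl the \linkS4class{ReflectionSet} supplying cell and indices.
#' @param params from \code{\link{anisoScaleParams}}.
#' @return scaled amplitudes.
#' @export
applyAnisoScale <- function(amplitudes, refl, params) {
  sv <- sVectors(refl@cell, refl@hkl)
  q <- rowSums((sv %*% params$B) * sv)
  params$k0 * exp(-q / 4) * amplitudes
}

#' Fill the structure-factor slots of a ReflectionSet
#'
#' Computes \eqn{F_c} (direct summation), \eqn{F_m} (mask FFT) and
#' \eqn{F_t} (Babinet combination) for a crystal and mask model in one
#' call, returning the updated set.
#'
#' @param refl a \linkS4class{ReflectionSet}.
#' @param model a \linkS4class{CrystalModel}.
#' @param mask a \linkS4class{MaskPair}, or NULL for no solvent.
#' @param params solvent scale parameters.
#' @return the \linkS4class{ReflectionSet} with \code{fc}, \code{fm},
#'   \code{ft} filled.
#' @export
computeStructureFactors <- function(refl, model, mask = NULL,
                                    params = solventScaleParams()) {
  refl@fc <- atomicStructureFactors(model, refl)
  if (is.null(mask)) {
    refl@fm <- complex(length(refl@fc))
    refl@ft <- refl@fc
  } else {
    refl@fm <- maskStructureFactors(mask, refl)
    refl@ft <- totalStructureFactors(refl@fc, refl@fm, refl@s, params)
  }
  refl
}
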