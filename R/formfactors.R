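## X-ray scattering factors (International Tables 4-Gaussian + constant
## parameterization) and van der Waals radii for the elements a toy
## macromolecular structure is likely to contain.
##
## f(s) = sum_j a_j exp(-b_j (s/2)^2) + c   with s = 1/d.

.it92 <- list(
  H  = list(a = c(0.493002, 0.322912, 0.140191, 0.04081),
            b = c(10.5109, 26.1257, 3.14236, 57.7997),  c = 0.003038),
  C  = list(a = c(2.31, 1.02, 1.5886, 0.865),
            b = c(20.8439, 10.2075, 0.5687, 51.6512),   c = 0.2156),
  N  = list(a = c(12.2126, 3.1322, 2.0125, 1.1663),
            b = c(0.0057, 9.8933, 28.9975, 0.5826),     c = -11.529),
  O  = list(a = c(3.0485, 2.2868, 1.5463, 0.867),
            b = c(13.2771, 5.7011, 0.3239, 32.9089),    c = 0.2508),
  P  = list(a = c(6.4345, 4.1791, 1.78, 1.4908),
            b = c(1.9067, 27.157, 0.526, 68.1645),      c = 1.1149),
  S  = list(a = c(6.9053, 5.2034, 1.4379, 1.5863),
            b = c(1.4679, 22.2151, 0.2536, 56.172),     c = 0.8669),
  F  = list(a = c(3.5392, 2.6412, 1.517, 1.0243),
            b = c(10.2825, 4.2944, 0.2615, 26.1476),    c = 0.2776),
  Cl = list(a = c(11.4604, 7.1964, 6.2556, 1.6455),
            b = c(0.0104, 1.1662, 18.5194, 47.7784),    c = -9.5574),
  Br = list(a = c(17.1789, 5.2358, 5.6377, 3.9851),
            b = c(2.1723, 16.5796, 0.2609, 41.4328),    c = 2.9557),
  I  = list(a = c(20.1472, 18.9949, 7.5138, 2.2735),
            b = c(4.347, 0.3814, 27.766, 66.8776),      c = 4.0712),
  Na = list(a = c(4.7626, 3.1736, 1.2674, 1.1128),
            b = c(3.285, 8.8422, 0.3136, 129.424),      c = 0.676),
  Mg = list(a = c(5.4204, 2.1735, 1.2269, 2.3073),
            b = c(2.8275, 79.2611, 0.3808, 7.1937),     c = 0.8584),
  K  = list(a = c(8.2186, 7.4398, 1.0519, 0.8659),
            b = c(12.7949, 0.7748, 213.187, 41.6841),   c = 1.4228),
  Ca = list(a = c(8.6266, 7.3873, 1.5899, 1.0211),
            b = c(10.4421, 0.6599, 85.7484, 178.437),   c = 1.3751),
  Mn = list(a = c(11.2819, 7.3573, 3.0193, 2.2441),
            b = c(5.3409, 0.3432, 17.8674, 83.7543),    c = 1.0896),
  Fe = list(a = c(11.7695, 7.3573, 3.5222, 2.3045),
            b = c(4.7611, 0.3072, 15.3535, 76.8805),    c = 1.0369),
  Zn = list(a = c(14.0743, 7.0318, 5.1652, 2.41),
            b = c(3.2655, 0.2333, 10.3163, 58.7097),    c = 1.3041),
  Se = list(a = c(17.0006, 5.8196, 3.9731, 4.3543),
            b = c(2.4098, 0.2726, 15.2372, 43.8163),    c = 2.8409))

## Bondi-style van der Waals radii (A), with common crystallographic values
## for metals. Per-atom overrides are always possible through the atom table.
.vdwRadii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
               F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, Na = 2.27,
               Mg = 1.73, K = 2.75, Ca = 2.31, Mn = 2.05, Fe = 2.05,
               Zn = 1.39, Se = 1.90)

.normElement <- function(element) {
  e <- paste0(toupper(substr(element, 1, 1)),
              tolower(substr(element, 2, 2)))
  sub(" ", "", e)
}

#' Atomic scattering factor
#'
#' Evaluates the 4-Gaussian-plus-constant X-ray form factor \eqn{f(s)} for
#' an element at reciprocal coordinates \eqn{s = 1/d}.
#'
#' @param element element symbol (case-insensitive).
#' @param s numeric vector of \eqn{1/d} values in \eqn{\AA^{-1}}.
#' @return numeric vector of electron-count form factors.
#' @examples
#' formFactor("C", 0)      # ~6 electrons
#' formFactor("O", 0.25)
#' @export
formFactor <- function(element, s) {
  el <- .normElement(element)
  cf <- .it92[[el]]
  if (is.null(cf)) .stopf("no form-factor coefficients for element '%s'", element)
  st2 <- (s / 2)^2
  out <- rep(cf$c, length(s))
  for (j in 1:4) out <- out + cf$a[j] * exp(-cf$b[j] * st2)
  out
}

#' Van der Waals radius lookup
#'
#' @param element element symbol or vector of symbols.
#' @return numeric vector of vdW radii in \eqn{\AA}.
#' @examples
#' vdwRadius(c("C", "O"))
#' @export
vdwRadius <- function(element) {
  el <- vapply(element, .normElement, character(1))
  r <- .vdwRadii[el]
  if (any(is.na(r)))
    .stopf("no vdW radius for element(s): %s",
           paste(unique(el[is.na(r)]), collapse = ", "))
  unname(r)
}

#' @rdname formFactor
#' @export
knownElements <- function() names(.it92)
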