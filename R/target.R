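## Least-squares refinement target on amplitudes, R statistics and phase
## differences. The overall scale k is refit in closed form at every
## evaluation; by the envelope theorem its refit does not perturb the
## analytic derivatives with respect to anything else.

#' Least-squares amplitude target
#'
#' \eqn{T = \sum_{work} w(h) (|F_{obs}| - k |F_{model}|)^2} with unit
#' weights by default and the overall scale \eqn{k} refit in closed form
#' (\code{refitScale = FALSE} fixes \eqn{k = 1}). Free-flagged reflections
#' are excluded from the sum and get a zero derivative.
#'
#' @param fobs,fmodel observed and model amplitudes (matched vectors).
#' @param weights per-reflection weights (default 1).
#' @param free logical free-R flags (default none).
#' @param refitScale refit the overall scale k?
#' @return list with \code{value}, \code{scale} (k), and
#'   \code{dTdFmodel} (analytic per-reflection derivative
#'   \eqn{\partial T/\partial |F_{model}|}, zero on the free set).
#' @examples
#' leastSquaresTarget(c(10, 12), c(10, 12))$value        # 0
#' leastSquaresTarget(4, 2, refitScale = FALSE)          # T = 4, dT = -4
#' @export
leastSquaresTarget <- function(fobs, fmodel, weights = NULL, free = NULL,
                               refitScale = TRUE) {
  n <- length(fobs)
  stopifnot(length(fmodel) == n)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(free)) free <- rep(FALSE, n)
  work <- !free
  if (!any(work)) .stopf("empty work set")
  k <- if (refitScale) {
    denom <- sum(weights[work] * fmodel[work]^2)
    if (denom == 0) 1 else sum(weights[work] * fobs[work] * fmodel[work]) / denom
  } else 1
  resid <- fobs - k * fmodel
  value <- sum(weights[work] * resid[work]^2)
  d <- -2 * weights * k * resid
  d[free] <- 0
  list(value = value, scale = k, dTdFmodel = d)
}

#' R factor and free R factor
#'
#' \eqn{R = 100 \sum ||F_{obs}| - k |F_{model}|| / \sum |F_{obs}|} over the
#' work set, with \eqn{k} the least-squares overall scale fit on the work
#' set; the same formula and the same \eqn{k} are applied to the free set
#' for \eqn{R_{free}}.
#'
#' @param fobs,fmodel amplitude vectors.
#' @param free logical free flags (default: all work).
#' @return list with \code{R}, \code{Rfree} (NA when the free set is
#'   empty) and \code{scale}.
#' @examples
#' rFactors(c(10, 10), 2 * c(10, 10))$R  # 0: the scale absorbs proportionality
#' @export
rFactors <- function(fobs, fmodel, free = NULL) {
  n <- length(fobs)
  if (is.null(free)) free <- rep(FALSE, n)
  work <- !free
  if (!any(work)) .stopf("at least one work reflection is required")
  denom <- sum(fmodel[work]^2)
  k <- if (denom == 0) 1 else sum(fobs[work] * fmodel[work]) / denom
  R <- 100 * sum(abs(fobs[work] - k * fmodel[work])) / sum(fobs[work])
  Rfree <- if (any(free))
    100 * sum(abs(fobs[free] - k * fmodel[free])) / sum(fobs[free])
  else NA_real_
  list(R = R, Rfree = Rfree, scale = k)
}

#' Binned R factors across resolution
#'
#' Splits reflections into resolution bins (equal reflection counts) and
#' reports R and R_free per bin using a single overall scale fit on the
#' full work set.
#'
#' @param refl a \linkS4class{ReflectionSet} with \code{fobs} filled.
#' @param fmodel model amplitudes matching the set.
#' @param nbins number of bins.
#' @return data.frame with columns \code{bin}, \code{sMin}, \code{sMax},
#'   \code{s2mid}, \code{n}, \code{R}, \code{Rfree}.
#' @export
binnedRFactors <- function(refl, fmodel, nbins = 10) {
  fobs <- refl@fobs
  stopifnot(length(fobs) == length(fmodel))
  free <- if (length(refl@free)) refl@free else rep(FALSE, length(fobs))
  work <- !free
  denom <- sum(fmodel[work]^2)
  k <- if (denom == 0) 1 else sum(fobs[work] * fmodel[work]) / denom
  qs <- stats::quantile(refl@s, probs = seq(0, 1, length.out = nbins + 1))
  qs[1] <- qs[1] - 1e-9; qs[nbins + 1] <- qs[nbins + 1] + 1e-9
  bin <- cut(refl@s, qs, labels = FALSE)
  out <- lapply(seq_len(nbins), function(b) {
    i <- bin == b
    iw <- i & work; ifr <- i & free
    data.frame(
      bin = b, sMin = min(refl@s[i]), sMax = max(refl@s[i]),
      s2mid = mean(refl@s[i]^2), n = sum(i),
      R = if (any(iw))
        100 * sum(abs(fobs[iw] - k * fmodel[iw])) / sum(fobs[iw]) else NA_real_,
      Rfree = if (any(ifr))
        100 * sum(abs(fobs[ifr] - k * fmodel[ifr])) / sum(fobs[ifr]) else NA_real_)
  })
  do.call(rbind, out)
}

#' Mean absolute phase difference
#'
#' Circular absolute difference per reflection mapped to [0, 180] degrees,
#' averaged (optionally weighted, e.g. by amplitude).
#'
#' @param phiModel,phiRef phase vectors in degrees.
#' @param weights optional weights.
#' @return mean absolute phase difference in degrees.
#' @examples
#' phaseDifference(359, 1)  # 2, not 358
#' @export
phaseDifference <- function(phiModel, phiRef, weights = NULL) {
  stopifnot(length(phiModel) == length(phiRef))
  d <- abs(((phiModel - phiRef + 180) %% 360) - 180)
  if (is.null(weights)) mean(d) else sum(weights * d) / sum(weights)
}
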