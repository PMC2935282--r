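## Solvent-parameter optimization: bounded quasi-Newton (L-BFGS-B) over
## (k_s, B_s) with analytic derivatives, from the standard start
## (0.33 e/A^3, 50 A^2), converged when the rms gradient magnitude drops
## below 1e-5. An optional coarse grid search over k_s in [0, 0.6] and
## B_s in [0, 300] can precede the minimization (the combined strategy
## used by CNS-style refinement).

## T and dT/d(ks, bs) for fixed fc, fm. The overall scale refit inside the
## target is envelope-consistent with the analytic parameter derivatives.
.solventObjective <- function(par, fc, fm, s, fobs, weights, free,
                              refitScale = TRUE) {
  prm <- list(ks = par[1], bs = par[2])
  att <- solventScale(s, prm)
  ft <- fc - att * fm
  amp <- Mod(ft)
  lst <- leastSquaresTarget(fobs, amp, weights, free, refitScale = refitScale)
  ## d|ft|/dp = Re(conj(ft)/|ft| * dft/dp)
  u <- ifelse(amp > 0, 1 / amp, 0)
  dftdks <- -exp(-prm$bs * s^2 / 4) * fm
  dftdbs <- (prm$ks * s^2 / 4) * exp(-prm$bs * s^2 / 4) * fm
  dAdks <- Re(Conj(ft) * dftdks) * u
  dAdbs <- Re(Conj(ft) * dftdbs) * u
  list(value = lst$value, scale = lst$scale,
       grad = c(sum(lst$dTdFmodel * dAdks), sum(lst$dTdFmodel * dAdbs)))
}

#' Optimize bulk-solvent scale parameters
#'
#' Fits \eqn{(k_s, B_s)} to observed amplitudes by gradient-based
#' minimization of the least-squares target, holding the mask (and hence
#' \eqn{F_c}, \eqn{F_m}) fixed. Uses L-BFGS-B with both parameters bounded
#' below at zero and analytic derivatives; iterates until the rms gradient
#' magnitude is below \code{tol}. The overall scale is refit in closed
#' form at every evaluation.
#'
#' @param refl a \linkS4class{ReflectionSet} with \code{fc}, \code{fm} and
#'   \code{fobs} filled (use \code{\link{computeStructureFactors}} first).
#' @param start starting parameters (default
#'   \code{solventScaleParams(0.33, 50)}).
#' @param weights optional per-reflection weights.
#' @param gridSearch run a coarse (k_s, B_s) grid search over
#'   [0, 0.6] x [0, 300] before the minimization?
#' @param tol rms-gradient convergence threshold (default 1e-5).
#' @param maxRounds L-BFGS-B restarts allowed to reach \code{tol}.
#' @return list with \code{params} (fitted \code{solventScaleParams}),
#'   \code{scale} (overall k), \code{value} (target), \code{rmsGrad},
#'   \code{converged}, and \code{R} (work-set R factor, percent).
#' @export
optimizeSolventParams <- function(refl, start = solventScaleParams(),
                                  weights = NULL, gridSearch = FALSE,
                                  tol = 1e-5, maxRounds = 6) {
  stopifnot(length(refl@fc) > 0, length(refl@fm) > 0, length(refl@fobs) > 0)
  fc <- refl@fc; fm <- refl@fm; s <- refl@s; fobs <- refl@fobs
  free <- if (length(refl@free)) refl@free else rep(FALSE, length(fobs))
  fn <- function(p) .solventObjective(p, fc, fm, s, fobs, weights, free)$value
  gr <- function(p) .solventObjective(p, fc, fm, s, fobs, weights, free)$grad
  p0 <- c(start$ks, start$bs)
  if (gridSearch) {
    cand <- as.matrix(expand.grid(ks = seq(0, 0.6, by = 0.05),
                                  bs = seq(0, 300, by = 25)))
    vals <- apply(cand, 1, fn)
    p0 <- unname(cand[which.min(vals), ])
  }
  p <- p0
  converged <- FALSE
  for (round in seq_len(maxRounds)) {
    fit <- optim(p, fn, gr, method = "L-BFGS-B", lower = c(0, 0),
                 control = list(maxit = 500, factr = 1, pgtol = 0))
    p <- fit$par
    g <- gr(p)
    ## at an active bound the projected gradient is what must vanish
    gp <- ifelse(p <= 0 & g > 0, 0, g)
    if (sqrt(mean(gp^2)) < tol) { converged <- TRUE; break }
  }
  obj <- .solventObjective(p, fc, fm, s, fobs, weights, free)
  amp <- Mod(fc - solventScale(s, list(ks = p[1], bs = p[2])) * fm)
  rf <- rFactors(fobs, amp, if (any(free)) free else NULL)
  list(params = solventScaleParams(p[1], p[2]), scale = obj$scale,
       value = obj$value, rmsGrad = sqrt(mean(ifelse(p <= 0 & obj$grad > 0,
                                                     0, obj$grad)^2)),
       converged = converged, R = rf$R, Rfree = rf$Rfree)
}
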