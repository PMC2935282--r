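## Run configuration: every tunable with its standard default in one
## place. The command-line front end overlays user flags on top of these;
## precedence is CLI > config file > defaults.

#' Default run configuration
#'
#' All model parameters with their standard defaults: Gaussian threshold
#' A = 11.5 and sigma = 0.55 x vdW radius; polynomial window half-width
#' w = 0.8 \eqn{\AA}; binary probe and shrink radii 1.0 \eqn{\AA}; solvent
#' scale start k_s = 0.33 e \eqn{\AA^{-3}} (bulk water) and B_s = 50
#' \eqn{\AA^2}; symmetry shell 4.0 \eqn{\AA}; grid spacing d_min/3 bounded
#' to [0.57, 0.9] \eqn{\AA}.
#'
#' @param ... overrides (name = value) for any listed field.
#' @return named list of settings.
#' @examples
#' defaultConfig(model = "polynomial", w = 1.0)$w
#' @export
defaultConfig <- function(...) {
  cfg <- list(model = "gaussian", A = 11.5, sigmaScale = 0.55,
              supportSigma = 5, w = 0.8, probe = 1.0, shrink = 1.0,
              ks = 0.33, bs = 50.0, shell = 4.0, gridBounded = TRUE,
              dmin = 2.0, seed = 1, verbose = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) .stopf("unknown config field(s): %s",
                          paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Mask parameters from a configuration
#'
#' @param cfg list from \code{\link{defaultConfig}}.
#' @param model mask model (defaults to \code{cfg$model}).
#' @return the model-specific parameter list.
#' @export
configMaskParams <- function(cfg, model = cfg$model) {
  switch(model,
         gaussian = gaussianMaskParams(cfg$A, cfg$sigmaScale,
                                       cfg$supportSigma),
         polynomial = polynomialMaskParams(cfg$w),
         binary = binaryMaskParams(cfg$probe, cfg$shrink),
         none = NULL,
         .stopf("unknown mask model '%s'", model))
}
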