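test_that("double-wide finite difference is exact for quadratics", {
  expect_equal(finiteDifferenceGradient(function(x) x^2, 1, 0.3), 2)
  expect_equal(finiteDifferenceGradient(function(x) x^2, 1, 1e-4), 2)
  expect_error(finiteDifferenceGradient(identity, 0, -1), "positive")
})

test_that("analytic gradients match finite differences for both smooth models", {
  spec <- smallSpec(seed = 3, noise = 0.04)
  mdl <- toyCrystal(spec)
  refl <- syntheticObservations(mdl, spec)
  grid <- densityGrid(modelCell(mdl), gridDimensions(modelCell(mdl), spec$dmin))
  xyz <- as.matrix(atoms(mdl)[, c("x", "y", "z")])
  solv <- solventScaleParams(0.33, 50)
  for (mm in c("gaussian", "polynomial")) {
    gf <- coordinateGradients(mdl, refl, mm, solvParams = solv, grid = grid)
    tf <- solventTargetFunction(mdl, refl, mm, solvParams = solv, grid = grid)
    expect_equal(tf(xyz), gf@target, tolerance = 1e-12)
    relmax <- 0
    for (i in seq_len(nrow(xyz))) for (ax in 1:3) {
      fd <- finiteDifferenceGradient(function(d) {
        x <- xyz; x[i, ax] <- x[i, ax] + d; tf(x)
      }, 0, 1e-4)
      relmax <- max(relmax, abs(gf@total[i, ax] - fd) /
                              (abs(gf@total[i, ax]) + 1e-12))
    }
    expect_lt(relmax, 1e-4)
    ## decomposition is consistent
    expect_equal(gf@total, gf@atomic + gf@solvent, tolerance = 1e-12)
  }
})

test_that("omitting the solvent chain term breaks finite-difference agreement", {
  spec <- smallSpec(seed = 3, noise = 0.04)
  mdl <- toyCrystal(spec)
  refl <- syntheticObservations(mdl, spec)
  grid <- densityGrid(modelCell(mdl), gridDimensions(modelCell(mdl), spec$dmin))
  solv <- solventScaleParams(0.33, 50)
  gfAb <- coordinateGradients(mdl, refl, "gaussian", solvParams = solv,
                              grid = grid, includeSolventTerm = FALSE)
  tf <- solventTargetFunction(mdl, refl, "gaussian", solvParams = solv,
                              grid = grid)
  xyz <- as.matrix(atoms(mdl)[, c("x", "y", "z")])
  w <- which(atoms(mdl)$water)
  fd <- finiteDifferenceGradient(function(d) {
    x <- xyz; x[w, 1] <- x[w, 1] + d; tf(x)
  }, 0, 1e-4)
  relAb <- abs(gfAb@total[w, 1] - fd) / (abs(gfAb@total[w, 1]) + 1e-12)
  expect_gt(relAb, 1e-3)  # systematic mismatch without the mask derivatives
})

test_that("the binary model refuses coordinate gradients", {
  spec <- smallSpec(seed = 3)
  mdl <- toyCrystal(spec)
  refl <- syntheticObservations(mdl, spec)
  expect_error(coordinateGradients(mdl, refl, "binary"),
               "not differentiable")
})

test_that("solvent chain term is negligible for a buried atom", {
  ## dense cluster: the most crowded atom sits where the solvent mask is
  ## ~0 throughout its support, so its solvent chain term nearly vanishes
  spec <- toySpec(nAtoms = 14, cell = c(16, 16, 16), minSep = 1.8,
                  seed = 21, noise = 0.04)
  mdl <- toyCrystal(spec)
  refl <- syntheticObservations(mdl, spec)
  gf <- coordinateGradients(mdl, refl, "gaussian",
                            solvParams = solventScaleParams(0.33, 50),
                            dmin = spec$dmin)
  at <- atoms(mdl)
  nn <- vapply(seq_len(nrow(at)), function(i)
    sum(bruteDist(modelCell(mdl), as.numeric(at[i, c("x", "y", "z")]),
                  as.matrix(at[-i, c("x", "y", "z")])) < 4), numeric(1))
  buried <- which.max(nn)
  water <- which(at$water)
  nrmSolv <- sqrt(rowSums(gf@solvent^2))
  expect_lt(nrmSolv[buried], 0.25 * nrmSolv[water])
})

test_that("self-consistent data give a zero gradient and grid-shift invariance holds", {
  spec <- smallSpec(seed = 6, trueModel = "gaussian", ks = 0.33, bs = 50)
  mdl <- toyCrystal(spec)
  refl <- syntheticObservations(mdl, spec)   # noiseless, same model/params
  grid <- densityGrid(modelCell(mdl), gridDimensions(modelCell(mdl), spec$dmin))
  gf <- coordinateGradients(mdl, refl, "gaussian",
                            solvParams = solventScaleParams(0.33, 50),
                            grid = grid)
  expect_lt(gf@target, 1e-12 * sum(refl@fobs^2))
  expect_lt(max(abs(gf@total)), 1e-4)
  ## rigid shift by exactly one grid spacing permutes the mask samples:
  ## the target is unchanged to round-off
  tf <- solventTargetFunction(mdl, refl, "gaussian",
                              solvParams = solventScaleParams(0.4, 60),
                              grid = grid)
  xyz <- as.matrix(atoms(mdl)[, c("x", "y", "z")])
  shift <- c(cellLengths(modelCell(mdl))[1] / gridDim(grid)[1], 0, 0)
  t1 <- tf(xyz)
  t2 <- tf(sweep(xyz, 2, -shift))
  expect_equal(t1, t2, tolerance = 1e-9)
  ## continuum invariance under rigid translation: with no solvent model
  ## the amplitudes only pick up a global phase, so the gradient summed
  ## over all atoms vanishes even with residuals present
  spec2 <- smallSpec(seed = 6, noise = 0.05)
  refl2 <- syntheticObservations(mdl, spec2)
  gf2 <- coordinateGradients(mdl, refl2, "none", grid = grid)
  expect_lt(max(abs(colSums(gf2@atomic))), 1e-6 * max(abs(gf2@atomic)))
})

test_that("translation scan reports matching derivatives for smooth models", {
  spec <- smallSpec(seed = 4, noise = 0.04)
  mdl <- toyCrystal(spec)
  refl <- syntheticObservations(mdl, spec)
  grid <- densityGrid(modelCell(mdl), gridDimensions(modelCell(mdl), spec$dmin))
  sc <- translationScan(mdl, refl, stepSize = 0.05, nSteps = 4,
                        maskModel = "polynomial",
                        solvParams = solventScaleParams(0.33, 50),
                        grid = grid, dx = 1e-4)
  expect_equal(nrow(sc), 5)
  expect_lt(max(sc$absDiff), 1e-4 * max(abs(sc$dAnalytic)))
  ## zero steps: single-row table at the origin
  sc0 <- translationScan(mdl, refl, nSteps = 0, maskModel = "gaussian",
                         grid = grid, solvParams = solventScaleParams(0.33, 50))
  expect_equal(nrow(sc0), 1)
  expect_equal(sc0$displacement, 0)
})
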