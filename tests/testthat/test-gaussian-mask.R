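test_that("atomic Gaussian has the closed-form values", {
  expect_equal(atomicGaussian(0, 1.2), 1)
  expect_equal(atomicGaussian(sqrt(2 * log(2)) * 0.9, 0.9), 0.5,
               tolerance = 1e-12)
  expect_equal(atomicGaussian(3 * 0.7, 0.7), exp(-4.5), tolerance = 1e-12)
  expect_error(atomicGaussian(1, -1), "positive")
})

test_that("rho_sum accumulation is additive and matches the untruncated brute force", {
  cell <- unitCell(14, 14, 14)
  grid <- densityGrid(cell, c(18, 18, 18))
  prm <- gaussianMaskParams()
  ## single atom exactly on a grid node: that node reads ~1
  mdl1 <- crystalModel(cell, data.frame(element = "C",
                                        x = 14 * 5 / 18, y = 14 * 6 / 18,
                                        z = 14 * 7 / 18))
  rho1 <- accumulateRhoSum(expandSymmetryShell(mdl1, 0), grid, prm)
  expect_equal(gridValues(rho1)[6, 7, 8], 1, tolerance = 1e-5)
  ## two identical atoms equidistant from a point: twice the single value
  mdl2 <- crystalModel(cell, data.frame(element = c("C", "C"),
                                        x = c(5, 9), y = 7, z = 7))
  rho2 <- accumulateRhoSum(expandSymmetryShell(mdl2, 0), grid, prm)
  mid <- neighborGridPoints(grid, c(7, 7, 7), 0.1)
  li <- smoothsolv:::.linearIndex(unclass(mid), gridDim(grid))
  single <- atomicGaussian(2.0, 0.55 * vdwRadius("C"))
  expect_equal(gridValues(rho2)[li][1], 2 * single, tolerance = 1e-4)
  ## empty atom list: all zeros, not an error
  empty <- atoms(mdl1)[0, ]
  expect_equal(max(abs(gridValues(accumulateRhoSum(empty, grid, prm)))), 0)

  ## random 5-atom toy vs brute-force double loop with no truncation
  spec <- toySpec(nAtoms = 5, cell = c(14, 14, 14), seed = 9)
  mdl <- toyCrystal(spec)
  ex <- expandSymmetryShell(mdl, 0)
  rho <- accumulateRhoSum(ex, grid, prm)
  coords <- smoothsolv:::.gridCoords(grid)
  oracle <- numeric(nrow(coords))
  for (i in seq_len(nrow(atoms(mdl)))) {
    d <- bruteDist(cell, as.numeric(atoms(mdl)[i, c("x", "y", "z")]), coords)
    oracle <- oracle + atoms(mdl)$occ[i] *
      atomicGaussian(d, 0.55 * atoms(mdl)$radius[i])
  }
  expect_lt(max(abs(as.vector(gridValues(rho)) - oracle)), 1e-4)
})

test_that("thresholding gives the closed-form characteristic function", {
  cell <- unitCell(10, 10, 10)
  prm <- gaussianMaskParams()
  rho <- densityGrid(cell, values = array(c(0, log(2) / 11.5, 1, 0.2,
                                            rep(0, 4)), c(2, 2, 2)))
  mp <- gaussianSoluteMask(rho, prm)
  chi <- gridValues(soluteMask(mp))
  expect_equal(chi[1, 1, 1], 0)
  expect_equal(gridValues(solventMask(mp))[1, 1, 1], 1)
  expect_equal(chi[2, 1, 1], 0.5, tolerance = 1e-12)
  expect_equal(chi[1, 2, 1], 1 - exp(-11.5), tolerance = 1e-12)
  ## solute + solvent = 1 pointwise, both within [0, 1]
  expect_equal(max(abs(chi + gridValues(solventMask(mp)) - 1)), 0)
  bad <- densityGrid(cell, values = array(-0.5, c(2, 2, 2)))
  expect_error(gaussianSoluteMask(bad, prm), "negative")
})

test_that("adding an atom never decreases the solute mask", {
  spec <- toySpec(nAtoms = 6, cell = c(14, 15, 16), seed = 4)
  mdl <- toyCrystal(spec)
  m6 <- gaussianMasks(mdl, dmin = 2.5)
  at5 <- atoms(mdl)[1:5, ]
  mdl5 <- crystalModel(modelCell(mdl), at5)
  m5 <- gaussianMasks(mdl5, dmin = 2.5)
  expect_true(all(gridValues(soluteMask(m6)) >=
                  gridValues(soluteMask(m5)) - 1e-12))
})

test_that("1D radial profile is smooth, monotone and reaches bulk by ~3.5 A", {
  ## single atom with vdW 1.75 A at default parameters
  sigma <- 0.55 * 1.75
  r <- seq(0, 5, by = 0.01)
  chi <- 1 - exp(-11.5 * atomicGaussian(r, sigma))
  expect_true(all(diff(chi) <= 0))            # monotone decreasing in r
  expect_lt(max(abs(diff(chi))), 0.02)        # no jumps at this sampling
  expect_lt(chi[which.min(abs(r - 3.5))], 0.02)  # solvent ~1 by 3.5 A
  ## crosses half height between a - w and a + 1.0 (shared with polynomial)
  cross <- r[which(chi < 0.5)[1]]
  expect_gt(cross, 1.75 - 0.8)
  expect_lt(cross, 1.75 + 1.0)
})

test_that("mask point derivative matches finite differences and is antisymmetric", {
  sigma <- 0.55 * 1.52
  A <- 11.5
  atomPos <- c(3.1, 2.2, 4.4)
  gp <- c(4.0, 2.9, 3.6)
  chiAt <- function(p) 1 - exp(-A * atomicGaussian(sqrt(sum((gp - p)^2)), sigma))
  dvec <- matrix(gp - atomPos, 1)
  solv <- exp(-A * atomicGaussian(sqrt(sum(dvec^2)), sigma))
  gAna <- gaussianMaskGradient(dvec, solv, sigma, A)
  for (a in 1:3) {
    fd <- finiteDifferenceGradient(function(d) {
      p <- atomPos; p[a] <- p[a] + d; chiAt(p)
    }, 0, 1e-5)
    expect_equal(gAna[1, a], fd, tolerance = 1e-4)
  }
  ## atom on the grid point: zero vector
  g0 <- gaussianMaskGradient(matrix(0, 1, 3), solv, sigma, A)
  expect_equal(as.numeric(g0), c(0, 0, 0))
  ## two grid points symmetric about the atom: equal and opposite
  gPlus <- gaussianMaskGradient(matrix(c(1, -0.4, 0.2), 1), 0.7, sigma, A)
  gMinus <- gaussianMaskGradient(matrix(-c(1, -0.4, 0.2), 1), 0.7, sigma, A)
  expect_equal(gPlus, -gMinus)
})
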