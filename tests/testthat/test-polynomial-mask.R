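test_that("cubic switch hits its closed-form values and endpoints", {
  w <- 0.8
  s0 <- switchValue(0, w)
  expect_equal(s0$S, 1)
  expect_equal(s0$dS, 0)
  expect_equal(switchValue(w, w)$S, 0.5, tolerance = 1e-12)  # r = a midpoint
  expect_equal(switchValue(0.4, w)$S, 1 - 3 * 0.25^2 + 2 * 0.25^3,
               tolerance = 1e-12)                             # 0.84375
  s2 <- switchValue(2 * w, w)
  expect_equal(s2$S, 0)
  expect_equal(s2$dS, 0)
  expect_error(switchValue(0.1, -1), "positive")
})

test_that("switch is C1 at both window boundaries", {
  w <- 0.8
  for (edge in c(0, 2 * w)) {
    ## slope probed from each side of the boundary
    eps <- 1e-7
    slopeIn <- (switchValue(edge + eps, w)$S - switchValue(edge, w)$S) / eps
    slopeOut <- (switchValue(edge, w)$S - switchValue(edge - eps, w)$S) / eps
    expect_lt(abs(slopeIn - slopeOut), 1e-6)
    ## analytic slope continuous too
    expect_lt(abs(switchValue(edge + eps, w)$dS -
                  switchValue(edge - eps, w)$dS), 1e-6)
  }
})

test_that("polynomial mask equals the brute-force product and has exact limits", {
  spec <- toySpec(nAtoms = 5, cell = c(14, 14, 14), seed = 9)
  mdl <- toyCrystal(spec)
  cell <- modelCell(mdl)
  grid <- densityGrid(cell, c(18, 18, 18))
  prm <- polynomialMaskParams()
  mp <- polynomialMasks(mdl, grid = grid, params = prm)
  solv <- as.vector(gridValues(solventMask(mp)))

  coords <- smoothsolv:::.gridCoords(grid)
  oracle <- rep(1, nrow(coords))
  mind <- rep(Inf, nrow(coords))
  maxin <- rep(FALSE, nrow(coords))
  at <- atoms(mdl)
  for (i in seq_len(nrow(at))) {
    d <- bruteDist(cell, as.numeric(at[i, c("x", "y", "z")]), coords)
    oracle <- oracle * (1 - at$occ[i] * switchValue(d - at$radius[i] + prm$w,
                                                    prm$w)$S)
    mind <- pmin(mind, d - at$radius[i])
    maxin <- maxin | d < at$radius[i] + prm$w
  }
  expect_lt(max(abs(solv - oracle)), 1e-12)
  chi <- as.vector(gridValues(soluteMask(mp)))
  ## compactly supported transition: exact 1 inside any core, exact 0 in bulk
  expect_true(all(chi[mind <= -prm$w] == 1))
  expect_true(all(chi[!maxin] == 0))
  expect_true(all(chi >= 0 & chi <= 1))
})

test_that("mask is 0.5 at the vdW radius of an isolated atom", {
  cell <- unitCell(14, 14, 14)
  grid <- densityGrid(cell, c(18, 18, 18))
  ## atom on a node; probe the node at distance ~a along x
  mdl <- crystalModel(cell, data.frame(element = "Cl", x = 14 * 5 / 18,
                                       y = 14 * 9 / 18, z = 14 * 9 / 18))
  a <- vdwRadius("Cl")  # 1.75
  chiAt <- function(rvec) {
    d <- sqrt(sum(rvec^2))
    switchValue(d - a + 0.8, 0.8)$S
  }
  mp <- polynomialMasks(mdl, grid = grid)
  ## closed form at the exact radius
  expect_equal(switchValue(a - a + 0.8, 0.8)$S, 0.5)
  ## grid agrees with the single-atom closed form at a probe node
  probe <- gridValues(soluteMask(mp))[8, 10, 10]  # 2 spacings off along x
  expect_equal(probe, chiAt(c(2 * 14 / 18, 0, 0)), tolerance = 1e-12)
})

test_that("window wider than an atom radius is rejected", {
  mdl <- toyCrystal(toySpec(nAtoms = 3, cell = c(14, 14, 14), seed = 2))
  expect_error(polynomialMasks(mdl, dmin = 2.5,
                               params = polynomialMaskParams(w = 1.6)),
               "radius must exceed")
})

test_that("polynomial point derivative matches finite differences", {
  a <- 1.52; w <- 0.8
  atomPos <- c(5.0, 5.0, 5.0)
  ## in-window grid point
  gp <- atomPos + c(1.1, 0.6, -0.4)
  others <- 0.9  # product of the other atoms' factors
  chiAt <- function(p) {
    d <- sqrt(sum((gp - p)^2))
    1 - others * (1 - switchValue(d - a + w, w)$S)
  }
  r <- sqrt(sum((gp - atomPos)^2))
  h <- 1 - switchValue(r - a + w, w)$S
  gAna <- polynomialMaskGradient(matrix(gp - atomPos, 1), r,
                                 solvent = others * h, radius = a, w = w)
  for (ax in 1:3) {
    fd <- finiteDifferenceGradient(function(d) {
      p <- atomPos; p[ax] <- p[ax] + d; chiAt(p)
    }, 0, 1e-5)
    expect_equal(gAna[1, ax], fd, tolerance = 1e-4)
  }
  ## outside every window: zero vector
  gpFar <- atomPos + c(3, 0, 0)
  gFar <- polynomialMaskGradient(matrix(gpFar - atomPos, 1), 3,
                                 solvent = 1, radius = a, w = w)
  expect_equal(as.numeric(gFar), c(0, 0, 0))
  ## antipodal in-window points: equal magnitude, opposite sign
  d1 <- matrix(c(1.4, 0, 0), 1)
  g1 <- polynomialMaskGradient(d1, 1.4, 0.5, a, w)
  g2 <- polynomialMaskGradient(-d1, 1.4, 0.5, a, w)
  expect_equal(g1, -g2)
})
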