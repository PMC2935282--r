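test_that("form factors match the frozen external-oracle values", {
  ## values computed once with an independent crystallographic library
  ## (float32 precision there bounds the comparison at ~1e-6 relative)
  expect_equal(formFactor("C", 0), 5.999199867, tolerance = 1e-6)
  expect_equal(formFactor("C", 0.25), 4.713607311, tolerance = 1e-6)
  expect_equal(formFactor("C", 0.5), 2.949761152, tolerance = 1e-6)
  expect_equal(formFactor("O", 0.3), 6.472083092, tolerance = 1e-6)
  expect_equal(formFactor("N", 0.4), 4.559760094, tolerance = 1e-6)
  expect_equal(formFactor("S", 0.2), 14.177241325, tolerance = 1e-6)
  expect_error(formFactor("Xx", 0.1), "no form-factor")
})

test_that("atomic structure factors match the frozen external oracle", {
  mdl <- oracleModel()
  hkl <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(2, 3, 1),
               c(-1, 2, 4), c(3, -2, 2), c(5, 1, 0))
  refl <- reflectionSet(tricCell(), hkl)
  fc <- atomicStructureFactors(mdl, refl)
  oracle <- c(-1.7749882984287142 + 14.383328864960312i,
              -6.955257464155112 + 1.8953856179336315i,
              -3.9808582801953265 + 12.62367016628229i,
              5.608872198920009 - 1.1969875942317605i,
              5.566605659447606 - 0.18237865004023313i,
              -6.152483713210369 - 2.6021493398836895i,
              0.9502013044105391 - 1.8139278020302014i)
  expect_lt(max(Mod(fc - oracle)) / max(Mod(oracle)), 1e-6)
})

test_that("origin atom and shift theorem behave as structure-factor algebra requires", {
  cell <- unitCell(10, 10, 10)
  refl <- makeReflectionSet(cell, 2.5)
  mdl0 <- crystalModel(cell, data.frame(element = "C", x = 0, y = 0, z = 0,
                                        b = 0))
  fc0 <- atomicStructureFactors(mdl0, refl)
  expect_lt(max(abs(Im(fc0))), 1e-10)               # phase zero at origin
  expect_equal(Re(fc0), formFactor("C", sValues(refl)), tolerance = 1e-10)
  ## half-cell shift along a: F(h00) gains (-1)^h
  mdl5 <- crystalModel(cell, data.frame(element = "C", x = 5, y = 0, z = 0,
                                        b = 0))
  fc5 <- atomicStructureFactors(mdl5, refl)
  h00 <- millerIndices(refl)[, 2] == 0 & millerIndices(refl)[, 3] == 0
  expect_equal(fc5[h00], fc0[h00] * (-1)^millerIndices(refl)[h00, 1],
               tolerance = 1e-10)
})

test_that("mask FFT matches a brute-force DFT and Babinet's identity holds", {
  cell <- unitCell(9, 10, 11, 90, 95, 90)
  set.seed(21)
  vals <- array(runif(8 * 10 * 8), c(8, 10, 8))
  grid <- densityGrid(cell, values = vals)
  refl <- reflectionSet(cell, rbind(c(1, 0, 0), c(0, 2, 1), c(-2, 1, 3),
                                    c(3, -1, -2), c(1, 1, 1)))
  fm <- maskStructureFactors(grid, refl)
  ## brute-force DFT oracle over every grid point
  coordsF <- cbind(rep((0:7) / 8, times = 80),
                   rep(rep((0:9) / 10, each = 8), times = 8),
                   rep((0:7) / 8, each = 80))
  vol <- cellVolume(cell)
  oracle <- vapply(seq_len(length(refl)), function(j) {
    ph <- 2 * pi * (coordsF %*% millerIndices(refl)[j, ])
    (vol / length(vals)) * sum(as.vector(vals) * exp(1i * ph))
  }, complex(1))
  expect_lt(max(Mod(fm - oracle)) / max(Mod(oracle)), 1e-10)

  ## all-one mask: zero at every non-origin reflection
  ones <- densityGrid(cell, values = array(1, c(8, 10, 8)))
  expect_lt(max(Mod(maskStructureFactors(ones, refl))), 1e-9)
  ## FT(1 - chi) = -FT(chi) for h != 0 (Babinet)
  compl <- densityGrid(cell, values = 1 - vals)
  expect_lt(max(Mod(maskStructureFactors(compl, refl) + fm)), 1e-9)
  ## too-coarse grid is an error
  expect_error(maskStructureFactors(grid, reflectionSet(cell, rbind(c(5, 0, 0)))),
               "too coarse")
})

test_that("Friedel symmetry and Parseval consistency hold for real masks", {
  spec <- toySpec(nAtoms = 5, cell = c(14, 14, 14), seed = 9)
  mdl <- toyCrystal(spec)
  mask <- gaussianMasks(mdl, dmin = 3)
  cell <- modelCell(mdl)
  hkl <- rbind(c(1, 2, 1), c(2, 0, 1), c(1, 1, 3))
  both <- reflectionSet(cell, rbind(hkl, -hkl))
  fm <- maskStructureFactors(mask, both)
  expect_equal(fm[4:6], Conj(fm[1:3]), tolerance = 1e-12)
  fc <- atomicStructureFactors(mdl, both)
  expect_equal(fc[4:6], Conj(fc[1:3]), tolerance = 1e-10)
  ## Parseval: (V/N)^2 sum|DFT|^2 = V^2/N * mean(chi^2) * N/N
  v <- gridValues(soluteMask(mask))
  X <- fft(v, inverse = TRUE)
  lhs <- sum(Mod(X)^2) / length(v)
  expect_equal(lhs, sum(v^2), tolerance = 1e-9)
})

test_that("solvent scaling and Babinet combination follow the closed forms", {
  p <- solventScaleParams(0.33, 50)
  expect_equal(solventScale(0, p), 0.33)
  expect_equal(solventScale(0.4, solventScaleParams(0.2, 0)), 0.2)
  expect_equal(solventScale(1 / 6, p), 0.33 * exp(-50 / 144),
               tolerance = 1e-12)
  s <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(solventScale(s, p)) < 0))  # monotone decreasing

  spec <- smallSpec(seed = 8)
  mdl <- toyCrystal(spec)
  refl <- makeReflectionSet(modelCell(mdl), spec$dmin)
  mask <- gaussianMasks(mdl, dmin = spec$dmin)
  fc <- atomicStructureFactors(mdl, refl)
  fm <- maskStructureFactors(mask, refl)
  ## k_s = 0 switches the solvent off exactly
  expect_equal(totalStructureFactors(fc, fm, sValues(refl),
                                     solventScaleParams(0, 123)), fc)
  ## solvent-region mask with + sign equals solute mask with - sign
  fmSolv <- maskStructureFactors(solventMask(mask), refl)
  ftA <- fc - solventScale(sValues(refl), p) * fm
  ftB <- fc + solventScale(sValues(refl), p) * fmSolv
  expect_lt(max(Mod(ftA - ftB)) / max(Mod(ftA)), 1e-10)
  ## solvent correction concentrates at low resolution on the toy fixture
  dAmp <- Mod(ftA - fc)
  sref <- sValues(refl)
  lowQ <- sref <= stats::quantile(sref, 0.1)
  highQ <- sref >= stats::quantile(sref, 0.9)
  expect_gt(mean(dAmp[lowQ]), 5 * mean(dAmp[highQ]))
  expect_error(totalStructureFactors(fc[-1], fm, sValues(refl), p),
               "same reflection list")
})

test_that("anisotropic overall scale reduces correctly and matches brute force", {
  spec <- smallSpec(seed = 8)
  mdl <- toyCrystal(spec)
  refl <- makeReflectionSet(modelCell(mdl), 3)
  amp <- runif(length(refl), 10, 100)
  ## identity: unchanged
  expect_equal(applyAnisoScale(amp, refl, anisoScaleParams()), amp)
  ## isotropic tensor = scalar Debye-Waller
  iso <- applyAnisoScale(amp, refl, anisoScaleParams(1.3, diag(3) * 20))
  expect_equal(iso, 1.3 * exp(-20 * sValues(refl)^2 / 4) * amp,
               tolerance = 1e-12)
  ## random symmetric tensor vs per-reflection quadratic form
  set.seed(5)
  M <- matrix(rnorm(9), 3); B <- M + t(M)
  got <- applyAnisoScale(amp, refl, anisoScaleParams(0.9, B))
  sv <- sVectors(modelCell(mdl), millerIndices(refl))
  oracle <- vapply(seq_len(length(refl)), function(j)
    0.9 * exp(-drop(sv[j, ] %*% B %*% sv[j, ]) / 4) * amp[j], numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(anisoScaleParams(1, matrix(1:9, 3)), "symmetric")
})

test_that("reflection enumeration excludes F(000), duplicates and Friedel mates", {
  refl <- makeReflectionSet(unitCell(20, 20, 20), 3)
  hkl <- millerIndices(refl)
  expect_false(any(rowSums(hkl == 0) == 3))
  expect_equal(anyDuplicated(hkl), 0L)
  expect_equal(anyDuplicated(rbind(hkl, -hkl)), 0L)  # one per Friedel pair
  expect_true(all(sValues(refl) <= 1 / 3 + 1e-12))
  expect_error(reflectionSet(unitCell(10, 10, 10), rbind(c(0, 0, 0))),
               "F\\(000\\)")
})
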